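STOP_CODONS <- c("TGA", "TAA", "TAG")

#' Locate open reading frames on both strands
#'
#' Finds all maximal stop-terminated ORFs: within each stop-bounded segment
#' of each reading frame, the most upstream start codon defines the single
#' reported ORF. The reported span includes the stop codon. ORFs are purely
#' syntactic -- no ribosome-binding-site or codon-usage scoring.
#'
#' @param seq_id Sequence identifier carried into the output.
#' @param residues Nucleotide string over `{A,C,G,T}` (+ ambiguity codes;
#'   codons holding ambiguity codes never count as start or stop).
#' @param min_len Minimum ORF length in nucleotides, stop codon included
#'   (default 300, sized for selB-scale genes in genome scans; unit-scale
#'   work typically passes 30). Must be at least 6.
#' @param start_codons Set of permitted initiator codons.
#' @return Tibble with columns `seq_id`, `start`, `end` (0-based half-open,
#'   genome forward-strand coordinates), `strand`, `frame` (0..2 on the
#'   scanned strand), `start_codon`, `stop_codon`. Sorted by strand then
#'   start.
#' @export
find_orfs <- function(seq_id, residues, min_len = 300,
                      start_codons = c("ATG", "GTG", "TTG")) {
  stopifnot(min_len >= 6)
  L <- nchar(residues)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") residues else reverse_complement(residues)
    for (frame in 0:2) {
      if (L - frame < 6) next
      starts <- seq(frame + 1, L - 2, by = 3)
      codons <- substring(s, starts, starts + 2)
      stop_i <- which(codons %in% STOP_CODONS)
      if (length(stop_i) == 0) next
      seg_begin <- c(1L, stop_i + 1L)       # codon index where segment opens
      for (k in seq_along(stop_i)) {
        lo <- seg_begin[k]
        hi <- stop_i[k]
        if (lo > hi - 1) next
        cand <- which(codons[lo:(hi - 1)] %in% start_codons)
        if (length(cand) == 0) next
        first <- lo + cand[1] - 1L
        loc_start <- starts[first] - 1L     # 0-based on scanned strand
        loc_end <- starts[hi] + 2L          # 0-based exclusive, incl. stop
        if (loc_end - loc_start < min_len) next
        if (strand == "+") {
          g_start <- loc_start; g_end <- loc_end
        } else {
          g_start <- L - loc_end; g_end <- L - loc_start
        }
        rows[[length(rows) + 1]] <- tibble(
          seq_id = seq_id, start = g_start, end = g_end, strand = strand,
          frame = frame, start_codon = codons[first], stop_codon = codons[hi])
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(seq_id = character(), start = integer(), end = integer(),
                  strand = character(), frame = integer(),
                  start_codon = character(), stop_codon = character()))
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$strand, .data$start, .data$end)
}

#' Stop-start translational coupling between consecutive ORFs
#'
#' Measures how the upstream ORF's stop codon relates to the downstream
#' ORF's start codon: either the two codon intervals share `overlap_len`
#' positions (1..3, the re-initiation geometry of polycistronic operons) or
#' they are disjoint and separated by `spacer` nucleotides.
#'
#' @param upstream,downstream Single-row ORF tibbles (rows of
#'   [find_orfs()] output) on the same strand of the same sequence, with
#'   the downstream ORF starting at or after the upstream stop codon in the
#'   direction of translation.
#' @return A list with `overlap_len` (0..3) and `spacer` (NA unless
#'   `overlap_len` is 0).
#' @export
detect_stop_start_coupling <- function(upstream, downstream) {
  if (upstream$seq_id != downstream$seq_id) {
    stop("ORFs are on different sequences")
  }
  if (upstream$strand != downstream$strand) {
    stop("ORFs are on different strands")
  }
  if (upstream$strand == "+") {
    stop_iv <- c(upstream$end - 3, upstream$end)
    start_iv <- c(downstream$start, downstream$start + 3)
    gap <- downstream$start - upstream$end
  } else {
    stop_iv <- c(upstream$start, upstream$start + 3)
    start_iv <- c(downstream$end - 3, downstream$end)
    gap <- upstream$start - downstream$end
  }
  ov <- max(0, min(stop_iv[2], start_iv[2]) - max(stop_iv[1], start_iv[1]))
  list(overlap_len = as.integer(ov),
       spacer = if (ov == 0) as.integer(gap) else NA_integer_)
}

# nearest same-strand ORF downstream (in translation direction) of `orf`
# among `orfs`; ties broken by length (longest first). NULL when none.
nearest_downstream_orf <- function(orf, orfs) {
  same <- orfs[orfs$seq_id == orf$seq_id & orfs$strand == orf$strand, ]
  if (orf$strand == "+") {
    cand <- same[same$start >= orf$end - 3 & same$start > orf$start, ]
    if (nrow(cand) == 0) return(NULL)
    cand <- cand[order(cand$start, -(cand$end - cand$start)), ]
  } else {
    cand <- same[same$end <= orf$start + 3 & same$end < orf$end, ]
    if (nrow(cand) == 0) return(NULL)
    cand <- cand[order(-cand$end, -(cand$end - cand$start)), ]
  }
  cand[1, ]
}
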