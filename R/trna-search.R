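#' Default thresholds for tRNA homology search
#'
#' Scoring is the standard nucleotide local-alignment regime (match +2,
#' mismatch -2, affine gaps -5 open / -2 per position); it keeps a
#' 75%-identity 96-nt tRNA well above the background of random sequence at
#' the default identity/coverage filters.
#'
#' @param min_identity Minimum alignment identity for a reported hit.
#' @param min_cov_nt Minimum number of reference positions covered.
#' @param flank Window flank (nt) added on both sides of an ORF when
#'   searching for tRNA hits.
#' @param match,mismatch,gap_open,gap_extend Alignment scoring parameters;
#'   a gap run of length L costs `gap_open + L * gap_extend`.
#' @return A named list of thresholds used by [locate_trna()] and
#'   [scan_genome()].
#' @export
trna_search_config <- function(min_identity = 0.75, min_cov_nt = 30,
                               flank = 150, match = 2, mismatch = -2,
                               gap_open = -5, gap_extend = -2) {
  list(min_identity = min_identity, min_cov_nt = min_cov_nt, flank = flank,
       match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend)
}

#' Optimal local alignment of two nucleotide strings
#'
#' Smith-Waterman local alignment with affine gap penalties (a gap run of
#' length L costs `gap_open + L * gap_extend`). The heavy lifting is done
#' by [Biostrings::pairwiseAlignment()]; this wrapper fixes the scoring
#' convention and exposes the column-level pair map needed to transfer
#' coordinates between the reference and the target.
#'
#' @param a Query/reference nucleotide string.
#' @param b Target nucleotide string.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters
#'   (`match > 0`, the others `< 0`).
#' @return A list of class `local_alignment` with elements `score`,
#'   `query_interval` and `target_interval` (0-based half-open; empty when
#'   the best score is 0), `identity` (matches / alignment columns,
#'   gapped columns included), and `pair_map`, an integer matrix with
#'   columns `ref`/`tgt` giving the 1-based positions of every
#'   matched or mismatched column (gap columns omitted), strictly
#'   increasing in both coordinates.
#' @export
sw_align <- function(a, b, match = 2, mismatch = -2, gap_open = -5,
                     gap_extend = -2) {
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0)
  empty <- list(score = 0, query_interval = c(0L, 0L),
                target_interval = c(0L, 0L), identity = NA_real_,
                pair_map = matrix(integer(0), ncol = 2,
                                  dimnames = list(NULL, c("ref", "tgt"))))
  class(empty) <- "local_alignment"
  if (nchar(a) == 0 || nchar(b) == 0) return(empty)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = mat, gapOpening = abs(gap_open),
    gapExtension = abs(gap_extend))
  sc <- Biostrings::score(aln)
  if (sc <= 0) return(empty)
  pat <- Biostrings::pattern(aln)
  sub <- Biostrings::subject(aln)
  pg <- strsplit(as.character(pat), "", fixed = TRUE)[[1]]
  sg <- strsplit(as.character(sub), "", fixed = TRUE)[[1]]
  qpos <- Biostrings::start(pat) - 1L
  tpos <- Biostrings::start(sub) - 1L
  ref_i <- integer(0); tgt_i <- integer(0); nmatch <- 0L
  for (k in seq_along(pg)) {
    qgap <- pg[k] == "-"; tgap <- sg[k] == "-"
    if (!qgap) qpos <- qpos + 1L
    if (!tgap) tpos <- tpos + 1L
    if (!qgap && !tgap) {
      ref_i <- c(ref_i, qpos); tgt_i <- c(tgt_i, tpos)
      if (pg[k] == sg[k]) nmatch <- nmatch + 1L
    }
  }
  out <- list(
    score = sc,
    query_interval = c(Biostrings::start(pat) - 1L, Biostrings::end(pat)),
    target_interval = c(Biostrings::start(sub) - 1L, Biostrings::end(sub)),
    identity = nmatch / length(pg),
    pair_map = cbind(ref = ref_i, tgt = tgt_i))
  class(out) <- "local_alignment"
  out
}

#' Localize reference tRNA-Sec sequences within a window
#'
#' Aligns every reference against the window (and, optionally, its reverse
#' complement) and reports at most one best hit per reference per strand,
#' subject to identity and reference-coverage thresholds. Hit strand is
#' recorded relative to the window (i.e. the ORF orientation the window
#' was extracted in): `'-'` means the reference matches the reverse
#' complement of the window.
#'
#' @param window A list or one-row tibble with `id` and `residues`
#'   (typically an ORF plus flanks).
#' @param refs Reference tibble as returned by [reference_set()] (columns
#'   `id`, `residues`, `variant`, `has_cca`).
#' @param both_strands Search the reverse complement of the window too.
#' @param cfg Thresholds from [trna_search_config()].
#' @return Tibble of hits: `ref_id`, `seq_id`, `start`, `end` (0-based
#'   half-open window coordinates of the matched region), `strand`,
#'   `identity`, `ref_cov_start`, `ref_cov_end`, `score`, and a list-column
#'   `alignment` holding the `local_alignment` (computed on the
#'   strand-local window) plus the strand-local target string.
#' @export
locate_trna <- function(window, refs, both_strands = TRUE,
                        cfg = trna_search_config()) {
  if (is.null(refs) || nrow(refs) == 0) stop("no reference tRNA sequences given")
  Lw <- nchar(window$residues)
  strands <- if (both_strands) c("+", "-") else "+"
  rows <- list()
  for (strand in strands) {
    tgt <- if (strand == "+") window$residues else reverse_complement(window$residues)
    for (r in seq_len(nrow(refs))) {
      aln <- sw_align(refs$residues[r], tgt, cfg$match, cfg$mismatch,
                      cfg$gap_open, cfg$gap_extend)
      if (aln$score <= 0) next
      cov <- aln$query_interval[2] - aln$query_interval[1]
      if (is.na(aln$identity) || aln$identity < cfg$min_identity ||
          cov < cfg$min_cov_nt) next
      ti <- aln$target_interval
      span <- if (strand == "+") ti else c(Lw - ti[2], Lw - ti[1])
      rows[[length(rows) + 1]] <- tibble(
        ref_id = refs$id[r], seq_id = window$id,
        start = as.integer(span[1]), end = as.integer(span[2]),
        strand = strand, identity = aln$identity,
        ref_cov_start = aln$query_interval[1],
        ref_cov_end = aln$query_interval[2],
        score = aln$score,
        alignment = list(list(aln = aln, strand = strand, target = tgt,
                              window_len = Lw)))
    }
  }
  if (length(rows) == 0) {
    return(tibble(ref_id = character(), seq_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  identity = numeric(), ref_cov_start = integer(),
                  ref_cov_end = integer(), score = numeric(),
                  alignment = list()))
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, dplyr::desc(.data$score), .data$start, .data$ref_id)
}

#' Extract tRNA gene features from a hit
#'
#' Reports the matched gene length, whether the gene encodes its own 3'
#' CCA tail, the discriminator base, 5' anchoring, and the fraction of the
#' reference covered. The discriminator is located through the alignment
#' (the base matched to the reference position immediately 5' of the
#' encoded CCA, or to the reference 3' terminus for CCA-less references),
#' so tRNA-length variants do not shift it; if the alignment does not
#' cover that position the discriminator is reported as `NA` (unknown).
#'
#' @param hit One row of [locate_trna()] output.
#' @param ref The matching row of the reference tibble.
#' @return A list: `gene_length`, `has_cca`, `discriminator`,
#'   `five_prime_anchored`, `coverage_fraction`.
#' @export
trna_features <- function(hit, ref) {
  stopifnot(hit$ref_id == ref$id)
  aln_info <- hit$alignment[[1]]
  pm <- aln_info$aln$pair_map
  tgt <- aln_info$target
  gene_length <- hit$end - hit$start
  last3 <- ""
  if (nrow(pm) >= 3) {
    tail_pairs <- pm[(nrow(pm) - 2):nrow(pm), , drop = FALSE]
    last3 <- paste(substring(tgt, tail_pairs[, "tgt"], tail_pairs[, "tgt"]),
                   collapse = "")
  }
  ref_len <- nchar(ref$residues)
  disc_pos <- if (isTRUE(ref$has_cca)) ref_len - 3L else ref_len
  hitmatch <- match(disc_pos, pm[, "ref"])
  discriminator <- if (is.na(hitmatch)) NA_character_ else
    substring(tgt, pm[hitmatch, "tgt"], pm[hitmatch, "tgt"])
  reaches_3p <- nrow(pm) > 0 && pm[nrow(pm), "ref"] == ref_len
  list(gene_length = as.integer(gene_length),
       has_cca = identical(last3, "CCA") && reaches_3p,
       discriminator = discriminator,
       five_prime_anchored = hit$ref_cov_start <= 5,
       coverage_fraction = (hit$ref_cov_end - hit$ref_cov_start) / ref_len)
}
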