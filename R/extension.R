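#' Translated C-terminal extension signature of an overlap call
#'
#' Conceptually translates, in the host ORF's reading frame, the region of
#' the ORF that derives from the tRNA gene, yielding the C-terminal
#' extension peptide of the SelB-like product.
#'
#' For forward calls the extension runs from the first in-frame codon at or
#' after the tRNA 5' boundary through the last codon before the ORF stop.
#' For reverse calls the first codon is the one containing the complement
#' of the encoded CCA end (`TGG` on the sense strand, hence Trp) and the
#' last codon is the triplet covering tRNA positions -1..+2 complemented
#' (`CCN`, hence Pro); with a tRNA gene length of 2 mod 3 both fall in one
#' frame. An internal stop codon (possible after mutation) truncates the
#' peptide, which then ends in `'*'` and is flagged `truncated`.
#'
#' @param call An `overlap_call` from [classify_locus()] with a non-NONE
#'   archetype among COMPLETE_FORWARD, COMPLETE_REVERSE, PARTIAL_FORWARD,
#'   REMNANT_FORWARD.
#' @param residues The sequence the call's coordinates refer to (the scan
#'   window, ORF-forward orientation).
#' @return A list of class `extension_signature`: `peptide`, `first_aa`,
#'   `last_aa`, `length_nt` (nt count of the tRNA-derived region, i.e. the
#'   hit span), `multiple_of_3`, `frame_offset` (0 when the tRNA 5'
#'   boundary is on a codon boundary), `truncated`, and `codons`, a tibble
#'   anchoring each translated codon to the 1-based tRNA reference
#'   coordinate of its first base (`NA` where the alignment has no matched
#'   column there). Returns `NULL` with a warning when no complete first
#'   codon fits before the stop.
#' @export
extension_signature <- function(call, residues) {
  stopifnot(inherits(call, "overlap_call"))
  if (!(call$archetype %in% c("COMPLETE_FORWARD", "COMPLETE_REVERSE",
                              "PARTIAL_FORWARD", "REMNANT_FORWARD"))) {
    stop("extension signatures are defined for overlap archetypes only, not ",
         call$archetype)
  }
  orf <- call$orf
  hit <- call$hit
  aln_info <- hit$alignment[[1]]
  pm <- aln_info$aln$pair_map
  Lw <- aln_info$window_len
  frame_offset <- (hit$start - orf$start) %% 3
  c1 <- orf$start + 3 * ceiling((hit$start - orf$start) / 3)
  last_before_stop <- orf$end - 6
  if (hit$strand == "+") {
    lc <- last_before_stop
  } else {
    # codon containing the base just past the hit span (complement of -1)
    lc <- orf$start + 3 * ((hit$end - orf$start) %/% 3)
    if (lc > last_before_stop) lc <- last_before_stop
  }
  if (c1 > lc) {
    warning("no complete extension codon fits between the tRNA boundary and the stop")
    return(NULL)
  }
  region <- substr(residues, c1 + 1, lc + 3)
  peptide <- translate_nt(region, run_to_stop = TRUE)
  # the region excludes the ORF stop, so any stop here is internal
  truncated <- grepl("*", peptide, fixed = TRUE)
  aas <- strsplit(peptide, "", fixed = TRUE)[[1]]
  non_stop <- aas[aas != "*"]
  codon_starts <- seq(c1, by = 3, length.out = length(aas))
  ref_coord <- vapply(codon_starts, function(p) {
    t1 <- if (hit$strand == "+") p + 1L else Lw - p
    k <- match(t1, pm[, "tgt"])
    if (is.na(k)) NA_integer_ else as.integer(pm[k, "ref"])
  }, integer(1))
  length_nt <- hit$end - hit$start
  out <- list(
    peptide = peptide,
    first_aa = if (length(aas) > 0) aas[1] else NA_character_,
    last_aa = if (length(non_stop) > 0) non_stop[length(non_stop)] else NA_character_,
    length_nt = as.integer(length_nt),
    multiple_of_3 = length_nt %% 3 == 0,
    frame_offset = as.integer(frame_offset),
    truncated = truncated,
    codons = tibble(ref_coord = ref_coord, aa = aas))
  class(out) <- "extension_signature"
  out
}

#' tRNA-coordinate-anchored conservation profile of extensions
#'
#' Aggregates extension signatures into per-column residue frequencies,
#' where a column is the 1-based tRNA reference coordinate of a codon's
#' first base. Anchoring by reference coordinate replaces a multiple
#' sequence alignment: calls that lack a column (remnants, partial
#' overlaps) simply do not contribute to it. The result is invariant under
#' permutation of the input.
#'
#' @param signatures A list of `extension_signature` objects (stop
#'   characters and unanchored codons are skipped).
#' @return A list with `columns`, a tibble (`ref_coord`, `residue`,
#'   `count`, `fraction` of contributing sequences at that column), and
#'   `n_sequences`.
#' @export
profile_extensions <- function(signatures) {
  signatures <- Filter(Negate(is.null), signatures)
  if (length(signatures) == 0) {
    return(list(columns = tibble(ref_coord = integer(), residue = character(),
                                 count = integer(), fraction = numeric()),
                n_sequences = 0L))
  }
  rows <- dplyr::bind_rows(lapply(signatures, function(s) s$codons))
  rows <- rows[!is.na(rows$ref_coord) & rows$aa != "*", ]
  counts <- dplyr::count(rows, .data$ref_coord, .data$aa, name = "count")
  totals <- dplyr::count(rows, .data$ref_coord, name = "n_col")
  counts <- dplyr::left_join(counts, totals, by = "ref_coord")
  counts$fraction <- counts$count / counts$n_col
  counts <- dplyr::arrange(counts, .data$ref_coord, dplyr::desc(.data$count),
                           .data$aa)
  list(columns = tibble(ref_coord = counts$ref_coord, residue = counts$aa,
                        count = as.integer(counts$count),
                        fraction = counts$fraction),
       n_sequences = length(signatures))
}

#' Write a conservation profile as TSV
#'
#' @param profile Output of [profile_extensions()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_conservation_tsv <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#ref_coord\tresidue\tcount\tfraction", con)
  cols <- profile$columns
  if (nrow(cols) > 0) {
    writeLines(sprintf("%d\t%s\t%d\t%.6f", cols$ref_coord, cols$residue,
                       cols$count, cols$fraction), con)
  }
  invisible(path)
}
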