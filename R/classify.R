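ARCHETYPES <- c("COMPLETE_FORWARD", "COMPLETE_REVERSE", "PARTIAL_FORWARD",
                "REMNANT_FORWARD", "ADJACENT", "SPACED", "NONE")

#' Classification thresholds
#'
#' The overlap archetypes are qualitative categories; these numeric cut
#' points separate them operationally. Defaults keep the planted archetype
#' geometries cleanly separable at point-mutation rates up to ~10%.
#'
#' @param complete_cov Minimum reference coverage fraction for a
#'   COMPLETE_* call.
#' @param remnant_cov_lo,remnant_cov_hi Coverage-fraction window
#'   `[lo, hi)` that, together with 5' anchoring, qualifies a hit as a
#'   remnant (the "5' half remains" geometry).
#' @param adjacent_max Maximum distance (nt) between the ORF stop codon
#'   and the tRNA start for an ADJACENT call; larger gaps are SPACED.
#' @param partial_min_ext Minimum number of reference positions the
#'   alignment must cover 3' of the stop codon for a PARTIAL call: the
#'   stop must lie in the middle of the tRNA, not in the few noisy tail
#'   columns a local alignment can accrete past a remnant/stop junction.
#' @param promoter_max_mismatch,promoter_spacer Promoter-scan settings,
#'   passed to [find_promoter()].
#' @param promoter_margin Half-width (nt) of the region around the ORF
#'   stop codon scanned for a promoter on reverse/adjacent calls.
#' @return Named list of thresholds for [classify_locus()].
#' @export
classify_config <- function(complete_cov = 0.95, remnant_cov_lo = 0.30,
                            remnant_cov_hi = 0.70, adjacent_max = 30,
                            partial_min_ext = 12,
                            promoter_max_mismatch = 4,
                            promoter_spacer = 15:19,
                            promoter_margin = 40) {
  list(complete_cov = complete_cov, remnant_cov_lo = remnant_cov_lo,
       remnant_cov_hi = remnant_cov_hi, adjacent_max = adjacent_max,
       partial_min_ext = partial_min_ext,
       promoter_max_mismatch = promoter_max_mismatch,
       promoter_spacer = promoter_spacer, promoter_margin = promoter_margin)
}

#' Classify one ORF / tRNA-hit constellation into a locus archetype
#'
#' Applies a total, first-match-wins decision procedure to the best hit
#' (highest alignment score):
#' \enumerate{
#'   \item coverage >= `complete_cov` and hit span inside the coding span
#'     (stop codon excluded) -> `COMPLETE_FORWARD` / `COMPLETE_REVERSE`
#'     by hit strand;
#'   \item the ORF stop codon intersects a forward hit span ->
#'     `PARTIAL_FORWARD`, with the stop position mapped into tRNA
#'     coordinates;
#'   \item a 5'-anchored hit covering `[lo, hi)` of the reference that
#'     starts inside the coding span (tolerating up to `partial_min_ext`
#'     alignment-tail positions past it) -> `REMNANT_FORWARD`;
#'   \item hit starting within `adjacent_max` nt after the stop codon ->
#'     `ADJACENT`;
#'   \item hit starting further downstream -> `SPACED`;
#'   \item otherwise `NONE`.
#' }
#' Coordinates are interpreted in an ORF-forward frame of reference: the
#' ORF must lie on the `'+'` strand of the supplied coordinate system
#' ([scan_genome()] guarantees this by extracting windows in ORF
#' orientation). Stop-start coupling against `downstream` is computed when
#' present; a sigma-70 promoter scan around the stop codon is run for
#' reverse and adjacent calls.
#'
#' @param orf One-row tibble with at least `seq_id`, `start`, `end`
#'   (0-based half-open, span includes the stop codon), `strand` `'+'`.
#' @param hits [locate_trna()] output for the window around `orf`, in the
#'   same coordinates.
#' @param refs Reference tibble ([reference_set()]).
#' @param downstream Optional one-row ORF tibble for the nearest
#'   downstream ORF (same coordinates).
#' @param residues The window/sequence residues the coordinates refer to
#'   (needed for the promoter scan); may be `NULL` to skip it.
#' @param cfg Thresholds from [classify_config()].
#' @return A list of class `overlap_call`: `orf`, `hit` (best hit row or
#'   `NULL`), `archetype`, `features`, `stop_in_trna` (+ `stop_gapped`),
#'   `coupling`, `promoter` (best promoter hit row or `NULL`).
#' @export
classify_locus <- function(orf, hits, refs, downstream = NULL,
                           residues = NULL, cfg = classify_config()) {
  stopifnot(identical(orf$strand, "+"))
  call <- list(orf = orf, hit = NULL, archetype = "NONE", features = NULL,
               stop_in_trna = NA_integer_, stop_gapped = FALSE,
               coupling = NULL, promoter = NULL)
  class(call) <- "overlap_call"
  if (!is.null(downstream)) {
    call$coupling <- detect_stop_start_coupling(orf, downstream)
  }
  if (nrow(hits) == 0) return(call)
  if (any(hits$seq_id != orf$seq_id)) {
    stop("hits refer to a different sequence than the ORF")
  }
  best <- hits[1, ]
  ref <- refs[refs$id == best$ref_id, ]
  feats <- trna_features(best, ref)
  call$hit <- best
  call$features <- feats
  coding <- c(orf$start, orf$end - 3)
  stop_iv <- c(orf$end - 3, orf$end)
  contained <- best$start >= coding[1] && best$end <= coding[2]
  stop_hits_trna <- min(stop_iv[2], best$end) > max(stop_iv[1], best$start)
  gap <- best$start - orf$end
  sp <- if (best$strand == "+" && stop_hits_trna) {
    stop_position_in_trna(orf, best)
  } else list(pos = NA_integer_, gapped = FALSE)
  is_partial <- !is.na(sp$pos) &&
    best$ref_cov_end - sp$pos >= cfg$partial_min_ext
  if (feats$coverage_fraction >= cfg$complete_cov && contained) {
    call$archetype <- if (best$strand == "+") "COMPLETE_FORWARD" else "COMPLETE_REVERSE"
  } else if (is_partial) {
    call$archetype <- "PARTIAL_FORWARD"
    call$stop_in_trna <- sp$pos
    call$stop_gapped <- sp$gapped
  } else if (feats$five_prime_anchored &&
             feats$coverage_fraction >= cfg$remnant_cov_lo &&
             feats$coverage_fraction < cfg$remnant_cov_hi &&
             best$start >= coding[1] && best$start < coding[2] &&
             best$end <= coding[2] + cfg$partial_min_ext) {
    call$archetype <- "REMNANT_FORWARD"
  } else if (gap >= 0 && gap <= cfg$adjacent_max) {
    call$archetype <- "ADJACENT"
  } else if (gap > cfg$adjacent_max) {
    call$archetype <- "SPACED"
  }
  if (!is.null(residues) &&
      (call$archetype == "ADJACENT" || call$archetype == "COMPLETE_REVERSE" ||
       (call$archetype != "NONE" && best$strand == "-"))) {
    lo <- max(0, stop_iv[1] - cfg$promoter_margin)
    hi <- min(nchar(residues), stop_iv[2] + cfg$promoter_margin)
    region <- substr(residues, lo + 1, hi)
    if (nchar(region) >= 29) {
      prom <- find_promoter(region, spacer_range = cfg$promoter_spacer,
                            max_mismatch = cfg$promoter_max_mismatch)
      if (nrow(prom) > 0) {
        prom <- prom[1, ]
        prom$m35_start <- prom$m35_start + lo
        prom$m10_start <- prom$m10_start + lo
        call$promoter <- prom
      }
    }
  }
  call
}

#' Map the ORF stop codon into 1-based tRNA reference coordinates
#'
#' Takes the position of the first base of the ORF's stop codon and
#' transfers it through the hit's alignment pair map onto the reference.
#' If that base falls in an alignment gap (no matched column), the nearest
#' aligned position is reported with `gapped = TRUE`; if it lies outside
#' the aligned reference interval the position is absent (`NA`).
#'
#' @param orf,hit As in [classify_locus()]; the hit must be on the `'+'`
#'   strand relative to the ORF.
#' @return List with `pos` (1-based reference coordinate or `NA`) and
#'   `gapped`.
#' @export
stop_position_in_trna <- function(orf, hit) {
  stopifnot(hit$strand == "+")
  pm <- hit$alignment[[1]]$aln$pair_map
  stop_first <- orf$end - 3 + 1   # 1-based target position
  if (nrow(pm) == 0 || stop_first < min(pm[, "tgt"]) ||
      stop_first > max(pm[, "tgt"])) {
    return(list(pos = NA_integer_, gapped = FALSE))
  }
  k <- match(stop_first, pm[, "tgt"])
  if (!is.na(k)) {
    return(list(pos = as.integer(pm[k, "ref"]), gapped = FALSE))
  }
  nearest <- which.min(abs(pm[, "tgt"] - stop_first))
  list(pos = as.integer(pm[nearest, "ref"]), gapped = TRUE)
}

#' Scan for sigma-70-like promoter box pairs
#'
#' Enumerates every placement of a -35 box (consensus `TTGACA`) and a -10
#' box (consensus `TATAAT`) separated by a spacer in `spacer_range`, and
#' reports the pairs whose total mismatch count against the two consensus
#' boxes is at most `max_mismatch`.
#'
#' @param s Nucleotide string, at least 29 nt
#'   (6 + min spacer + 6 with the default spacer range).
#' @param spacer_range Allowed spacer lengths (nt) between the boxes.
#' @param max_mismatch Maximum total mismatches over both boxes.
#' @return Tibble with `m35_start`, `m35`, `m10_start`, `m10` (starts
#'   0-based), `spacer`, `mismatches`, sorted by ascending mismatches then
#'   position.
#' @export
find_promoter <- function(s, spacer_range = 15:19, max_mismatch = 4) {
  n <- nchar(s)
  rows <- list()
  if (n >= 12 + min(spacer_range)) {
    for (i in seq_len(n)) {
      if (i + 5 > n) break
      m35 <- substr(s, i, i + 5)
      mm35 <- hamming(m35, "TTGACA")
      if (mm35 > max_mismatch) next
      for (sp in spacer_range) {
        j <- i + 6 + sp
        if (j + 5 > n) next
        m10 <- substr(s, j, j + 5)
        mm <- mm35 + hamming(m10, "TATAAT")
        if (mm > max_mismatch) next
        rows[[length(rows) + 1]] <- tibble(
          m35_start = i - 1L, m35 = m35, m10_start = j - 1L, m10 = m10,
          spacer = as.integer(sp), mismatches = as.integer(mm))
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(m35_start = integer(), m35 = character(),
                  m10_start = integer(), m10 = character(),
                  spacer = integer(), mismatches = integer()))
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$mismatches, .data$m35_start, .data$spacer)
}

hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}
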