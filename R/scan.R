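#' Full scan configuration
#'
#' Collects every tunable of the pipeline in one place. Unknown keys are
#' rejected.
#'
#' @param min_orf_len Minimum ORF length (nt) for the genome scan.
#' @param start_codons Permitted initiator codons.
#' @param search [trna_search_config()] thresholds.
#' @param classify [classify_config()] thresholds.
#' @param report_all Keep NONE-archetype ORFs in the output (suppressed by
#'   default so genome-scale reports list positive loci only).
#' @param ... Rejected; catches misspelled keys.
#' @return Named list used by [scan_genome()].
#' @export
scan_config <- function(min_orf_len = 300,
                        start_codons = c("ATG", "GTG", "TTG"),
                        search = trna_search_config(),
                        classify = classify_config(),
                        report_all = FALSE, ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    stop("unknown scan_config keys: ", paste(names(extra), collapse = ", "))
  }
  list(min_orf_len = min_orf_len, start_codons = start_codons,
       search = search, classify = classify, report_all = report_all)
}

read_refs_fasta <- function(path) {
  seqs <- read_fasta(path)
  variant <- sub(".*variant=(\\S+).*", "\\1", seqs$description)
  bad <- !variant %in% TRNA_VARIANTS
  if (any(bad)) variant[bad] <- "complete"
  tibble(id = seqs$id, residues = seqs$residues, variant = variant,
         has_cca = variant != "cca_less",
         discriminator = ifelse(variant == "complete_A73", "A", "G"),
         length = nchar(seqs$residues))
}

#' Scan a genome for selB-nested tRNA-Sec loci
#'
#' The end-to-end procedure: locate ORFs on both strands, search each
#' ORF's flanked window for reference tRNA-Sec hits on both strands,
#' classify every ORF into a locus archetype against its nearest
#' downstream ORF, and compute tRNA gene features, C-terminal extension
#' signatures and (for reverse/adjacent loci) sigma-70 promoter hits.
#'
#' @param input Path to a FASTA file, or a sequence tibble from
#'   [read_fasta()].
#' @param refs Reference tibble ([reference_set()]) or path to a reference
#'   FASTA whose descriptions carry `variant=` tags.
#' @param cfg [scan_config()].
#' @param outdir Optional output directory; when given, writes
#'   `calls.gff3`, `report.tsv` and `conservation.tsv` there.
#' @return A tibble of calls (one row per reported ORF) with genome
#'   coordinates (0-based half-open), archetype, tRNA features, coupling,
#'   extension-signature summary columns, and list-columns `call` /
#'   `signature` holding the full objects. The ids of all scanned
#'   sequences are attached as attribute `seq_ids`.
#' @export
scan_genome <- function(input, refs, cfg = scan_config(), outdir = NULL) {
  seqs <- if (is.character(input)) read_fasta(input) else input
  if (is.character(refs)) refs <- read_refs_fasta(refs)
  rows <- list()
  for (s in seq_len(nrow(seqs))) {
    seq_id <- seqs$id[s]
    residues <- seqs$residues[s]
    L <- nchar(residues)
    orfs <- find_orfs(seq_id, residues, min_len = cfg$min_orf_len,
                      start_codons = cfg$start_codons)
    for (o in seq_len(nrow(orfs))) {
      orf <- orfs[o, ]
      flank <- cfg$search$flank
      win_lo <- max(0, orf$start - flank)
      win_hi <- min(L, orf$end + flank)
      wres <- substr(residues, win_lo + 1, win_hi)
      if (orf$strand == "-") wres <- reverse_complement(wres)
      to_w <- function(g_start, g_end) {
        if (orf$strand == "+") c(g_start - win_lo, g_end - win_lo)
        else c(win_hi - g_end, win_hi - g_start)
      }
      to_g <- function(w_start, w_end) {
        if (orf$strand == "+") c(win_lo + w_start, win_lo + w_end)
        else c(win_hi - w_end, win_hi - w_start)
      }
      ow <- to_w(orf$start, orf$end)
      orf_w <- tibble(seq_id = seq_id, start = ow[1], end = ow[2],
                      strand = "+")
      ds <- nearest_downstream_orf(orf, orfs)
      ds_w <- NULL
      if (!is.null(ds)) {
        dw <- to_w(ds$start, ds$end)
        ds_w <- tibble(seq_id = seq_id, start = dw[1], end = dw[2],
                       strand = "+")
      }
      hits <- locate_trna(list(id = seq_id, residues = wres), refs,
                          both_strands = TRUE, cfg = cfg$search)
      call <- classify_locus(orf_w, hits, refs, downstream = ds_w,
                             residues = wres, cfg = cfg$classify)
      if (call$archetype == "NONE" && !cfg$report_all) next
      sig <- NULL
      if (call$archetype %in% c("COMPLETE_FORWARD", "COMPLETE_REVERSE",
                                "PARTIAL_FORWARD", "REMNANT_FORWARD")) {
        sig <- extension_signature(call, wres)
      }
      hit <- call$hit
      if (!is.null(hit)) {
        tg <- to_g(hit$start, hit$end)
      }
      feats <- call$features
      rows[[length(rows) + 1]] <- tibble(
        seq_id = seq_id,
        orf_start = orf$start, orf_end = orf$end, orf_strand = orf$strand,
        trna_start = if (is.null(hit)) NA_integer_ else as.integer(tg[1]),
        trna_end = if (is.null(hit)) NA_integer_ else as.integer(tg[2]),
        trna_strand = if (is.null(hit)) NA_character_ else
          genome_strand(orf$strand, hit$strand),
        ref_id = if (is.null(hit)) NA_character_ else hit$ref_id,
        archetype = call$archetype,
        identity = if (is.null(hit)) NA_real_ else hit$identity,
        coverage_fraction = if (is.null(feats)) NA_real_ else feats$coverage_fraction,
        gene_length = if (is.null(feats)) NA_integer_ else feats$gene_length,
        has_cca = if (is.null(feats)) NA else feats$has_cca,
        discriminator = if (is.null(feats)) NA_character_ else feats$discriminator,
        stop_in_trna = call$stop_in_trna,
        coupling_overlap = if (is.null(call$coupling)) NA_integer_ else
          call$coupling$overlap_len,
        coupling_spacer = if (is.null(call$coupling)) NA_integer_ else
          call$coupling$spacer,
        ext_first = if (is.null(sig)) NA_character_ else sig$first_aa,
        ext_last = if (is.null(sig)) NA_character_ else sig$last_aa,
        ext_len_nt = if (is.null(sig)) NA_integer_ else sig$length_nt,
        ext_mult3 = if (is.null(sig)) NA else sig$multiple_of_3,
        promoter_mismatches = if (is.null(call$promoter)) NA_integer_ else
          call$promoter$mismatches,
        call = list(call), signature = list(sig))
    }
  }
  calls <- if (length(rows) == 0) empty_calls() else dplyr::bind_rows(rows)
  calls <- dplyr::arrange(calls, .data$seq_id, .data$orf_start)
  attr(calls, "seq_ids") <- seqs$id
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_gff3(calls, file.path(outdir, "calls.gff3"))
    write_report_tsv(calls, file.path(outdir, "report.tsv"))
    prof <- profile_extensions(calls$signature)
    write_conservation_tsv(prof, file.path(outdir, "conservation.tsv"))
  }
  calls
}

empty_calls <- function() {
  tibble(seq_id = character(), orf_start = integer(), orf_end = integer(),
         orf_strand = character(), trna_start = integer(),
         trna_end = integer(), trna_strand = character(),
         ref_id = character(), archetype = character(),
         identity = numeric(), coverage_fraction = numeric(),
         gene_length = integer(), has_cca = logical(),
         discriminator = character(), stop_in_trna = integer(),
         coupling_overlap = integer(), coupling_spacer = integer(),
         ext_first = character(), ext_last = character(),
         ext_len_nt = integer(), ext_mult3 = logical(),
         promoter_mismatches = integer(), call = list(), signature = list())
}

reciprocal_overlap <- function(a_start, a_end, b_start, b_end) {
  ov <- max(0, min(a_end, b_end) - max(a_start, b_start))
  if (ov == 0) return(0)
  min(ov / (a_end - a_start), ov / (b_end - b_start))
}

#' Evaluate calls against synthetic ground truth
#'
#' A call matches a truth locus when they are on the same sequence and
#' tRNA strand, the tRNA spans overlap at least 50% reciprocally, and the
#' archetypes agree. Sensitivity is reported per truth archetype;
#' precision is the fraction of calls matching some truth locus; the
#' confusion table assigns each truth locus the archetype of its best
#' span-overlapping call (or `MISSED`).
#'
#' @param calls Calls tibble from [scan_genome()].
#' @param truth Truth tibble from [generate_dataset()] (or the path to a
#'   written `truth.tsv`).
#' @param min_overlap Minimum reciprocal span overlap.
#' @return List with `sensitivity` (tibble: archetype, n_truth, n_matched,
#'   sensitivity), `precision`, `confusion` (tibble of truth vs called
#'   archetype counts; one row per truth locus aggregated), and
#'   `mean_sensitivity` (mean of per-locus indicator).
#' @export
evaluate_calls <- function(calls, truth, min_overlap = 0.5) {
  if (is.character(truth)) {
    truth <- as_tibble(utils::read.table(truth, sep = "\t", header = TRUE,
                                         stringsAsFactors = FALSE))
  }
  seq_ids <- attr(calls, "seq_ids")
  if (!is.null(seq_ids)) {
    unknown <- setdiff(unique(truth$seq_id), seq_ids)
    if (length(unknown) > 0) {
      stop("truth references sequences absent from the scan: ",
           paste(unknown, collapse = ", "))
    }
  }
  n_t <- nrow(truth)
  matched <- logical(n_t)
  called_as <- rep("MISSED", n_t)
  call_matched <- if (nrow(calls) > 0) logical(nrow(calls)) else logical(0)
  for (i in seq_len(n_t)) {
    tr <- truth[i, ]
    best_ov <- 0
    for (j in seq_len(nrow(calls))) {
      cl <- calls[j, ]
      if (cl$seq_id != tr$seq_id || is.na(cl$trna_start)) next
      ov <- reciprocal_overlap(cl$trna_start, cl$trna_end,
                               tr$trna_start, tr$trna_end)
      if (ov < min_overlap) next
      if (ov > best_ov) {
        best_ov <- ov
        called_as[i] <- cl$archetype
      }
      if (cl$archetype == tr$archetype && cl$trna_strand == tr$trna_strand) {
        matched[i] <- TRUE
        call_matched[j] <- TRUE
      }
    }
  }
  sens <- dplyr::summarise(
    dplyr::group_by(tibble(archetype = truth$archetype, matched = matched),
                    .data$archetype),
    n_truth = dplyr::n(), n_matched = sum(.data$matched),
    sensitivity = mean(.data$matched), .groups = "drop")
  confusion <- dplyr::count(
    tibble(truth_archetype = truth$archetype, called_archetype = called_as),
    .data$truth_archetype, .data$called_archetype, name = "n")
  precision <- if (nrow(calls) == 0) NA_real_ else mean(call_matched)
  list(sensitivity = sens, precision = precision, confusion = confusion,
       mean_sensitivity = mean(matched))
}
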