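#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

IUPAC_NT <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N")

#' Read nucleotide sequences from a FASTA file
#'
#' Reads a (multi-record) FASTA file into a tibble of normalized nucleotide
#' records. Residues are upper-cased and RNA `U` is converted to DNA `T`,
#' so downstream code works on the `{A,C,G,T}` alphabet throughout. IUPAC
#' ambiguity codes (`N`, `R`, `Y`, ...) are retained unchanged; records
#' containing any are flagged in their `description`.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `residues`, one row
#'   per record, in file order. An empty file yields a zero-row tibble.
#' @details Characters outside the IUPAC nucleotide set, and records with
#'   empty or duplicated identifiers, raise an error naming the offending
#'   line of the input file.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  out <- tibble(id = character(), description = character(),
                residues = character())
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) return(out)
  is_header <- startsWith(lines, ">")
  if (!is_header[[nonblank[1]]]) {
    stop("malformed FASTA: first non-blank line is not a header (line ",
         nonblank[1], ")")
  }
  rec_idx <- cumsum(is_header)
  headers <- lines[is_header]
  header_lines <- which(is_header)
  ids <- sub("^>\\s*(\\S*).*$", "\\1", headers)
  descs <- trimws(sub("^>\\s*\\S*\\s*", "", headers))
  if (any(!nzchar(ids))) {
    stop("malformed FASTA header: empty id (line ",
         header_lines[which(!nzchar(ids))[1]], ")")
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("duplicate FASTA id '", dup, "' (line ",
         header_lines[which(ids == dup)[2]], ")")
  }
  body <- !is_header & nzchar(trimws(lines))
  seq_lines <- toupper(chartr("u", "U", lines))
  seq_lines <- chartr("U", "T", seq_lines)
  bad <- body & grepl(paste0("[^", paste(IUPAC_NT, collapse = ""), "]"),
                      gsub("\\s", "", seq_lines))
  if (any(bad)) {
    ln <- which(bad)[1]
    ch <- regmatches(seq_lines[ln],
                     regexpr(paste0("[^", paste(IUPAC_NT, collapse = ""), " ]"),
                             seq_lines[ln]))
    stop("illegal nucleotide character '", ch, "' (line ", ln, ")")
  }
  residues <- vapply(seq_along(ids), function(i) {
    paste(gsub("\\s", "", seq_lines[body & rec_idx == i]), collapse = "")
  }, character(1))
  ambig <- grepl("[^ACGT]", residues)
  descs[ambig] <- trimws(paste(descs[ambig], "[contains ambiguity codes]"))
  tibble(id = ids, description = descs, residues = residues)
}

#' Write nucleotide records to a FASTA file
#'
#' @param seqs Tibble with columns `id`, `residues` and optionally
#'   `description` (as returned by [read_fasta()]).
#' @param path Output path.
#' @param width Line width for wrapping residues.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  desc <- if ("description" %in% names(seqs)) seqs$description else ""
  for (i in seq_len(nrow(seqs))) {
    hdr <- if (nzchar(desc[i] %||% "")) paste(seqs$id[i], desc[i]) else seqs$id[i]
    writeLines(paste0(">", hdr), con)
    s <- seqs$residues[i]
    if (nchar(s) > 0) {
      starts <- seq(1, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
    }
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Reverse complement of a nucleotide string
#'
#' Complements `{A,C,G,T}` (and all IUPAC ambiguity codes; `N` maps to `N`)
#' and reverses the result. The empty string maps to itself.
#'
#' @param s A nucleotide string over the IUPAC alphabet.
#' @return The reverse-complement string.
#' @export
reverse_complement <- function(s) {
  stopifnot(is.character(s), length(s) == 1)
  if (grepl("[^ACGTRYSWKMBDHVN]", s)) {
    stop("illegal character in nucleotide string")
  }
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Conceptual translation of a nucleotide string
#'
#' Translates codon-by-codon under the standard bacterial genetic code
#' (translation table 11; identical amino-acid assignments to the standard
#' code). Translation stops at the first stop codon, which is rendered as a
#' terminal `'*'`. A trailing incomplete codon is dropped. A codon holding
#' an ambiguity code is translated when every resolution agrees (e.g.
#' `CCN` -> `P`), otherwise it yields `X`.
#'
#' @param nt Nucleotide string over the IUPAC alphabet.
#' @param frame_offset Integer 0..2; number of 5' bases skipped before the
#'   first codon.
#' @param as_start If `TRUE`, the first codon is treated as an annotated
#'   initiator: `ATG`/`GTG`/`TTG` all render as `M` (bacterial convention).
#' @param run_to_stop If `FALSE`, stop codons are emitted as `'*'` without
#'   terminating translation (used for frame diagnostics).
#' @return A single string over the 20 amino-acid letters plus `'*'`/`X`.
#' @export
translate_nt <- function(nt, frame_offset = 0, as_start = FALSE,
                         run_to_stop = TRUE) {
  stopifnot(frame_offset %in% 0:2)
  if (grepl("[^ACGTRYSWKMBDHVN]", nt)) stop("illegal character in nucleotide string")
  n <- nchar(nt) - frame_offset
  if (n < 3) return("")
  starts <- seq(frame_offset + 1, frame_offset + n - 2, by = 3)
  codons <- substring(nt, starts, starts + 2)
  aas <- vapply(codons, codon_aa, character(1), USE.NAMES = FALSE)
  if (as_start && length(aas) > 0 && codons[1] %in% c("ATG", "GTG", "TTG")) {
    aas[1] <- "M"
  }
  if (run_to_stop) {
    st <- which(aas == "*")
    if (length(st) > 0) aas <- aas[seq_len(st[1])]
  }
  paste(aas, collapse = "")
}

# amino acid for one codon, resolving IUPAC ambiguity when unambiguous
codon_aa <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  if (!grepl("[^ACGT]", codon)) return(unname(gc[[codon]]))
  bases <- strsplit(codon, "", fixed = TRUE)[[1]]
  opts <- lapply(bases, function(b) {
    strsplit(Biostrings::IUPAC_CODE_MAP[[b]], "", fixed = TRUE)[[1]]
  })
  combos <- expand.grid(opts, stringsAsFactors = FALSE)
  aas <- unique(gc[apply(combos, 1, paste, collapse = "")])
  if (length(aas) == 1) unname(aas) else "X"
}

# percent-encode GFF3 attribute values
gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  gsub("\t", "%09", x, fixed = TRUE)
}

#' Write overlap calls as GFF3
#'
#' Each call is emitted as one `tRNA` feature over the tRNA hit span
#' (genome strand), with `archetype`, `identity` and (for partial overlaps)
#' `stop_in_trna` attributes. Internal 0-based half-open coordinates are
#' converted to the 1-based inclusive GFF3 convention; attribute values are
#' percent-encoded.
#'
#' @param calls A calls tibble as returned by [scan_genome()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    if (is.na(cl$trna_start)) next
    strand <- genome_strand(cl$orf_strand, cl$trna_strand)
    attrs <- c(
      ID = sprintf("call%d", i),
      archetype = cl$archetype,
      identity = sprintf("%.4f", cl$identity),
      orf_span = sprintf("%d-%d", cl$orf_start + 1, cl$orf_end)
    )
    if (!is.na(cl$stop_in_trna)) attrs <- c(attrs, stop_in_trna = cl$stop_in_trna)
    attr_s <- paste(paste0(names(attrs), "=", gff3_escape(as.character(attrs))),
                    collapse = ";")
    writeLines(paste(cl$seq_id, "selnest", "tRNA",
                     cl$trna_start + 1, cl$trna_end, ".", strand, ".",
                     attr_s, sep = "\t"), con)
  }
  invisible(path)
}

# strand of the tRNA on the genome, given ORF strand and hit strand
# (hit strand is recorded relative to the ORF strand)
genome_strand <- function(orf_strand, hit_strand) {
  ifelse(orf_strand == hit_strand, "+", "-")
}

REPORT_COLUMNS <- c("seq_id", "orf_start", "orf_end", "orf_strand",
                    "trna_start", "trna_end", "trna_strand", "ref_id",
                    "archetype", "identity", "coverage_fraction",
                    "gene_length", "has_cca", "discriminator",
                    "stop_in_trna", "coupling_overlap", "coupling_spacer",
                    "ext_first", "ext_last", "ext_len_nt", "ext_mult3")

#' Write the per-call report as TSV
#'
#' One row per call in a fixed, documented column order; the header line is
#' prefixed with `#`. [read_report_tsv()] round-trips the file.
#'
#' @param calls A calls tibble as returned by [scan_genome()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report_tsv <- function(calls, path) {
  df <- as.data.frame(calls)[, intersect(REPORT_COLUMNS, names(calls)), drop = FALSE]
  for (col in setdiff(REPORT_COLUMNS, names(df))) df[[col]] <- NA
  df <- df[, REPORT_COLUMNS, drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(REPORT_COLUMNS, collapse = "\t")), con)
  if (nrow(df) > 0) {
    rows <- apply(df, 1, function(r) paste(ifelse(is.na(r), "NA", trimws(r)),
                                           collapse = "\t"))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a per-call TSV report written by [write_report_tsv()]
#'
#' @param path Path to the report.
#' @return A tibble with the documented report columns.
#' @export
read_report_tsv <- function(path) {
  first <- readLines(path, n = 1)
  cols <- strsplit(sub("^#", "", first), "\t", fixed = TRUE)[[1]]
  df <- utils::read.table(path, sep = "\t", header = FALSE, skip = 1,
                          col.names = cols, stringsAsFactors = FALSE,
                          na.strings = "NA",
                          colClasses = NA, comment.char = "")
  for (col in c("orf_start", "orf_end", "trna_start", "trna_end",
                "gene_length", "stop_in_trna", "coupling_overlap",
                "coupling_spacer", "ext_len_nt")) {
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
  }
  for (col in c("identity", "coverage_fraction")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  for (col in c("has_cca", "ext_mult3")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  as_tibble(df)
}
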