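TRNA_VARIANTS <- c("complete", "cca_less", "u66_del", "complete_A73")

# Eight in-frame codons, none a stop, that place a stop codon in every
# reading frame other than the host ORF's own: "TCA" at offsets 0/4/8
# yields reverse-strand TGA in all three frames, "ATGAAT" a forward TGA at
# offset +1, "ACTAAC" a forward TAA at offset +2. Interspersed in ORF
# filler it bounds off-frame/antisense open runs well below the genome-scan
# ORF length floor.
ORF_GUARD <- "TCAATCAATCAAATGAATACTAAC"

# Self-reverse-complementary 12-mer with TAA stops in all six frames; used
# to punctuate intergenic background.
BG_TERMINATOR <- "TTAATTAATTAA"

SELC_PROMOTER_EXAMPLE <- "TTGATTCAGGTTTACACATTTTCTACTATC"

LOCUS_TEMPLATES <- c("complete_forward", "adjacent_forward", "spaced",
                     "remnant_forward", "partial_forward",
                     "complete_reverse", "adjacent_reverse")

DEFAULT_TEMPLATE_VARIANTS <- c(
  complete_forward = "complete", adjacent_forward = "complete_A73",
  spaced = "complete", remnant_forward = "complete",
  partial_forward = "complete",
  complete_reverse = "u66_del",   # 95 nt: length 2 mod 3 puts the Trp and
                                  # Pro codons of the reverse extension in
                                  # one reading frame
  adjacent_reverse = "complete")

TEMPLATE_ARCHETYPE <- c(
  complete_forward = "COMPLETE_FORWARD", adjacent_forward = "ADJACENT",
  spaced = "SPACED", remnant_forward = "REMNANT_FORWARD",
  partial_forward = "PARTIAL_FORWARD", complete_reverse = "COMPLETE_REVERSE",
  adjacent_reverse = "ADJACENT")

rand_bases <- function(n, gc = 0.6) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# n random sense codons, none a stop
rand_codons <- function(n, gc = 0.6) {
  if (n <= 0) return("")
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      cd <- rand_bases(3, gc)
      if (!(cd %in% STOP_CODONS)) break
    }
    out[i] <- cd
  }
  paste(out, collapse = "")
}

# ORF filler: blocks of up to `block` random codons, each followed by the
# off-frame guard, so no non-host frame stays open across a block
orf_filler <- function(n_codons, gc = 0.6, block = 10) {
  pieces <- character(0)
  left <- n_codons
  while (left > 0) {
    k <- min(block, left)
    pieces <- c(pieces, rand_codons(k, gc), ORF_GUARD)
    left <- left - k
  }
  paste(pieces, collapse = "")
}

# intergenic background: terminator-punctuated random sequence of length n
background <- function(n, gc = 0.6) {
  pieces <- character(0)
  len <- 0
  while (len < n) {
    pieces <- c(pieces, BG_TERMINATOR, rand_bases(58, gc))
    len <- len + 12 + 58
  }
  substr(paste(pieces, collapse = ""), 1, n)
}

#' Construct a reference tRNA-Sec gene sequence
#'
#' Builds a random sequence satisfying the positional constraints of the
#' tRNA-Sec gene variants: the `complete` variant is 96 nt, starts `GGA`,
#' ends with the encoded `CCA` tail preceded by discriminator `G` (and a
#' `CC` acceptor-side motif, so that CCA-less derivatives still end in a
#' Pro-encoding `CCN` triplet). Derived variants are single edits of the
#' complete sequence: `cca_less` drops the terminal CCA (93 nt),
#' `u66_del` deletes the base at reference position 66 (95 nt),
#' `complete_A73` substitutes the discriminator G for A. Sequences shown
#' only graphically in the source literature are not machine-readable, so
#' the reference set is synthetic; all downstream assertions are
#' positional/compositional, not sequence-specific.
#'
#' The random interior is rejection-sampled so that (i) no variant carries
#' an internal stop codon in the reading frame its in-ORF plant is
#' translated in (forward plants for complete/cca_less/u66_del, the
#' reverse-complement frame for the 95-nt variant) and (ii) no start codon
#' opens the translationally coupled downstream frame inside the gene.
#'
#' @param variant One of `"complete"`, `"cca_less"`, `"u66_del"`,
#'   `"complete_A73"`.
#' @param seed Integer seed fixing the sequence.
#' @param gc GC fraction of the random interior.
#' @return One-row tibble: `id`, `residues`, `variant`, `has_cca`,
#'   `discriminator`, `length`.
#' @export
make_reference_trna <- function(variant = "complete", seed = 1, gc = 0.6) {
  variant <- match.arg(variant, TRNA_VARIANTS)
  refs <- reference_set(seed = seed, gc = gc)
  refs[refs$variant == variant, ]
}

#' The full synthetic reference set (all four variants from one seed)
#'
#' @inheritParams make_reference_trna
#' @return Tibble with one row per variant; see [make_reference_trna()].
#' @export
reference_set <- function(seed = 1, gc = 0.6) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  complete <- NULL
  for (i in 1:5000) {
    cand <- paste0("GGA", rand_bases(87, gc), "CCGCCA")
    if (reference_ok(cand)) { complete <- cand; break }
  }
  if (is.null(complete)) stop("could not build a reference satisfying the frame constraints")
  u66 <- paste0(substr(complete, 1, 65), substr(complete, 67, 96))
  tibble(
    id = paste0("trnaSec_", TRNA_VARIANTS),
    residues = c(complete, substr(complete, 1, 93), u66,
                 paste0(substr(complete, 1, 92), "A", "CCA")),
    variant = TRNA_VARIANTS,
    has_cca = c(TRUE, FALSE, TRUE, TRUE),
    discriminator = c("G", "G", "G", "A"),
    length = c(96L, 93L, 95L, 96L))
}

codons_of <- function(s, offset = 0) {
  n <- nchar(s) - offset
  if (n < 3) return(character(0))
  starts <- seq(offset + 1, offset + n - (n %% 3) - 2, by = 3)
  substring(s, starts, starts + 2)
}

reference_ok <- function(complete, start_codons = c("ATG", "GTG", "TTG")) {
  u66 <- paste0(substr(complete, 1, 65), substr(complete, 67, 96))
  # no internal stop in any translated plant frame
  if (any(codons_of(complete) %in% STOP_CODONS)) return(FALSE)
  if (any(codons_of(u66) %in% STOP_CODONS)) return(FALSE)
  if (any(codons_of(reverse_complement(u66)) %in% STOP_CODONS)) return(FALSE)
  # no start codon opening the coupled downstream frame (local offset 2)
  if (any(codons_of(complete, 2) %in% start_codons)) return(FALSE)
  if (any(codons_of(u66, 2) %in% start_codons)) return(FALSE)
  TRUE
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# substitution-only point mutations outside the protected positions
mutate_seq <- function(s, rate, protected = integer(0)) {
  if (rate <= 0) return(s)
  bases <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(bases)) < rate)
  hit <- setdiff(hit, protected)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
  }
  paste(bases, collapse = "")
}

#' Simulation configuration
#'
#' @param n_per_archetype Number of loci planted per template.
#' @param templates Locus templates to plant (default: all seven).
#' @param variants Named character vector mapping template -> reference
#'   variant; defaults cover the canonical arrangement of each template.
#' @param gc_fraction Background/filler GC content (rhizobial-like 0.6).
#' @param mut_rate Per-base substitution rate applied to each planted tRNA
#'   copy outside functionally fixed positions (GGA start, encoded CCA
#'   tail, planted stop codons).
#' @param margin Background padding (nt) on each side of a locus.
#' @param seed Integer seed; fixes every random draw, so identical
#'   configurations generate byte-identical output.
#' @return Named list understood by [generate_dataset()].
#' @export
gen_config <- function(n_per_archetype = 1, templates = LOCUS_TEMPLATES,
                       variants = DEFAULT_TEMPLATE_VARIANTS,
                       gc_fraction = 0.6, mut_rate = 0, margin = 300,
                       seed = 1) {
  stopifnot(all(templates %in% LOCUS_TEMPLATES))
  v <- DEFAULT_TEMPLATE_VARIANTS
  v[names(variants)] <- variants
  list(n_per_archetype = n_per_archetype, templates = templates,
       variants = v, gc_fraction = gc_fraction, mut_rate = mut_rate,
       margin = margin, seed = seed)
}

#' Plant one selB-selC locus archetype into background sequence
#'
#' Constructs a selB-like host ORF (random codons, no internal stop, with
#' off-frame guards) and places a copy of the reference tRNA gene per the
#' requested template:
#' \describe{
#'   \item{complete_forward}{tRNA in frame inside the ORF, stop codon
#'     immediately after (padded to frame for the 95-nt variant), and a
#'     downstream ORF whose start codon overlaps the stop by 1 nt
#'     (`TGATG`).}
#'   \item{adjacent_forward}{new stop codon before the tRNA; the tRNA
#'     begins 5 nt after the ORF end.}
#'   \item{spaced}{tRNA separated from the ORF by a 100-nt spacer.}
#'   \item{remnant_forward}{only reference residues 1..48 (the 5' half)
#'     embedded, stop immediately after.}
#'   \item{partial_forward}{full tRNA placed so its residues 46-48 form
#'     the ORF's in-frame TGA stop.}
#'   \item{complete_reverse}{reverse complement of the (95-nt) tRNA in
#'     frame inside the ORF, the Pro-encoding `CCN` triplet completing the
#'     extension, and the example selC promoter string placed after the
#'     stop.}
#'   \item{adjacent_reverse}{reverse complement of the tRNA immediately
#'     after the ORF stop codon.}
#' }
#' Point mutations at `mut_rate` are applied to the planted copy outside
#' the functionally fixed positions. Draws from the current RNG state; use
#' [generate_dataset()] for seeded, reproducible datasets.
#'
#' @param template One of the seven locus templates.
#' @param ref One-row reference tibble ([make_reference_trna()]).
#' @param mut_rate Per-base substitution rate for the planted tRNA copy.
#' @param gc GC fraction of filler/background.
#' @param margin Background padding on each side.
#' @param seq_id Identifier for the generated sequence.
#' @return List with `record` (one-row sequence tibble) and `truth`
#'   (one-row ground-truth tibble).
#' @export
plant_locus <- function(template, ref, mut_rate = 0, gc = 0.6, margin = 300,
                        seq_id = template) {
  template <- match.arg(template, LOCUS_TEMPLATES)
  tlen <- nchar(ref$residues)
  protected <- c(1:3, if (isTRUE(ref$has_cca)) (tlen - 2):tlen)
  if (template == "partial_forward") protected <- c(protected, 46:48)
  trna <- mutate_seq(ref$residues, mut_rate, protected)
  up <- background(margin, gc)
  down <- background(margin, gc)
  head_f <- orf_filler(60, gc)            # 60 codons + guards = 324 nt
  head <- paste0("ATG", head_f)
  coupling <- NA_integer_
  stop_in_trna <- NA_integer_
  strand <- "+"
  if (template %in% c("complete_forward")) {
    dangling <- tlen %% 3
    pad <- if (dangling == 0) "" else rand_bases(3 - dangling, gc)
    # overlap geometry TAATG: the downstream ATG shares the stop codon's
    # final A; TAA (not TGA) so no earlier in-frame start codon can form
    # at the tRNA/stop junction
    ds_body <- paste0(orf_filler(60, gc), "TAA")
    locus <- paste0(head, trna, pad, "TAA", "TG", ds_body)
    t_start <- nchar(up) + nchar(head)
    orf_end <- t_start + tlen + nchar(pad) + 3
    orf_span <- c(nchar(up), orf_end)
    coupling <- 1L
  } else if (template %in% c("adjacent_forward", "spaced")) {
    gap <- if (template == "spaced") 100 else 5
    locus <- paste0(head, "TGA", rand_bases(gap, gc), trna)
    orf_span <- c(nchar(up), nchar(up) + nchar(head) + 3)
    t_start <- orf_span[2] + gap
  } else if (template == "remnant_forward") {
    trna <- substr(trna, 1, 48)
    tlen <- 48L
    locus <- paste0(head, trna, "TGA")
    t_start <- nchar(up) + nchar(head)
    orf_span <- c(nchar(up), t_start + 48 + 3)
  } else if (template == "partial_forward") {
    trna <- paste0(substr(trna, 1, 45), "TGA", substr(trna, 49, tlen))
    locus <- paste0(head, trna)
    t_start <- nchar(up) + nchar(head)
    orf_span <- c(nchar(up), t_start + 48)
    stop_in_trna <- 46L
  } else if (template == "complete_reverse") {
    rc <- reverse_complement(trna)
    locus <- paste0(head, rc, rand_bases(1, gc), "TGA", SELC_PROMOTER_EXAMPLE)
    t_start <- nchar(up) + nchar(head)
    orf_span <- c(nchar(up), t_start + tlen + 1 + 3)
    strand <- "-"
  } else if (template == "adjacent_reverse") {
    rc <- reverse_complement(trna)
    locus <- paste0(head, "TGA", rc)
    orf_span <- c(nchar(up), nchar(up) + nchar(head) + 3)
    t_start <- orf_span[2]
    strand <- "-"
  }
  residues <- paste0(up, locus, down)
  record <- tibble(id = seq_id, description = paste("synthetic", template),
                   residues = residues)
  truth <- tibble(
    seq_id = seq_id, template = template,
    archetype = unname(TEMPLATE_ARCHETYPE[template]),
    trna_start = as.integer(t_start), trna_end = as.integer(t_start + tlen),
    trna_strand = strand,
    orf_start = as.integer(orf_span[1]), orf_end = as.integer(orf_span[2]),
    coupling_overlap_len = coupling, stop_in_trna = stop_in_trna,
    ref_variant = ref$variant, mut_rate = mut_rate)
  list(record = record, truth = truth)
}

#' Generate a synthetic genome dataset with planted loci
#'
#' Produces one sequence per planted locus, a ground-truth table, and the
#' reference set used, all as a pure function of the configuration: the
#' same `cfg` yields byte-identical outputs.
#'
#' @param cfg Configuration from [gen_config()].
#' @param outdir Optional directory; when given, writes `genome.fasta`,
#'   `truth.tsv` and `refs.fasta` there.
#' @return List with `seqs` (sequence tibble), `truth` (truth tibble) and
#'   `refs` (reference tibble).
#' @export
generate_dataset <- function(cfg = gen_config(), outdir = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  refs <- reference_set(seed = cfg$seed, gc = cfg$gc_fraction)
  set.seed(cfg$seed + 1L)
  recs <- list(); truths <- list()
  for (template in cfg$templates) {
    ref <- refs[refs$variant == cfg$variants[[template]], ]
    for (i in seq_len(cfg$n_per_archetype)) {
      planted <- plant_locus(template, ref, mut_rate = cfg$mut_rate,
                             gc = cfg$gc_fraction, margin = cfg$margin,
                             seq_id = sprintf("%s_%02d", template, i))
      recs[[length(recs) + 1]] <- planted$record
      truths[[length(truths) + 1]] <- planted$truth
    }
  }
  seqs <- dplyr::bind_rows(recs)
  truth <- dplyr::bind_rows(truths)
  truth$seed <- cfg$seed
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(seqs, file.path(outdir, "genome.fasta"))
    write_fasta(tibble(id = refs$id,
                       description = paste0("variant=", refs$variant),
                       residues = refs$residues),
                file.path(outdir, "refs.fasta"))
    utils::write.table(truth, file.path(outdir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(seqs = seqs, truth = truth, refs = refs)
}
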