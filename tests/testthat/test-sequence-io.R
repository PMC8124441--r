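test_that("read_fasta parses, normalizes and preserves record order", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1 first record", "ACGT", ">s2", "acgu", "ggnn"), path)
  recs <- read_fasta(path)
  expect_equal(recs$id, c("s1", "s2"))
  expect_equal(recs$residues, c("ACGT", "ACGTGGNN"))
  expect_match(recs$description[2], "ambiguity codes")
  expect_equal(recs$description[1], "first record")
})

test_that("read_fasta handles empty files and rejects malformed input", {
  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_equal(nrow(read_fasta(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGT", ">s2", "AC!T"), bad)
  expect_error(read_fasta(bad), "line 4")

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGT", ">s1", "ACGT"), dup)
  expect_error(read_fasta(dup), "duplicate")
})

test_that("fasta write/read round-trips ids and residues exactly", {
  set.seed(11)
  seqs <- tibble::tibble(
    id = sprintf("rec%d", 1:5),
    description = c("", "with text", "", "x", ""),
    residues = vapply(c(0, 1, 70, 71, 213), random_dna, character(1)))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, path)
  back <- read_fasta(path)
  expect_equal(back$id, seqs$id)
  expect_equal(back$residues, seqs$residues)
})

test_that("reverse_complement maps the CCA end to TGG and is an involution", {
  expect_equal(reverse_complement("CCA"), "TGG")
  expect_equal(reverse_complement(""), "")
  expect_equal(reverse_complement("AANT"), "ANTT")
  expect_error(reverse_complement("ACQ"), "illegal")
  set.seed(7)
  for (i in 1:100) {
    x <- random_dna(sample(1:60, 1))
    expect_equal(reverse_complement(reverse_complement(x)), x)
    # cross-check against an independent implementation
    expect_equal(reverse_complement(x),
                 as.character(Biostrings::reverseComplement(Biostrings::DNAString(x))))
  }
})

test_that("translate_nt follows the bacterial code with stop termination", {
  expect_equal(translate_nt("GGA"), "G")   # extension start, Gly
  expect_equal(translate_nt("CCA"), "P")   # CCA tail, Pro
  expect_equal(translate_nt("TGA"), "*")
  expect_equal(translate_nt("GGATGACCC"), "G*")  # stops terminate
  expect_equal(translate_nt("GGAAA"), "G")       # trailing codon dropped
  expect_equal(translate_nt("AGGA", frame_offset = 1), "G")
  expect_equal(translate_nt("CCN"), "P")   # all resolutions agree
  expect_equal(translate_nt("AAN"), "X")   # ambiguous: AAA/G=K, AAC/T=N
  expect_equal(translate_nt("GTGAAA", as_start = TRUE), "MK")
  expect_equal(translate_nt("GTGAAA"), "VK")
})

test_that("reverse-strand translation equals six-frame brute force", {
  set.seed(21)
  for (i in 1:20) {
    x <- random_dna(sample(6:60, 1))
    rc <- reverse_complement(x)
    for (f in 0:2) {
      starts <- seq(f + 1, nchar(rc) - 2, by = 3)
      starts <- starts[starts + 2 <= nchar(rc)]
      manual <- paste(vapply(starts, function(p) {
        unname(Biostrings::GENETIC_CODE[[substr(rc, p, p + 2)]])
      }, character(1)), collapse = "")
      first_stop <- regexpr("*", manual, fixed = TRUE)
      if (first_stop > 0) manual <- substr(manual, 1, first_stop)
      expect_equal(translate_nt(rc, frame_offset = f), manual)
    }
  }
})

test_that("gff3 output uses 1-based inclusive coordinates and escaping", {
  calls <- tibble::tibble(
    seq_id = c("chr", "chr"), orf_start = c(0L, 500L), orf_end = c(96L, 900L),
    orf_strand = c("+", "+"), trna_start = c(0L, 600L), trna_end = c(96L, 696L),
    trna_strand = c("+", "-"), archetype = c("COMPLETE_FORWARD; test", "ADJACENT"),
    identity = c(1, 1), stop_in_trna = c(NA_integer_, NA_integer_))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(calls, path)
  lines <- readLines(path)
  expect_equal(lines[1], "##gff-version 3")
  f1 <- strsplit(lines[2], "\t")[[1]]
  expect_equal(as.integer(f1[4:5]), c(1L, 96L))
  expect_equal(f1[7], "+")
  expect_match(f1[9], "COMPLETE_FORWARD%3B test", fixed = TRUE)
  f2 <- strsplit(lines[3], "\t")[[1]]
  expect_equal(f2[7], "-")
  expect_true(as.integer(f2[4]) <= as.integer(f2[5]))
})

test_that("report TSV round-trips call fields", {
  ds <- generate_dataset(gen_config(seed = 3))
  calls <- scan_genome(ds$seqs, ds$refs)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report_tsv(calls, path)
  back <- read_report_tsv(path)
  expect_equal(nrow(back), nrow(calls))
  for (col in c("seq_id", "archetype", "trna_start", "trna_end",
                "gene_length", "stop_in_trna", "has_cca", "ext_first",
                "ext_last", "ext_mult3", "coupling_overlap")) {
    expect_equal(back[[col]], calls[[col]], info = col)
  }
  empty_path <- withr::local_tempfile(fileext = ".tsv")
  write_report_tsv(calls[0, ], empty_path)
  expect_equal(length(readLines(empty_path)), 1)  # header only
})
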