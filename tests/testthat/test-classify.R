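# Build a window with the given piece planted at `at`, locate it, and
# classify against the supplied ORF span.
classified <- function(piece, at, orf_start, orf_end, refs,
                       total = NULL, downstream = NULL, gc = 0.6) {
  total <- total %||% (at + nchar(piece) + 200)
  left <- random_dna(at, gc)
  right <- random_dna(total - at - nchar(piece), gc)
  res <- paste0(left, piece, right)
  win <- list(id = "w", residues = res)
  hits <- locate_trna(win, refs)
  classify_locus(orf_row(orf_start, orf_end, seq_id = "w"), hits, refs,
                 downstream = downstream, residues = res)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the decision procedure labels each planted geometry correctly", {
  refs <- reference_set(seed = 5)
  complete <- refs[refs$variant == "complete", ]$residues
  set.seed(51)

  # full-coverage '+' hit inside the coding span -> COMPLETE_FORWARD
  cf <- classified(complete, 100, 40, 100 + 96 + 3, refs)
  expect_equal(cf$archetype, "COMPLETE_FORWARD")

  # full-coverage '-' hit inside the coding span -> COMPLETE_REVERSE
  cr <- classified(reverse_complement(complete), 100, 40, 100 + 96 + 4, refs)
  expect_equal(cr$archetype, "COMPLETE_REVERSE")

  # five-prime-anchored half-reference inside the coding span -> REMNANT
  rm <- classified(substr(complete, 1, 48), 100, 40, 151, refs)
  expect_equal(rm$archetype, "REMNANT_FORWARD")

  # hit starting 5 nt after the stop codon -> ADJACENT
  adj <- classified(complete, 100, 40, 95, refs)
  expect_equal(adj$archetype, "ADJACENT")

  # hit starting far after the stop codon -> SPACED
  sp <- classified(complete, 200, 40, 97, refs, total = 500)
  expect_equal(sp$archetype, "SPACED")

  # no hit at all -> NONE
  none <- classify_locus(orf_row(0, 300, seq_id = "w"),
                         locate_trna(list(id = "w",
                                          residues = random_dna(400, 0.6)),
                                     refs),
                         refs)
  expect_equal(none$archetype, "NONE")
})

test_that("a stop codon inside the tRNA yields PARTIAL_FORWARD at residue 46", {
  refs <- reference_set(seed = 5)
  complete <- refs[refs$variant == "complete", ]$residues
  planted <- paste0(substr(complete, 1, 45), "TGA", substr(complete, 49, 96))
  set.seed(52)
  # ORF ends at the planted TGA (tRNA residues 46-48)
  call <- classified(planted, 99, 0, 99 + 48, refs)
  expect_equal(call$archetype, "PARTIAL_FORWARD")
  expect_equal(call$stop_in_trna, 46L)
  expect_false(call$stop_gapped)
})

test_that("classification is invariant under shifting the whole locus", {
  refs <- reference_set(seed = 5)
  complete <- refs[refs$variant == "complete", ]$residues
  planted <- paste0(substr(complete, 1, 45), "TGA", substr(complete, 49, 96))
  set.seed(53)
  res0 <- paste0(random_dna(99, 0.6), planted, random_dna(150, 0.6))
  for (k in c(0, 7, 31)) {
    res <- paste0(random_dna(k, 0.6), res0)
    hits <- locate_trna(list(id = "w", residues = res), refs)
    call <- classify_locus(orf_row(k, 99 + k + 48, seq_id = "w"), hits, refs,
                           residues = res)
    expect_equal(call$archetype, "PARTIAL_FORWARD", info = paste("shift", k))
    expect_equal(call$stop_in_trna, 46L, info = paste("shift", k))
  }
})

test_that("coupling is attached when a downstream ORF is supplied", {
  refs <- reference_set(seed = 5)
  complete <- refs[refs$variant == "complete", ]$residues
  set.seed(54)
  ds <- orf_row(198, 198 + 330, seq_id = "w")  # start overlaps the stop by 1
  call <- classified(complete, 100, 40, 100 + 99, refs, downstream = ds)
  expect_equal(call$archetype, "COMPLETE_FORWARD")
  expect_equal(call$coupling$overlap_len, 1L)
})

test_that("stop position maps through gapped alignments", {
  # constructed toy: reference positions 5-6 are deleted in the target,
  # so target t maps to ref t for t <= 4 and ref t+2 after the gap
  pm <- cbind(ref = c(1:4, 7:12), tgt = 1:10)
  hit <- tibble::tibble(
    ref_id = "r", seq_id = "w", start = 0L, end = 10L, strand = "+",
    identity = 1, ref_cov_start = 0L, ref_cov_end = 12L, score = 10,
    alignment = list(list(aln = list(pair_map = pm), strand = "+",
                          target = strrep("A", 10), window_len = 10L)))
  # stop codon first base at target position 7 (0-based 6): ref 9
  expect_equal(stop_position_in_trna(orf_row(0, 9), hit),
               list(pos = 9L, gapped = FALSE))
  # stop entirely downstream of the alignment -> absent
  expect_true(is.na(stop_position_in_trna(orf_row(0, 30), hit)$pos))
  # target base missing from the pair map -> nearest ref position, flagged
  pm2 <- cbind(ref = c(1:4, 5:10), tgt = c(1:4, 7:12))
  hit2 <- hit
  hit2$alignment <- list(list(aln = list(pair_map = pm2), strand = "+",
                              target = strrep("A", 12), window_len = 12L))
  res <- stop_position_in_trna(orf_row(0, 8), hit2)   # target pos 6 is gapped
  expect_true(res$gapped)
  expect_equal(res$pos, 5L)   # nearest aligned column is target 7 / ref 5
})

test_that("find_promoter recovers the printed selC promoter layout", {
  s <- "TTGATTCAGGTTTACACATTTTCTACTATC"
  hits <- find_promoter(s)
  match <- hits[hits$m35_start == 0 & hits$m10_start == 23, ]
  expect_equal(nrow(match), 1)
  expect_equal(match$m35, "TTGATT")
  expect_equal(match$m10, "TACTAT")
  expect_equal(match$spacer, 17L)
  expect_equal(match$mismatches, 4L)
})

test_that("consensus boxes give a zero-mismatch promoter hit", {
  set.seed(55)
  s <- paste0("TTGACA", random_dna(17), "TATAAT")
  hits <- find_promoter(s)
  expect_equal(hits$mismatches[1], 0L)
  expect_equal(hits$spacer[1], 17L)
})

test_that("find_promoter equals brute-force box placement on random strings", {
  set.seed(56)
  for (i in 1:20) {
    s <- random_dna(30)
    expect_equal(nrow(find_promoter(s)), promoter_oracle_count(s), info = s)
  }
})
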