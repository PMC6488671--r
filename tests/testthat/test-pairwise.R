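test_that("full alignment reproduces enumeration on tiny and random cases", {
  sc <- scoring_params()
  a1 <- align_full("ACGT", "ACGT", sc)
  expect_equal(a1$score, 4)
  expect_equal(a1$aligned_a, "ACGT")
  expect_equal(a1$cells_filled, 25)

  expect_equal(align_full("ACGT", "AGT", sc)$score, 1)   # 3 matches, 1 gap
  expect_equal(align_full("AA", "TT", sc)$score, -2)     # mismatches beat gaps

  set.seed(401)
  for (rep in 1:60) {
    a <- random_dna_str(sample(1:7, 1))
    b <- random_dna_str(sample(1:7, 1))
    f <- align_full(a, b, sc)
    expect_equal(f$score, enum_align_score(a, b))
    expect_equal(degap(f$aligned_a), a)
    expect_equal(degap(f$aligned_b), b)
    expect_equal(nchar(f$aligned_a), nchar(f$aligned_b))
    expect_equal(score_gapped_pair(f$aligned_a, f$aligned_b, sc), f$score)
    # no column may be a gap in both rows
    ga <- strsplit(f$aligned_a, "")[[1]] == "-"
    gb <- strsplit(f$aligned_b, "")[[1]] == "-"
    expect_false(any(ga & gb))
  }
})

test_that("full alignment agrees with an independent aligner on random pairs", {
  sc <- scoring_params()
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  set.seed(402)
  for (rep in 1:25) {
    a <- random_dna_str(sample(20:120, 1))
    b <- random_dna_str(sample(20:120, 1))
    ours <- align_full(a, b, sc)$score
    # linear gaps: gapOpening 0, gapExtension 2 (Biostrings uses penalties)
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 2,
                                         scoreOnly = TRUE)
    expect_equal(ours, as.numeric(ref))
  }
})

test_that("N is scored as a mismatch against everything, including N", {
  sc <- scoring_params()
  expect_equal(align_full("NN", "NN", sc)$score, -2)
  expect_equal(align_full("ANA", "AAA", sc)$score, 1)
})

test_that("banded alignment equals the full optimum whenever the band covers the path", {
  sc <- scoring_params()
  # identical strings need the main diagonal only
  x <- random_dna_str(80)
  b0 <- align_banded(x, x, sc, band_spec(0))
  f0 <- align_full(x, x, sc)
  expect_equal(b0$score, f0$score)
  # d = 0, k = 0: exactly one cell per row (the main diagonal)
  expect_equal(b0$cells_filled, 81)

  set.seed(403)
  for (rep in 1:40) {
    a <- random_dna_str(sample(10:120, 1))
    b <- random_dna_str(sample(10:120, 1))
    f <- align_full(a, b, sc)
    wide <- align_banded(a, b, sc, band_spec(max(nchar(a), nchar(b))))
    expect_equal(wide$score, f$score)
    expect_identical(wide$aligned_a, f$aligned_a)
    expect_identical(wide$aligned_b, f$aligned_b)
  }
})

test_that("banded score is monotone non-decreasing in d and symmetric in the inputs", {
  sc <- scoring_params()
  set.seed(404)
  for (rep in 1:25) {
    a <- random_dna_str(sample(30:100, 1))
    b <- random_dna_str(sample(30:100, 1))
    scores <- vapply(c(0, 1, 2, 4, 8, 16, 64),
                     function(d) align_banded(a, b, sc, band_spec(d))$score,
                     numeric(1))
    expect_true(all(diff(scores) >= 0))
    expect_equal(align_banded(a, b, sc, band_spec(5))$score,
                 align_banded(b, a, sc, band_spec(5))$score)
  }
})

test_that("cells_filled respects the band budget", {
  sc <- scoring_params()
  set.seed(405)
  for (rep in 1:20) {
    la <- sample(20:150, 1); lb <- sample(20:150, 1)
    a <- random_dna_str(la); b <- random_dna_str(lb)
    d <- sample(0:10, 1)
    k <- abs(la - lb)
    r <- align_banded(a, b, sc, band_spec(d))
    expect_lte(r$cells_filled, (2 * d + 1 + 2 * k) * (min(la, lb) + 1) + (2 * (d + k) + 1))
    expect_lte(r$cells_filled, (la + 1) * (lb + 1))
  }
})

test_that("min_band_oracle finds the smallest sufficient band", {
  sc <- scoring_params()
  x <- random_dna_str(60)
  expect_equal(min_band_oracle(x, x, sc), 0L)
  d <- min_band_oracle("ACGTACGT", "ACGACGT", sc)
  expect_equal(align_banded("ACGTACGT", "ACGACGT", sc, band_spec(d))$score,
               align_full("ACGTACGT", "ACGACGT", sc)$score)

  set.seed(406)
  for (rep in 1:15) {
    fam <- generate_family(m = sample(60:150, 1), n_sequences = 2,
                           target_identity_pct = sample(50:99, 1),
                           seed = sample.int(1e6, 1))
    a <- fam$sequences$seq[1]; b <- fam$sequences$seq[2]
    ds <- min_band_oracle(a, b, sc)
    full <- align_full(a, b, sc)$score
    expect_equal(align_banded(a, b, sc, band_spec(ds))$score, full)
    if (ds > 0)
      expect_lt(align_banded(a, b, sc, band_spec(ds - 1L))$score, full)
  }
})

test_that("dot-plot band estimation brackets constructed offsets", {
  x <- random_dna_str(300)
  self <- estimate_band_dotplot(x, x, word_size = 8)
  expect_equal(self$d, 8L)  # all matches on the main diagonal; margin only

  # single 10-base insertion at the midpoint
  y <- paste0(substr(x, 1, 150), random_dna_str(10), substr(x, 151, 300))
  bs <- estimate_band_dotplot(x, y, word_size = 8)
  expect_gte(bs$d, 10)
  expect_lte(bs$d, 18)
  expect_equal(bs$k, 10L)

  # unrelated sequences: full-matrix fallback with a warning
  set.seed(407)
  expect_warning(
    fb <- estimate_band_dotplot(random_dna_str(500), random_dna_str(500),
                                word_size = 12),
    "full matrix"
  )
  expect_equal(fb$d, 500L)
})

test_that("band k consistency and infeasibility are reported as errors", {
  sc <- scoring_params()
  expect_error(align_banded("ACGT", "AC", sc, band_spec(1, k = 0)),
               "does not match")
  expect_error(scoring_params(gap = 1), "negative")
  expect_error(scoring_params(match = -2, mismatch = 0), "exceed")
})
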