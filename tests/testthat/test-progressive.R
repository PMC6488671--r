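test_that("guide order sorts joins by distance with lexicographic ties", {
  f <- tibble::tibble(
    id_a = c("A", "A", "B"), id_b = c("B", "C", "C"),
    identity_pct = c(99.9, 99.5, 99.7), length_diff_pct = 0
  )
  g <- build_guide_order(f)
  expect_equal(g$id_a, c("A", "B", "A"))
  expect_equal(g$id_b, c("B", "C", "C"))
  expect_true(all(diff(g$distance) >= 0))

  # equal distances: lexicographic pair order
  f2 <- tibble::tibble(id_a = c("A", "A", "B"), id_b = c("B", "C", "C"),
                       identity_pct = 99, length_diff_pct = 0)
  g2 <- build_guide_order(f2)
  expect_equal(paste(g2$id_a, g2$id_b), c("A B", "A C", "B C"))

  # two sequences: a single join
  expect_equal(nrow(build_guide_order(f[1, ])), 1)
  expect_error(build_guide_order(f[-1, ]), "every sequence pair")
})

test_that("segment-wise alignment copies identical segments and bounds DP work", {
  sc <- scoring_params()
  x <- random_dna_str(600)
  same <- align_pair_segmented(x, x, band_pct = 1, scoring = sc,
                               segment_size = 100)
  expect_equal(same$cells_filled, 0)
  expect_equal(same$aligned_a, x)
  expect_equal(same$segments_copied, 6)

  # one substituted base: exactly one segment goes through DP
  y <- x
  substr(y, 250, 250) <- if (substr(x, 250, 250) == "A") "C" else "A"
  one <- align_pair_segmented(x, y, band_pct = 2, scoring = sc,
                              segment_size = 100)
  expect_equal(one$segments_aligned, 1)
  d <- diagonals_pct_to_d(2, 100, 100)
  expect_lte(one$cells_filled, (2 * d + 1) * 101)
  expect_equal(degap(one$aligned_a), x)
  expect_equal(degap(one$aligned_b), y)
})

test_that("serial and multicore backends give byte-identical alignments", {
  fam <- generate_family(m = 800, n_sequences = 6, target_identity_pct = 92,
                         seed = 31)
  serial <- run_msa(fam$sequences, segment_size = 200, backend = "serial")
  multi <- run_msa(fam$sequences, segment_size = 200, backend = "multicore",
                   workers = 4)
  expect_identical(serial$rows, multi$rows)
  # and rerunning serially is deterministic
  again <- run_msa(fam$sequences, segment_size = 200)
  expect_identical(serial$rows, again$rows)
})

test_that("profile merge propagates gaps by the once-a-gap-always-a-gap rule", {
  sc <- scoring_params()
  profile <- c(r1 = "ACGTA", r2 = "ACGTA")
  # merging an identical sequence: column count unchanged, row copied
  aln_same <- align_full("ACGTA", "ACGTA", sc)
  m1 <- merge_into_profile(profile, aln_same, "r1", "new")
  expect_equal(nchar(m1[["new"]]), 5)
  expect_equal(m1[["new"]], m1[["r1"]])

  # a single-indel merge adds exactly one gap column to every prior row
  aln_ins <- align_full("ACGTA", "ACGGTA", sc)
  m2 <- merge_into_profile(profile, aln_ins, "r1", "new")
  expect_equal(nchar(m2[["r1"]]), 6)
  gap_cols <- which(strsplit(m2[["r1"]], "")[[1]] == "-")
  expect_equal(length(gap_cols), 1)
  expect_equal(strsplit(m2[["r2"]], "")[[1]][gap_cols], "-")
  expect_equal(degap(m2[["new"]]), "ACGGTA")

  expect_error(merge_into_profile(profile, aln_same, "zz", "new"),
               "representative")

  # degap round-trip after a chain of merges of mutated siblings
  set.seed(702)
  base <- random_dna_str(300)
  profile <- c(s0 = base)
  for (i in 1:10) {
    mut <- mutate_seq(base, 0.03, 0.002, 0.002, seed = 800 + i)$seq
    rep_id <- names(profile)[1]
    aln <- align_full(degap(profile[[rep_id]]), mut, sc)
    profile <- merge_into_profile(profile, aln, rep_id, paste0("s", i))
    expect_equal(unname(degap(profile[[paste0("s", i)]])), mut)
    expect_equal(unname(degap(profile[["s0"]])), base)
    expect_equal(length(unique(nchar(profile))), 1)
  }
})

test_that("refinement removes all-gap columns, never lowers the score, and fixes identical rows", {
  sc <- scoring_params()
  msa <- c(a = "AC--GT", b = "AC--GT", c = "ACA-GT")
  ref <- refine_msa(msa, sc, band_pct = 100)
  expect_false(any(apply(do.call(rbind, strsplit(ref$rows, "")) == "-", 2, all)))
  expect_equal(unname(degap(ref$rows)), unname(degap(msa)))

  ident <- c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT")
  fx <- refine_msa(ident, sc, band_pct = 100)
  expect_identical(fx$rows, ident)

  set.seed(703)
  fam <- generate_family(m = 600, n_sequences = 8, target_identity_pct = 95,
                         seed = 37)
  raw <- run_msa(fam$sequences, segment_size = 200, refine = FALSE)
  pol <- refine_msa(raw, sc, band_pct = raw$report$band_pct)
  sp_sum <- function(rows) {
    ids <- names(rows); tot <- 0
    for (i in 1:(length(ids) - 1)) for (j in (i + 1):length(ids))
      tot <- tot + score_gapped_pair(rows[[i]], rows[[j]], sc)
    tot
  }
  expect_gte(sp_sum(pol$rows), sp_sum(raw$rows))
  expect_equal(unname(degap(pol$rows[fam$sequences$id])), fam$sequences$seq)
})

test_that("run_msa on identical sequences does no DP work and aligns gap-free", {
  x <- random_dna_str(400)
  msa <- run_msa(tibble::tibble(id = c("p", "q"), seq = c(x, x)),
                 segment_size = 100)
  expect_equal(msa$report$total_cells, 0)
  expect_false(any(grepl("-", msa$rows, fixed = TRUE)))
  expect_equal(average_sp_score(msa$rows, msa$rows), 1.0)
})

test_that("run_msa flow: preloaded KB hit skips the dot plot; empty KB learns once", {
  fam <- generate_family(m = 1000, n_sequences = 2, target_identity_pct = 95,
                         seed = 41)
  with_kb <- run_msa(fam$sequences, kb = kb_table1(), segment_size = 250)
  expect_true(with_kb$report$kb_hit)
  expect_equal(with_kb$report$dotlet_runs, 0L)
  expect_equal(with_kb$report$kb_size_after, with_kb$report$kb_size_before)

  no_kb <- run_msa(fam$sequences, segment_size = 250)
  expect_false(no_kb$report$kb_hit)
  expect_equal(no_kb$report$dotlet_runs, 1L)
  expect_equal(no_kb$report$kb_size_after - no_kb$report$kb_size_before, 1L)
  # the learned entry answers the same query exactly afterwards
  q <- no_kb$report$query
  relook <- kb_lookup(no_kb$report$kb, q$length_diff_pct, q$identity_pct)
  expect_equal(relook$match, "exact")
})

test_that("every run_msa output row degaps to its input across conditions", {
  set.seed(704)
  for (t in c(95, 45)) {
    fam <- generate_family(m = 700, n_sequences = 5, target_identity_pct = t,
                           seed = 50 + t)
    msa <- run_msa(fam$sequences, segment_size = 200)
    expect_equal(unname(degap(msa$rows[fam$sequences$id])), fam$sequences$seq)
    expect_equal(length(unique(nchar(msa$rows))), 1)
  }
  expect_error(run_msa(tibble::tibble(id = "a", seq = "ACGT")), "at least 2")
})

test_that("recovered alignments beat the ungapped stacking baseline on indel families", {
  set.seed(705)
  wins <- replicate(5, {
    fam <- generate_family(m = 800, n_sequences = 4, target_identity_pct = 93,
                           seed = sample.int(1e6, 1), indel_frac = 0.3)
    msa <- run_msa(fam$sequences, segment_size = 200)
    # naive baseline: stack unaligned sequences padded to equal length
    L <- max(nchar(fam$sequences$seq))
    pad <- vapply(fam$sequences$seq, function(s)
      paste0(s, strrep("-", L - nchar(s))), character(1))
    names(pad) <- fam$sequences$id
    average_sp_score(msa, fam$truth) - average_sp_score(pad, fam$truth)
  })
  expect_true(all(wins >= 0))
  expect_gt(mean(wins), 0)
})

test_that("tidy and glance expose the alignment and its audit", {
  fam <- generate_family(m = 300, n_sequences = 3, target_identity_pct = 95,
                         seed = 61)
  msa <- run_msa(fam$sequences, segment_size = 100)
  td <- tidy(msa)
  expect_equal(names(td), c("id", "aligned"))
  expect_equal(nrow(td), 3)
  gl <- glance(msa)
  expect_equal(gl$n_sequences, 3)
  expect_true(gl$total_cells >= 0)
  expect_s3_class(autoplot(msa), "ggplot")
})
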