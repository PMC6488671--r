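test_that("packaged knowledge base loads and answers exact lookups", {
  kb <- kb_table1()
  expect_equal(nrow(tidy(kb)), 12)
  expect_equal(kb_lookup(kb, 0.30, 99.20)$diagonals_pct, 0.15)
  expect_equal(kb_lookup(kb, 0.30, 99.20)$match, "exact")
  expect_equal(kb_lookup(kb, 25, 50.00)$diagonals_pct, 20)
  expect_equal(kb_lookup(kb, 0.10, 95.90)$diagonals_pct, 0.18)
  # every stored row is retrievable exactly
  e <- tidy(kb)
  for (i in seq_len(nrow(e))) {
    got <- kb_lookup(kb, e$length_diff_pct[i], e$identity_pct[i])
    expect_equal(got$diagonals_pct, e$diagonals_pct[i])
    expect_equal(got$match, "exact")
  }
})

test_that("nearest-neighbour lookup respects the per-dimension tolerance window", {
  kb <- kb_table1()
  near <- kb_lookup(kb, 0.31, 99.21)
  expect_equal(near$match, "nn")
  expect_equal(near$diagonals_pct, 0.15)
  # far from every entry on at least one axis
  expect_equal(kb_lookup(kb, 50, 10)$match, "miss")
  # within tolerance on one axis only is still a miss
  expect_equal(kb_lookup(kb, 0.30, 80)$match, "miss")
  # empty knowledge base always misses
  expect_equal(kb_lookup(kb_new(), 1, 99)$match, "miss")
  # distance ties resolve to the first-loaded entry
  tie_kb <- kb_new(tibble::tibble(length_diff_pct = c(1, 3),
                                  identity_pct = c(90, 90),
                                  diagonals_pct = c(5, 7)))
  expect_equal(kb_lookup(tie_kb, 2, 90)$diagonals_pct, 5)
})

test_that("CSV round-trip preserves entries and order; malformed rows are rejected", {
  kb <- kb_table1()
  f <- tempfile(fileext = ".csv")
  kb_save(kb, f)
  expect_equal(tidy(kb_load(f)), tidy(kb))

  # empty KB round-trips as header-only file
  f0 <- tempfile(fileext = ".csv")
  kb_save(kb_new(), f0)
  expect_equal(nrow(tidy(kb_load(f0))), 0)

  # invariant violations are caught
  expect_error(kb_new(tibble::tibble(length_diff_pct = 1, identity_pct = 101,
                                     diagonals_pct = 5)), "invalid")
  expect_error(kb_new(tibble::tibble(length_diff_pct = c(1, 1),
                                     identity_pct = c(90, 90),
                                     diagonals_pct = c(5, 6))), "duplicate")
  bad <- tempfile(fileext = ".csv")
  writeLines(c("length_diff_pct,identity_pct,diagonals_pct", "1,2"), bad)
  expect_error(kb_load(bad), "malformed")
})

test_that("learn appends or replaces and round-trips through lookup", {
  kb <- kb_new()
  kb <- kb_learn(kb, 5.0, 80.0, 4.0)
  expect_equal(kb_lookup(kb, 5.0, 80.0)$diagonals_pct, 4.0)
  # same key twice: last write wins, size unchanged
  kb <- kb_learn(kb, 5.0, 80.0, 6.0)
  expect_equal(nrow(tidy(kb)), 1)
  expect_equal(kb_lookup(kb, 5.0, 80.0)$diagonals_pct, 6.0)

  # property: learn -> exact lookup holds for arbitrary valid entries
  set.seed(501)
  for (rep in 1:20) {
    ld <- round(runif(1, 0, 40), 2)
    id <- round(runif(1, 0, 100), 2)
    dg <- round(runif(1, 0.1, 99), 2)
    kb <- kb_learn(kb, ld, id, dg)
    expect_equal(kb_lookup(kb, ld, id)$diagonals_pct, dg)
  }
})

test_that("lookup result is invariant to entry order (absent exact distance ties)", {
  e <- tidy(kb_table1())
  kb_fwd <- kb_new(e)
  kb_rev <- kb_new(e[rev(seq_len(nrow(e))), ])
  queries <- list(c(0.31, 99.21), c(0.2, 96.2), c(24, 51), c(1.0, 98.5))
  for (q in queries) {
    expect_equal(kb_lookup(kb_fwd, q[1], q[2])$diagonals_pct,
                 kb_lookup(kb_rev, q[1], q[2])$diagonals_pct)
  }
})

test_that("a learned knowledge base reduces the miss rate on same-distribution queries", {
  set.seed(502)
  trained <- build_training_kb(n_datasets = 30, identity_range = c(55, 99),
                               m = 400, segment_size = 200, seed = 77)
  expect_gt(nrow(tidy(trained)), 5)
  # held-out queries from the same generator
  miss_trained <- 0; miss_empty <- 0
  empty <- kb_new()
  for (s in 1:15) {
    fam <- generate_family(m = 400, n_sequences = 2,
                           target_identity_pct = runif(1, 55, 99),
                           seed = 5000 + s)
    feats <- pair_similarity(fam$sequences$seq[1], fam$sequences$seq[2])
    q <- select_query_features(feats)
    if (kb_lookup(trained, q$length_diff_pct, q$identity_pct)$match == "miss")
      miss_trained <- miss_trained + 1
    if (kb_lookup(empty, q$length_diff_pct, q$identity_pct)$match == "miss")
      miss_empty <- miss_empty + 1
  }
  expect_lt(miss_trained, miss_empty)
})

test_that("select_query_features takes componentwise worst-case extremes", {
  f <- tibble::tibble(length_diff_pct = c(0.3, 1.2),
                      identity_pct = c(99.2, 99.0))
  q <- select_query_features(f)
  expect_equal(q$length_diff_pct, 1.2)
  expect_equal(q$identity_pct, 99.0)
  # single element returns itself
  q1 <- select_query_features(f[1, ])
  expect_equal(unlist(q1), c(length_diff_pct = 0.3, identity_pct = 99.2))
  # components may come from different pairs
  f2 <- tibble::tibble(length_diff_pct = c(1, 2), identity_pct = c(90, 95))
  q2 <- select_query_features(f2)
  expect_equal(q2$length_diff_pct, 2)
  expect_equal(q2$identity_pct, 90)
  expect_error(select_query_features(f2[0, ]))
})

test_that("diagonals percentage converts to an integer band width by ceiling", {
  expect_equal(diagonals_pct_to_d(0.15, 6570, 6560), as.integer(ceiling(0.0015 * 6570)))
  expect_equal(diagonals_pct_to_d(100, 50, 40), 50L)
  expect_equal(diagonals_pct_to_d(0.18, 500, 500), 1L)
})
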