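test_that("build_contingency reproduces the toy 2x2 layout", {
  fx <- toy_contingency_fixture()
  ct <- build_contingency(fx$roi, fx$dbset, fx$universe)
  expect_equal(ct$a, 2L)
  expect_equal(ct$b, 2L)
  expect_equal(ct$c, 1L)
  expect_equal(ct$d, 5L)

  empty_db <- region_set(character(0), integer(0), integer(0),
                         genome = fx$genome, label = "empty")
  ct0 <- build_contingency(fx$roi, empty_db, fx$universe)
  expect_equal(unlist(ct0[c("a", "b", "c", "d")]),
               c(a = 0L, b = 4L, c = 0L, d = 6L))

  whole <- region_set("chr1", 0, 1000, genome = fx$genome, label = "whole")
  ctw <- build_contingency(fx$roi, whole, fx$universe)
  expect_equal(ctw$a, 4L)
  expect_equal(ctw$b, 0L)

  stray <- region_set("chr1", c(10, 950), c(11, 951), name = c("in", "out"),
                      genome = fx$genome, label = "stray")
  expect_error(build_contingency(stray, fx$dbset, fx$universe),
               "not contained in the universe")
})

test_that("fisher_greater matches closed forms and the tail-sum oracle", {
  expect_equal(fisher_greater(contingency_table(0, 4, 3, 3)), 1.0)
  expect_equal(fisher_greater(contingency_table(2, 0, 0, 2)), 1 / 6,
               tolerance = 1e-15)
  expect_error(fisher_greater(contingency_table(0, 0, 3, 3)), "empty ROI")

  ct <- contingency_table(5, 5, 10, 80)
  expect_equal(fisher_greater(ct), fisher_tail_oracle(5, 5, 10, 80),
               tolerance = 1e-12)

  # small exhaustive sweep here; the full N <= 60 sweep runs in the
  # acceptance suite
  worst <- 0
  for (N in 2:25) {
    for (a in 0:N) for (b in 0:(N - a)) {
      if (a + b == 0) next
      for (cc in 0:(N - a - b)) {
        d <- N - a - b - cc
        delta <- abs(fisher_greater(contingency_table(a, b, cc, d)) -
                       fisher_tail_oracle(a, b, cc, d))
        worst <- max(worst, delta)
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("odds_ratio follows the zero-cell conventions", {
  expect_equal(odds_ratio(contingency_table(2, 2, 1, 5)), 5.0)
  expect_equal(odds_ratio(contingency_table(0, 3, 4, 5)), 0.0)
  expect_identical(odds_ratio(contingency_table(2, 0, 1, 5)), Inf)
  expect_true(is.nan(odds_ratio(contingency_table(0, 5, 0, 5))))
})

test_that("bh_adjust equals the naive step-up oracle and hand computations", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(99)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_naive(p), tolerance = 1e-12)
  }
  # invariance to permutation up to re-alignment
  p <- runif(20)
  perm <- sample(20)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
})

test_that("harmonic_score matches its conventions and published rows", {
  expect_equal(harmonic_score(1, 1, 1), 10.0)
  expect_equal(harmonic_score(0, 5, 2), 0.0)
  expect_equal(harmonic_score(5, 0, 2), 0.0)
  expect_equal(harmonic_score(5, 2, 0), 0.0)
  expect_error(harmonic_score(-1, 1, 1), "non-negative")

  # published row: strongest DBR match at the +/-50 kb extension
  expect_equal(harmonic_score(10.658, 158, 1.790), 45.544, tolerance = 0.05)

  # saturated odds ratio drops its reciprocal term
  expect_equal(harmonic_score(10, 10, Inf), 10 * 3 / (1 / 10 + 1 / 10))

  # HS(x,x,x) = kp * x; strictly increasing in each contributor
  for (x in c(0.5, 1, 7, 30)) {
    expect_equal(harmonic_score(x, x, x), 10 * x)
  }
  set.seed(3)
  for (i in 1:50) {
    v <- runif(3, 0.1, 50)
    base <- harmonic_score(v[1], v[2], v[3])
    expect_gt(harmonic_score(v[1] * 1.1, v[2], v[3]), base)
    expect_gt(harmonic_score(v[1], v[2] * 1.1, v[3]), base)
    expect_gt(harmonic_score(v[1], v[2], v[3] * 1.1), base)
  }
})

test_that("run_colocalization ranks by harmonic score with total ordering", {
  fx <- toy_contingency_fixture()
  empty <- region_collection(list())
  expect_equal(nrow(run_colocalization(fx$roi, empty, fx$universe)), 0L)

  whole <- region_set("chr1", 0, 1000, genome = fx$genome, label = "whole")
  coll <- region_collection(list(fx$dbset, whole))
  res <- run_colocalization(fx$roi, coll, fx$universe)
  expect_equal(nrow(res), 2L)
  wrow <- res[res$dbset == "whole", ]
  expect_equal(wrow$support, 4L)
  expect_identical(wrow$odds_ratio, Inf)
  # the genome-wide set saturates p at 1, so -log10 p = 0 and the
  # zero-contributor convention pins the score at 0
  expect_equal(wrow$p, 1.0)
  expect_equal(wrow$harmonic_score, 0)
  # the score column is consistent with direct recomputation
  expect_equal(res$harmonic_score,
               harmonic_score(res$neg_log10_p, res$support, res$odds_ratio))
  # marginals conserve in every emitted row
  expect_true(all(res$a + res$b + res$c + res$d == length(fx$universe)))
  # sorted by harmonic score descending
  expect_true(all(diff(res$harmonic_score) <= 0))
  # q >= p row-wise
  expect_true(all(res$q >= res$p - 1e-15))
})

test_that("the planted-enriched set is top-ranked in a synthetic collection", {
  hits <- 0L
  for (s in 1:5) {
    cfg <- sim_config(seed = 100 + s, planted_or = 3)
    sim <- simulate_universe_and_roi(cfg)
    coll <- simulate_collection(cfg, sim)
    res <- run_colocalization(sim$roi, coll$collection, sim$universe)
    if (res$dbset[1] == coll$truth$planted_label) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
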