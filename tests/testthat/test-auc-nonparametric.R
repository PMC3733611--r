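test_that("kernel scores pairs as win/tie/loss", {
  expect_equal(auc_kernel(1, 2), 1)
  expect_equal(auc_kernel(2, 2), 0.5)
  expect_equal(auc_kernel(3, 2), 0)
  expect_equal(auc_kernel(c(1, 2, 3), c(2, 2, 2)), c(1, 0.5, 0))
  expect_error(auc_kernel(NA_real_, 1), "finite")
  expect_error(auc_kernel(Inf, 1), "finite")
})

test_that("AUC estimate matches small hand-computed fixtures", {
  expect_equal(estimate_auc(score_sample(c(1, 2, 3), c(2.5, 3.5))), 5 / 6)
  expect_equal(estimate_auc(score_sample(0, 1)), 1)
  expect_equal(estimate_auc(score_sample(c(1, 2), c(1, 2))), 0.5)
})

test_that("AUC estimate equals brute-force pair counting on random instances", {
  set.seed(41)
  for (rep in 1:60) {
    n0 <- sample(2:50, 1); n1 <- sample(2:50, 1)
    s <- random_tied_sample(n0, n1)
    expect_equal(estimate_auc(score_sample(s$x, s$y)), bf_auc(s$x, s$y),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(42)
  for (rep in 1:20) {
    s <- random_tied_sample(sample(3:30, 1), sample(3:30, 1))
    a0 <- estimate_auc(score_sample(s$x, s$y))
    for (f in list(function(v) exp(v), function(v) v^3 + 2 * v,
                   function(v) atan(v))) {
      expect_equal(estimate_auc(score_sample(f(s$x), f(s$y))), a0)
    }
  }
})

test_that("class swap complements the AUC", {
  set.seed(43)
  for (rep in 1:20) {
    s <- random_tied_sample(sample(2:25, 1), sample(2:25, 1))
    expect_equal(estimate_auc(score_sample(s$x, s$y)) +
                   estimate_auc(score_sample(s$y, s$x)), 1)
  }
})

test_that("structural components match their definition and average to the AUC", {
  sc <- structural_components(score_sample(c(1, 3), c(2, 4)))
  expect_equal(sc$v01, c(1, 0.5))
  expect_equal(sc$v10, c(0.5, 1))
  sc <- structural_components(score_sample(c(1, 2), c(3, 4)))
  expect_equal(sc$v01, c(1, 1))
  expect_equal(sc$v10, c(1, 1))
  set.seed(44)
  for (rep in 1:25) {
    s <- random_tied_sample(sample(2:40, 1), sample(2:40, 1))
    smp <- score_sample(s$x, s$y)
    sc <- structural_components(smp)
    bf <- bf_components(s$x, s$y)
    expect_equal(sc$v01, bf$v01, tolerance = 1e-12)
    expect_equal(sc$v10, bf$v10, tolerance = 1e-12)
    expect_equal(mean(sc$v01), estimate_auc(smp), tolerance = 1e-12)
    expect_equal(mean(sc$v10), estimate_auc(smp), tolerance = 1e-12)
  }
})

test_that("DeLong variance matches the hand-computed fixture and is nonnegative", {
  expect_equal(delong_variance(score_sample(c(1, 3), c(2, 4))), 0.125)
  expect_equal(delong_variance(score_sample(c(1, 2), c(3, 4))), 0)
  set.seed(45)
  for (rep in 1:40) {
    s <- random_tied_sample(sample(2:40, 1), sample(2:40, 1))
    v <- delong_variance(score_sample(s$x, s$y))
    expect_gte(v, 0)
    expect_equal(v, bf_delong_variance(s$x, s$y), tolerance = 1e-12)
  }
})

test_that("optimized U-statistics variance equals literal index-tuple enumeration", {
  # degenerate perfect separation: every kernel value is 1
  expect_equal(ustat_variance(score_sample(c(1, 2), c(3, 4)))$variance, 0)
  set.seed(46)
  for (rep in 1:30) {
    n0 <- sample(2:12, 1); n1 <- sample(2:12, 1)
    s <- random_tied_sample(n0, n1)
    opt <- ustat_variance(score_sample(s$x, s$y))
    bf <- bf_ustat_variance(s$x, s$y)
    expect_equal(opt$variance, bf$variance, tolerance = 1e-12)
    expect_equal(opt$xi01, bf$xi01, tolerance = 1e-12)
    expect_equal(opt$xi10, bf$xi10, tolerance = 1e-12)
    expect_equal(opt$xi11, bf$xi11, tolerance = 1e-12)
  }
})

test_that("DeLong and U-statistics variances agree asymptotically", {
  set.seed(47)
  x <- rnorm(4000); y <- rnorm(4000) + 1
  s <- score_sample(x, y)
  vd <- delong_variance(s)
  vu <- ustat_variance(s)$variance
  expect_equal(vd, vu, tolerance = 1e-3)
  expect_lt(abs(vd - vu) / vd, 0.01)
})

test_that("DeLong variance tracks the Monte Carlo variance of the AUC estimate", {
  set.seed(48)
  n0 <- 40; n1 <- 60; mu <- 1
  reps <- 12000
  a <- numeric(reps); v <- numeric(reps)
  for (r in seq_len(reps)) {
    s <- score_sample(rnorm(n0), rnorm(n1) + mu)
    a[r] <- estimate_auc(s)
    v[r] <- delong_variance(s)
  }
  # first-order estimator: mean should sit within a few percent of the truth
  expect_lt(abs(mean(v) - var(a)) / var(a), 0.06)
})

test_that("variance estimators reject degenerate inputs", {
  expect_error(ustat_variance(score_sample(1, c(2, 3))), "at least 2")
  expect_error(delong_variance(score_sample(c(1, 2), 3)), "at least 2")
  expect_error(score_sample(numeric(0), 1), "at least one")
  expect_error(score_sample(c(1, NA), 2), "finite")
})
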