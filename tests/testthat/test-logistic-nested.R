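test_that("logistic fit recovers the null model limit", {
  set.seed(71)
  n <- 20000
  x <- matrix(rnorm(n), n, 1)
  y <- rbinom(n, 1, 0.3)  # independent of x
  fit <- fit_logistic(x, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients[2]), 0.05)
  expect_equal(unname(fit$coefficients[1]), qlogis(mean(y)), tolerance = 0.01)
})

test_that("achieved log-likelihood matches an independent numeric-optimizer oracle", {
  set.seed(72)
  for (rep in 1:5) {
    n <- 60
    x <- matrix(rnorm(n * 2), n, 2)
    y <- rbinom(n, 1, plogis(0.3 + x[, 1] - 0.5 * x[, 2]))
    if (length(unique(y)) < 2) next
    fit <- fit_logistic(x, y)
    expect_equal(fit$log_likelihood, bf_logistic_loglik(x, y),
                 tolerance = 1e-6)
  }
})

test_that("full-model likelihood is never below the nested model's", {
  set.seed(73)
  for (rep in 1:10) {
    n <- 80
    x <- matrix(rnorm(n * 3), n, 3)
    y <- rbinom(n, 1, plogis(x[, 1]))
    if (length(unique(y)) < 2) next
    full <- fit_logistic(x, y)
    part <- fit_logistic(x[, 1:2, drop = FALSE], y)
    expect_gte(full$log_likelihood, part$log_likelihood - 1e-8)
  }
})

test_that("LR statistic vanishes when the new biomarker is constant", {
  set.seed(74)
  # constant column is aliased with the intercept: the full fit collapses to
  # the partial fit and the likelihood ratio carries no information
  neg <- cbind(matrix(rnorm(40 * 2), 40), 0)
  pos <- cbind(matrix(rnorm(30 * 2), 30) + 0.5, 0)
  res <- lr_test(two_class_data(neg, pos), existing = 1:2, new = 3)
  expect_gte(unname(res$statistic), 0)
  expect_lt(unname(res$statistic), 1e-6)
  expect_gt(res$p.value, 0.999)
  expect_true(any(grepl("rank-deficient", res$warnings)))
})

test_that("LR test fields are coherent and clamped at zero", {
  set.seed(75)
  dat <- generate_two_class_gaussian(reference_panel_spec("null"), 60, 30)
  res <- lr_test(dat, existing = 1:15, new = 16)
  expect_gte(unname(res$statistic), 0)
  expect_equal(unname(res$parameter), 1)
  expect_equal(res$p.value,
               pchisq(unname(res$statistic), 1, lower.tail = FALSE))
  # intercept-only partial model
  res0 <- lr_test(dat, existing = NULL, new = 1)
  expect_equal(unname(res0$parameter), 1)
  expect_gte(unname(res0$statistic), 0)
})

test_that("Wald z and chi-square forms agree for one new biomarker", {
  set.seed(76)
  dat <- generate_two_class_gaussian(reference_panel_spec("alternative"),
                                     100, 100)
  res <- wald_test(dat, existing = 1:15, new = 16)
  z <- unname(res$statistic)
  expect_equal(res$p.value, pchisq(z^2, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # multivariate form with q = 2
  res2 <- wald_test(dat, existing = 1:14, new = 15:16)
  expect_equal(unname(res2$parameter), 2)
  expect_equal(res2$p.value,
               pchisq(unname(res2$statistic), 2, lower.tail = FALSE))
})

test_that("Wald null p-values are approximately uniform at large N", {
  set.seed(77)
  n_trials <- 400
  spec <- gaussian_class_spec(c(0, 0), c(0.5, 0), diag(2))
  pv <- numeric(n_trials)
  for (r in seq_len(n_trials)) {
    dat <- generate_two_class_gaussian(spec, 250, 250)
    pv[r] <- wald_test(dat, existing = 1, new = 2)$p.value
  }
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("separation is flagged but a result is still returned", {
  # perfectly separable data on one predictor
  neg <- matrix(seq(-2, -1, length.out = 20), ncol = 1)
  pos <- matrix(seq(1, 2, length.out = 20), ncol = 1)
  dat <- two_class_data(neg, pos)
  res <- lr_test(dat, existing = NULL, new = 1)
  expect_true(length(res$warnings) > 0)
  expect_true(is.finite(unname(res$statistic)))
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_logistic(matrix(rnorm(10), 10, 1), rep(1, 10)),
               "both 0 and 1")
  expect_error(fit_logistic(matrix(rnorm(4), 2, 2), c(0, 1)),
               "more subject")
})
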