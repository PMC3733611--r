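test_that("Mahalanobis-to-AUC mapping reproduces known anchors and round-trips", {
  expect_equal(mahalanobis_to_auc(0), 0.5)
  expect_equal(round(mahalanobis_to_auc(2.00), 4), 0.8413)
  expect_equal(round(mahalanobis_to_auc(2.36), 4), 0.8613)
  expect_error(mahalanobis_to_auc(-0.1), "nonnegative")
  d2 <- c(0.01, 0.5, 1, 2, 5, 10)
  expect_equal(auc_to_mahalanobis(mahalanobis_to_auc(d2)), d2,
               tolerance = 1e-10)
  # strictly increasing
  expect_true(all(diff(mahalanobis_to_auc(seq(0, 8, by = 0.1))) > 0))
})

test_that("sample Mahalanobis distance matches a constructed identity fixture", {
  # pooled sample covariance exactly identity, mean difference (1, 0)
  neg <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1)) * sqrt(3 / 2)
  pos <- sweep(neg, 2, c(1, 0), "+")
  dat <- two_class_data(neg, pos)
  s <- ((4 - 1) * cov(neg) + (4 - 1) * cov(pos)) / 6
  expect_equal(s, diag(2), ignore_attr = TRUE)
  expect_equal(sample_mahalanobis_sq(dat), 1.0)
})

test_that("sample Mahalanobis distance equals the explicit-inverse oracle", {
  set.seed(61)
  for (rep in 1:20) {
    n0 <- sample(8:30, 1); n1 <- sample(8:30, 1)
    neg <- matrix(rnorm(n0 * 4), n0)
    pos <- matrix(rnorm(n1 * 4), n1) + 0.3
    dat <- two_class_data(neg, pos)
    expect_equal(sample_mahalanobis_sq(dat), bf_mahalanobis_sq(neg, pos),
                 tolerance = 1e-10)
  }
})

test_that("adding biomarkers never decreases the sample Mahalanobis distance", {
  set.seed(62)
  for (rep in 1:20) {
    dat <- two_class_data(matrix(rnorm(25 * 5), 25),
                          matrix(rnorm(20 * 5), 20) + 0.2)
    d2a <- sample_mahalanobis_sq(dat, 1:2)
    d2b <- sample_mahalanobis_sq(dat, 1:4)
    d2c <- sample_mahalanobis_sq(dat, 1:5)
    expect_lte(d2a, d2b + 1e-12)
    expect_lte(d2b, d2c + 1e-12)
  }
})

test_that("singular pooled covariance is rejected", {
  set.seed(63)
  neg <- matrix(rnorm(20 * 2), 20); pos <- matrix(rnorm(20 * 2), 20)
  neg <- cbind(neg, neg[, 1] + neg[, 2])  # exact collinearity
  pos <- cbind(pos, pos[, 1] + pos[, 2])
  expect_error(sample_mahalanobis_sq(two_class_data(neg, pos)),
               "singular")
  expect_error(sample_mahalanobis_sq(two_class_data(matrix(rnorm(4), 2),
                                                    matrix(rnorm(4), 2))),
               "N0 \\+ N1 - 2")
})

test_that("Rao F statistic matches direct arithmetic and edge cases", {
  res <- rao_f_statistic(1.0, 1.5, 30, 30, 1, 1)
  expect_equal(unname(res$statistic), 5.8563, tolerance = 1e-4)
  expect_equal(unname(res$parameter), c(1, 57))
  expect_equal(res$p.value, pf(unname(res$statistic), 1, 57,
                               lower.tail = FALSE))
  # equal distances: no evidence
  res0 <- rao_f_statistic(1.2, 1.2, 40, 20, 3, 2)
  expect_equal(unname(res0$statistic), 0)
  expect_equal(res0$p.value, 1)
  expect_error(rao_f_statistic(1, 2, 4, 3, 3, 3), "invalid design")
  expect_error(rao_f_statistic(2, 1, 30, 30, 1, 1), "not nested")
})

test_that("empty existing panel reduces to a one-sample separation test", {
  set.seed(64)
  dat <- generate_two_class_gaussian(
    gaussian_class_spec(0, 0.8, matrix(1)), 40, 40)
  res <- ideal_auc_f_test(dat, existing = NULL, new = 1)
  expect_equal(res$d2_partial, 0)
  expect_equal(res$p, 0)
  expect_equal(unname(res$parameter["df2"]), 40 + 40 - 0 - 1 - 1)
  # matches calling the statistic directly with p = 0
  direct <- rao_f_statistic(0, sample_mahalanobis_sq(dat, 1), 40, 40, 0, 1)
  expect_equal(res$statistic, direct$statistic)
})

test_that("null p-values of the F test are uniform (KS check)", {
  set.seed(65)
  n_trials <- 3000
  spec <- gaussian_class_spec(c(0, 0), c(0.5, 0), diag(2))
  pv <- numeric(n_trials)
  for (r in seq_len(n_trials)) {
    dat <- generate_two_class_gaussian(spec, 25, 15)
    pv[r] <- ideal_auc_f_test(dat, existing = 1, new = 2)$p.value
  }
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
})
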