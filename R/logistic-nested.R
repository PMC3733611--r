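# numerically stable log(1 + exp(eta))
log1pexp <- function(eta) {
  out <- eta
  small <- eta < 30
  out[small] <- log1p(exp(eta[small]))
  out[!small] <- eta[!small] + log1p(exp(-eta[!small]))
  out
}

#' Maximum-likelihood logistic regression fit
#'
#' Fits a logistic regression with intercept by iteratively reweighted least
#' squares (Fisher scoring; tolerance 1e-10 on the relative deviance change,
#' at most 100 iterations). Flags quasi-complete separation, diagnosed as
#' nonconvergence or any slope exceeding 15 in absolute value, so that
#' downstream Monte Carlo summaries can report how often it occurred.
#'
#' @param features Numeric matrix, one row per subject, one column per
#'   predictor (no intercept column; one is added).
#' @param labels 0/1 vector; both classes must be present.
#' @return An object of class `"logistic_fit"`: `coefficients` (intercept
#'   first), `log_likelihood`, `coef_cov` (inverse Fisher information),
#'   `converged`, `n_iter`, `separation`, `warnings`.
#' @export
fit_logistic <- function(features, labels) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2L)
    stop("labels must contain both 0 and 1", call. = FALSE)
  if (nrow(x) != length(y)) stop("row/label length mismatch", call. = FALSE)
  if (nrow(x) < ncol(x) + 1L)
    stop("need at least one more subject than coefficients", call. = FALSE)
  xm <- cbind(`(Intercept)` = 1, x)
  fit <- suppressWarnings(
    stats::glm.fit(xm, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  beta <- fit$coefficients
  rank_deficient <- anyNA(beta)
  if (rank_deficient) beta[is.na(beta)] <- 0  # aliased columns contribute nothing
  eta <- drop(xm %*% beta)
  ll <- sum(y * eta - log1pexp(eta))
  p <- fit$fitted.values
  w <- p * (1 - p)
  info <- crossprod(xm, xm * w)
  cov <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
  warn <- character(0)
  if (rank_deficient) warn <- c(warn, "rank-deficient design (aliased columns)")
  singular <- is.null(cov)
  if (singular) {
    cov <- matrix(NA_real_, ncol(xm), ncol(xm))
    warn <- c(warn, "singular information matrix")
  }
  dimnames(cov) <- list(colnames(xm), colnames(xm))
  separation <- !fit$converged || any(abs(beta[-1]) > 15)
  if (!fit$converged) warn <- c(warn, "IRLS did not converge")
  if (separation) warn <- c(warn, "possible (quasi-)separation")
  structure(
    list(coefficients = beta, log_likelihood = ll, coef_cov = cov,
         fitted = p, converged = fit$converged, n_iter = fit$iter,
         separation = separation, singular = singular, warnings = warn),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic regression fit:", length(x$coefficients) - 1L, "predictors,",
      "log-likelihood", format(x$log_likelihood, digits = 6), "\n")
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

# stacked design matrix + labels for the selected biomarkers
nested_design <- function(data, idx) {
  x <- rbind(data$neg_matrix[, idx, drop = FALSE],
             data$pos_matrix[, idx, drop = FALSE])
  list(x = x, y = rep(c(0, 1), c(data$n0, data$n1)))
}

test_result <- function(statistic, df, p_value, name, warnings, extra = list()) {
  structure(
    c(list(statistic = statistic, parameter = c(df = df), p.value = p_value,
           test_name = name, warnings = warnings,
           method = name, data.name = "two-class biomarker data"),
      extra),
    class = c("nested_test", "htest")
  )
}

#' Likelihood ratio test for added biomarkers in nested logistic models
#'
#' Fits logistic regressions with and without the new biomarkers and refers
#' twice the log likelihood ratio to a chi-square distribution with `q`
#' degrees of freedom (asymptotic under the null hypothesis that the new
#' coefficients are all zero). Tiny negative statistics arising from the
#' convergence tolerance are clamped at zero. Separation or nonconvergence
#' in either fit is recorded in `warnings`; the achieved statistic is still
#' reported.
#'
#' @param data A [two_class_data()] training sample.
#' @param existing Columns of the existing biomarkers (may be `NULL`:
#'   the partial model is intercept-only).
#' @param new Columns of the new biomarkers.
#' @return A `"nested_test"`/`"htest"` object with `statistic` (LR), `df`,
#'   `p.value`, `warnings`, and both fits.
#' @export
lr_test <- function(data, existing, new) {
  stopifnot(inherits(data, "two_class_data"))
  existing <- resolve_idx(data, existing)
  new <- resolve_idx(data, new)
  if (length(new) < 1L) stop("need at least one new biomarker", call. = FALSE)
  if (length(intersect(existing, new)) > 0L)
    stop("existing and new biomarker sets must be disjoint", call. = FALSE)
  full <- fit_logistic(nested_design(data, c(existing, new))$x,
                       nested_design(data, integer(0))$y)
  partial <- if (length(existing) == 0L) {
    des <- nested_design(data, integer(0))
    # intercept-only: closed-form ML at the observed prevalence
    ph <- mean(des$y)
    list(log_likelihood = sum(des$y * log(ph) + (1 - des$y) * log(1 - ph)),
         separation = FALSE, converged = TRUE, warnings = character(0))
  } else {
    fit_logistic(nested_design(data, existing)$x,
                 nested_design(data, integer(0))$y)
  }
  stat <- max(0, 2 * (full$log_likelihood - partial$log_likelihood))
  q <- length(new)
  test_result(c(LR = stat), q, stats::pchisq(stat, q, lower.tail = FALSE),
              "Likelihood ratio test (nested logistic regression)",
              unique(c(full$warnings, partial$warnings)),
              extra = list(fit_full = full, fit_partial = partial))
}

#' Wald test for added biomarkers in the full logistic model
#'
#' Fits the full logistic regression and tests the new coefficients. For a
#' single new biomarker the statistic is the coefficient estimate divided by
#' its standard error, referred two-sided to the standard normal; for `q > 1`
#' the quadratic form of the new-coefficient block against its estimated
#' covariance is referred to chi-square with `q` degrees of freedom.
#'
#' @inheritParams lr_test
#' @return A `"nested_test"`/`"htest"` object. For `q = 1` the statistic is
#'   the `z` ratio (with `df = 1` recorded for the equivalent chi-square
#'   form); for `q > 1` it is the chi-square quadratic form.
#' @export
wald_test <- function(data, existing, new) {
  stopifnot(inherits(data, "two_class_data"))
  existing <- resolve_idx(data, existing)
  new <- resolve_idx(data, new)
  if (length(new) < 1L) stop("need at least one new biomarker", call. = FALSE)
  if (length(intersect(existing, new)) > 0L)
    stop("existing and new biomarker sets must be disjoint", call. = FALSE)
  idx <- c(existing, new)
  des <- nested_design(data, idx)
  full <- fit_logistic(des$x, des$y)
  q <- length(new)
  # positions of the new coefficients (after the intercept)
  pos <- 1L + (length(existing) + 1L):(length(existing) + q)
  w <- full$coefficients[pos]
  vb <- full$coef_cov[pos, pos, drop = FALSE]
  warn <- full$warnings
  if (anyNA(vb)) {
    return(test_result(c(W = NA_real_), q, NA_real_,
                       "Wald test (logistic regression)",
                       unique(c(warn, "degenerate: singular coefficient covariance")),
                       extra = list(fit_full = full)))
  }
  if (q == 1L) {
    z <- unname(w / sqrt(vb[1, 1]))
    test_result(c(z = z), 1L, 2 * stats::pnorm(-abs(z)),
                "Wald test (logistic regression)", warn,
                extra = list(fit_full = full, coefficient = unname(w),
                             se = sqrt(vb[1, 1])))
  } else {
    stat <- tryCatch(drop(crossprod(w, solve(vb, w))), error = function(e) NA_real_)
    if (!is.finite(stat)) {
      test_result(c(W = NA_real_), q, NA_real_,
                  "Wald test (logistic regression)",
                  unique(c(warn, "degenerate: singular coefficient covariance")),
                  extra = list(fit_full = full))
    } else {
      test_result(c(W = stat), q, stats::pchisq(stat, q, lower.tail = FALSE),
                  "Wald test (logistic regression)", warn,
                  extra = list(fit_full = full))
    }
  }
}
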