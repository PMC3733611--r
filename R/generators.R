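#' Two-class multivariate Gaussian specification
#'
#' Population model behind the exact F test: each class is multivariate
#' normal with its own mean vector and a covariance matrix shared by the two
#' classes.
#'
#' @param mean_neg,mean_pos Mean vectors (equal length `d`).
#' @param cov Common `d x d` covariance matrix, symmetric positive definite.
#' @return An object of class `"gaussian_class_spec"` (the Cholesky factor of
#'   `cov` is precomputed for sampling).
#' @export
gaussian_class_spec <- function(mean_neg, mean_pos, cov) {
  mean_neg <- as.numeric(mean_neg); mean_pos <- as.numeric(mean_pos)
  cov <- as.matrix(cov)
  d <- length(mean_neg)
  if (length(mean_pos) != d || !all(dim(cov) == d))
    stop("dimension mismatch between means and covariance", call. = FALSE)
  if (!isSymmetric(cov, tol = 1e-10))
    stop("covariance must be symmetric", call. = FALSE)
  ch <- tryCatch(chol(cov), error = function(e)
    stop("covariance must be positive definite", call. = FALSE))
  structure(
    list(mean_neg = mean_neg, mean_pos = mean_pos, cov = cov,
         chol = ch, d = d,
         identity_cov = isTRUE(all.equal(cov, diag(d), tolerance = 0))),
    class = "gaussian_class_spec"
  )
}

#' Sixteen-biomarker simulation panel
#'
#' The reference two-class Gaussian panel used throughout the Monte Carlo
#' studies: 16 biomarkers, identity covariance in both classes, negative
#' class centered at zero, positive-class mean shifts spanning a range of
#' single-marker performance (0.7 down to 0) with the 16th biomarker — the
#' candidate "new" marker — useless under the null scenario and shifted by
#' 0.6 under the alternative. The implied ideal AUCs of the optimal linear
#' discriminant are 0.8413 for the first 15 markers (squared Mahalanobis
#' distance 2.00) and 0.8413 / 0.8613 for all 16 under null / alternative.
#'
#' @param scenario `"null"` (new marker useless) or `"alternative"` (new
#'   marker adds separation).
#' @return A [gaussian_class_spec()] for the 16 biomarkers.
#' @export
reference_panel_spec <- function(scenario = c("null", "alternative")) {
  scenario <- match.arg(scenario)
  shifts <- c(0.7, 0.6, 0.6, 0.5, 0.5, 0.3, 0.3, 0.2,
              0.2, 0.1, 0.1, 0.1, 0, 0, 0, 0)
  if (scenario == "alternative") shifts[16] <- 0.6
  gaussian_class_spec(rep(0, 16), shifts, diag(16))
}

#' Draw a two-class Gaussian biomarker sample
#'
#' Samples `n0` negative-class and `n1` positive-class subjects from the
#' specified multivariate normal populations. Uses the current RNG stream;
#' fix it with [set.seed()] for reproducibility.
#'
#' @param spec A [gaussian_class_spec()].
#' @param n0,n1 Class sample sizes.
#' @return A [two_class_data()].
#' @export
generate_two_class_gaussian <- function(spec, n0, n1) {
  stopifnot(inherits(spec, "gaussian_class_spec"), n0 >= 1, n1 >= 1)
  d <- spec$d
  zn <- matrix(stats::rnorm(n0 * d), n0, d)
  zp <- matrix(stats::rnorm(n1 * d), n1, d)
  if (!spec$identity_cov) {
    zn <- zn %*% spec$chol
    zp <- zp %*% spec$chol
  }
  if (any(spec$mean_neg != 0)) zn <- sweep(zn, 2, spec$mean_neg, "+")
  if (any(spec$mean_pos != 0)) zp <- sweep(zp, 2, spec$mean_pos, "+")
  two_class_data(zn, zp)
}

#' Bivariate binormal paired-score specification
#'
#' Model for the test scores of two fixed classifiers on common subjects:
#' within each class the score pair is bivariate normal with unit variances
#' and correlation `rho`; class means are `(0, 0)` and `(mu, mu)`. Both
#' models share the binormal AUC `pnorm(mu / sqrt(2))`, so the comparison
#' null hypothesis holds for every `rho` and `mu`.
#'
#' @param rho Within-class correlation of the two models' scores, in
#'   `[-1, 1]`.
#' @param mu Common positive-class mean shift.
#' @return An object of class `"binormal_pair_spec"`.
#' @export
binormal_pair_spec <- function(rho = 0, mu = 0) {
  if (!is.finite(rho) || abs(rho) > 1)
    stop("rho must lie in [-1, 1]", call. = FALSE)
  if (!is.finite(mu)) stop("mu must be finite", call. = FALSE)
  structure(list(rho = rho, mu = mu,
                 auc = stats::pnorm(mu / sqrt(2))),
            class = "binormal_pair_spec")
}

#' Draw paired test scores from the bivariate binormal model
#'
#' @param spec A [binormal_pair_spec()].
#' @param n0,n1 Class sample sizes of the common test set.
#' @return A [paired_score_sample()].
#' @export
generate_paired_binormal_scores <- function(spec, n0, n1) {
  stopifnot(inherits(spec, "binormal_pair_spec"), n0 >= 1, n1 >= 1)
  b <- sqrt(1 - spec$rho^2)
  z1 <- stats::rnorm(n0 + n1)
  z2 <- spec$rho * z1 + b * stats::rnorm(n0 + n1)
  shift <- rep(c(0, spec$mu), c(n0, n1))
  s1 <- z1 + shift; s2 <- z2 + shift
  ineg <- seq_len(n0); ipos <- n0 + seq_len(n1)
  paired_score_sample(s1[ineg], s1[ipos], s2[ineg], s2[ipos])
}
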