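#' Map a squared Mahalanobis distance to the ideal AUC
#'
#' Under the two-class multivariate normal model with a common covariance
#' matrix, the best linear discriminant attains ideal AUC
#' \eqn{A = \Phi(\sqrt{D^2}/\sqrt{2})}, a strictly increasing one-to-one
#' function of the squared Mahalanobis distance \eqn{D^2} between the class
#' means. Equality of ideal AUCs of two nested discriminants is therefore
#' equivalent to equality of their Mahalanobis distances.
#'
#' @param d2 Squared Mahalanobis distance(s), nonnegative.
#' @return Ideal AUC value(s) in `[0.5, 1)`.
#' @seealso [auc_to_mahalanobis()] for the inverse.
#' @examples
#' mahalanobis_to_auc(2.00)   # 0.8413
#' mahalanobis_to_auc(2.36)   # 0.8613
#' @export
mahalanobis_to_auc <- function(d2) {
  if (any(!is.finite(d2)) || any(d2 < 0))
    stop("d2 must be finite and nonnegative", call. = FALSE)
  stats::pnorm(sqrt(d2) / sqrt(2))
}

#' @rdname mahalanobis_to_auc
#' @param auc Ideal AUC value(s) in `[0.5, 1)`.
#' @export
auc_to_mahalanobis <- function(auc) {
  if (any(!is.finite(auc)) || any(auc < 0.5) || any(auc >= 1))
    stop("auc must lie in [0.5, 1)", call. = FALSE)
  (stats::qnorm(auc) * sqrt(2))^2
}

#' Sample squared Mahalanobis distance between two classes
#'
#' \eqn{\hat D^2 = (\bar m_1 - \bar m_0)^T S^{-1} (\bar m_1 - \bar m_0)}
#' restricted to the selected biomarkers, with `S` the pooled within-class
#' sample covariance (denominator `N0 + N1 - 2`).
#'
#' @param data A [two_class_data()].
#' @param idx Biomarker selection: column names or integer indices. `NULL`
#'   selects all biomarkers.
#' @return Nonnegative scalar.
#' @export
sample_mahalanobis_sq <- function(data, idx = NULL) {
  stopifnot(inherits(data, "two_class_data"))
  if (is.null(idx)) idx <- seq_len(data$d)
  idx <- resolve_idx(data, idx)
  if (length(idx) == 0L) return(0)
  k <- length(idx)
  if (data$n0 + data$n1 - 2L <= k)
    stop("need N0 + N1 - 2 > number of biomarkers for a nonsingular ",
         "pooled covariance", call. = FALSE)
  xn <- data$neg_matrix[, idx, drop = FALSE]
  xp <- data$pos_matrix[, idx, drop = FALSE]
  s <- (crossprod(scale(xn, scale = FALSE)) +
          crossprod(scale(xp, scale = FALSE))) / (data$n0 + data$n1 - 2)
  if (rcond(s) < 1e-12)
    stop("pooled covariance is singular or near-singular on the selected ",
         "biomarkers", call. = FALSE)
  d <- colMeans(xp) - colMeans(xn)
  drop(crossprod(d, solve(s, d)))
}

#' Rao's F statistic for an added set of discriminant variables
#'
#' Given sample squared Mahalanobis distances of a partial model on `p`
#' biomarkers and a full model on `p + q`, the statistic
#' \deqn{U = \frac{N_0+N_1-p-q-1}{q}\left(
#'   \frac{1 + c\,\hat D^2_{p+q}}{1 + c\,\hat D^2_{p}} - 1\right),\quad
#'   c = \frac{N_0 N_1}{(N_0+N_1)(N_0+N_1-2)}}
#' follows, exactly under two-class multivariate normality with common
#' covariance and the null hypothesis of no added separation, the F
#' distribution with `q` and `N0 + N1 - p - q - 1` degrees of freedom.
#' The p-value is the upper tail (the test is one-sided by construction).
#'
#' @param d2_partial,d2_full Sample squared Mahalanobis distances of the
#'   nested models; `d2_full >= d2_partial >= 0`.
#' @param n0,n1 Class sample sizes of the training sample.
#' @param p,q Numbers of existing and new biomarkers.
#' @return An object of classes `"rao_ftest"` and `"htest"` with `statistic`,
#'   degrees of freedom in `parameter`, `p.value`, and the two distances.
#' @examples
#' rao_f_statistic(1.0, 1.5, 30, 30, 1, 1)  # U = 5.856 on (1, 57) df
#' @export
rao_f_statistic <- function(d2_partial, d2_full, n0, n1, p, q) {
  stopifnot(is.finite(d2_partial), is.finite(d2_full),
            d2_partial >= 0, q >= 1)
  if (d2_full < d2_partial) {
    if (d2_full < d2_partial - 1e-8)
      stop("d2_full < d2_partial: the models are not nested", call. = FALSE)
    d2_full <- d2_partial   # tolerate rounding at the equality boundary
  }
  df2 <- n0 + n1 - p - q - 1
  if (df2 < 1)
    stop("invalid design: N0 + N1 - p - q - 1 must be at least 1",
         call. = FALSE)
  cc <- n0 * n1 / ((n0 + n1) * (n0 + n1 - 2))
  u <- (df2 / q) * ((1 + cc * d2_full) / (1 + cc * d2_partial) - 1)
  structure(
    list(statistic = c(U = u),
         parameter = c(df1 = q, df2 = df2),
         p.value = stats::pf(u, q, df2, lower.tail = FALSE),
         d2_partial = d2_partial, d2_full = d2_full,
         n0 = n0, n1 = n1, p = p, q = q,
         method = "Exact F test of ideal AUC (Mahalanobis distance) for nested linear discriminants",
         data.name = sprintf("D2(p=%d) = %.4g, D2(p+q=%d) = %.4g, N0 = %d, N1 = %d",
                             p, d2_partial, p + q, d2_full, n0, n1)),
    class = c("rao_ftest", "htest")
  )
}

#' Exact F test of added ideal AUC for nested linear discriminants
#'
#' Tests whether `q` new biomarkers increase the ideal AUC of the optimal
#' linear discriminant beyond that of `p` existing biomarkers, assuming
#' two-class multivariate normal data with a common covariance matrix. The
#' test is carried out on the equivalent Mahalanobis-distance scale: sample
#' distances are computed for the partial and full panels from the training
#' data and referred to Rao's exact F distribution. Only training data are
#' used; the test is exact at any sample size satisfying the design
#' constraint `N0 + N1 - p - q - 1 >= 1`.
#'
#' @param data A [two_class_data()] training sample.
#' @param existing Columns (names or indices) of the existing biomarkers;
#'   may be empty (`NULL`) for a pure separation test.
#' @param new Columns of the new biomarkers (disjoint from `existing`).
#' @return A `"rao_ftest"`/`"htest"` object as from [rao_f_statistic()], with
#'   the sample ideal-AUC estimates of both panels attached
#'   (`auc_partial`, `auc_full`, via [mahalanobis_to_auc()]).
#' @export
ideal_auc_f_test <- function(data, existing, new) {
  stopifnot(inherits(data, "two_class_data"))
  existing <- resolve_idx(data, existing)
  new <- resolve_idx(data, new)
  if (length(new) < 1L) stop("need at least one new biomarker", call. = FALSE)
  if (length(intersect(existing, new)) > 0L)
    stop("existing and new biomarker sets must be disjoint", call. = FALSE)
  d2p <- if (length(existing) == 0L) 0 else sample_mahalanobis_sq(data, existing)
  d2f <- sample_mahalanobis_sq(data, c(existing, new))
  res <- rao_f_statistic(d2p, d2f, data$n0, data$n1,
                         length(existing), length(new))
  res$auc_partial <- mahalanobis_to_auc(res$d2_partial)
  res$auc_full <- mahalanobis_to_auc(res$d2_full)
  res
}
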