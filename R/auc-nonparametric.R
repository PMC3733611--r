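#' Mann-Whitney kernel for the nonparametric AUC
#'
#' The kernel scores a (negative, positive) score pair: 1 when the positive
#' subject scores higher, 1/2 on a tie, 0 otherwise. The nonparametric AUC
#' is the average of this kernel over all between-class pairs.
#'
#' @param x Scores of negative-class subjects (recycled against `y`).
#' @param y Scores of positive-class subjects.
#' @return Numeric vector with values in `{0, 0.5, 1}`.
#' @examples
#' auc_kernel(c(1, 2, 3), c(2, 2, 2))
#' @export
auc_kernel <- function(x, y) {
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("scores must be finite", call. = FALSE)
  (x < y) + 0.5 * (x == y)
}

#' Nonparametric (trapezoidal / Mann-Whitney) AUC estimate
#'
#' Computes the empirical AUC of a score sample as the fraction of
#' negative/positive pairs ranked correctly, ties counted half. Evaluated
#' via midranks in O(n log n), exactly equal to the all-pairs kernel average.
#'
#' @param sample A [score_sample()].
#' @return AUC estimate in `[0, 1]`.
#' @export
estimate_auc <- function(sample) {
  stopifnot(inherits(sample, "score_sample"))
  n0 <- sample$n0; n1 <- sample$n1
  r <- rank(c(sample$neg_scores, sample$pos_scores), ties.method = "average")
  (sum(r[(n0 + 1):(n0 + n1)]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

# Per-subject kernel row/column sums via midranks (exact under ties).
# Returns rowsums r_i = sum_j psi(X_i, Y_j) and colsums c_j = sum_i psi(X_i, Y_j).
psi_margin_sums <- function(x, y) {
  n0 <- length(x); n1 <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  # colsum over i for each Y_j: #(X < Y_j) + 0.5 #(X = Y_j)
  c_j <- r_all[(n0 + 1):(n0 + n1)] - rank(y, ties.method = "average")
  # rowsum over j for each X_i: #(Y > X_i) + 0.5 #(Y = X_i)
  r_i <- n1 - (r_all[seq_len(n0)] - rank(x, ties.method = "average"))
  list(rowsums = r_i, colsums = c_j)
}

# Number of tied between-class pairs #{(i,j): X_i == Y_j}, via sorted runs.
tie_cross_count <- function(x, y) {
  z <- c(x, y)
  is_pos <- rep(c(FALSE, TRUE), c(length(x), length(y)))
  o <- order(z)
  zs <- z[o]; ps <- is_pos[o]
  grp <- cumsum(c(1L, diff(zs) != 0))
  nx <- tapply(!ps, grp, sum)
  ny <- tapply(ps, grp, sum)
  sum(nx * ny)
}

#' Structural components of the nonparametric AUC
#'
#' Sen's per-subject structural components: for each negative subject the
#' average kernel against all positive subjects, and vice versa. Their
#' sample variances drive the DeLong variance and covariance estimators.
#'
#' @param sample A [score_sample()] with at least two subjects per class.
#' @return List with `v01` (length N0, negative-class components) and `v10`
#'   (length N1, positive-class components); both average to the AUC.
#' @export
structural_components <- function(sample) {
  stopifnot(inherits(sample, "score_sample"))
  if (sample$n0 < 2L || sample$n1 < 2L)
    stop("need at least 2 subjects per class for structural components",
         call. = FALSE)
  ms <- psi_margin_sums(sample$neg_scores, sample$pos_scores)
  list(v01 = ms$rowsums / sample$n1, v10 = ms$colsums / sample$n0)
}

#' DeLong variance of the nonparametric AUC
#'
#' Structural-components estimator of `Var(AUC-hat)`: sample variances of the
#' per-subject components with (n-1) denominators, scaled by class sizes.
#' First-order (the second-order term of the U-statistics variance
#' decomposition is dropped); always nonnegative.
#'
#' @param sample A [score_sample()] with at least two subjects per class.
#' @return Nonnegative variance estimate.
#' @seealso [ustat_variance()] for the unbiased estimator.
#' @export
delong_variance <- function(sample) {
  sc <- structural_components(sample)
  stats::var(sc$v01) / sample$n0 + stats::var(sc$v10) / sample$n1
}

#' Unbiased U-statistics variance of the nonparametric AUC
#'
#' Estimates the exact two-sample U-statistic variance
#' \deqn{Var(\hat A) = \frac{N_0-1}{N_0 N_1}\xi_{01} +
#'   \frac{N_1-1}{N_0 N_1}\xi_{10} + \frac{1}{N_0 N_1}\xi_{11}}
#' with each \eqn{\xi} term replaced by its unbiased estimator: expectations
#' of kernel products are averaged over index tuples with the required
#' indices distinct, and the squared AUC is estimated unbiasedly by the
#' average of \eqn{\psi(X_i,Y_j)\psi(X_{i'},Y_{j'})} over \eqn{i \ne i'},
#' \eqn{j \ne j'}. Computed in closed form from kernel row/column sums;
#' identical to the literal enumeration over index tuples. Unlike the
#' first-order DeLong estimator the result can be negative in tiny samples.
#'
#' @param sample A [score_sample()] with at least two subjects per class.
#' @return List with `variance` and the component estimates `xi01`, `xi10`,
#'   `xi11`.
#' @export
ustat_variance <- function(sample) {
  stopifnot(inherits(sample, "score_sample"))
  n0 <- sample$n0; n1 <- sample$n1
  if (n0 < 2L || n1 < 2L)
    stop("need at least 2 subjects per class for the U-statistics variance",
         call. = FALSE)
  ms <- psi_margin_sums(sample$neg_scores, sample$pos_scores)
  p_sum <- sum(ms$colsums)
  ties <- tie_cross_count(sample$neg_scores, sample$pos_scores)
  s2 <- p_sum - 0.25 * ties              # sum of psi^2 (psi^2 = psi - 0.25 on ties)
  q01 <- sum(ms$colsums^2)               # sum over (i, i', j) of psi_ij psi_i'j
  q10 <- sum(ms$rowsums^2)
  m01 <- (q01 - s2) / (n1 * n0 * (n0 - 1))
  m10 <- (q10 - s2) / (n0 * n1 * (n1 - 1))
  m11 <- s2 / (n0 * n1)
  m00 <- (p_sum^2 - q01 - q10 + s2) / (n0 * (n0 - 1) * n1 * (n1 - 1))
  xi01 <- m01 - m00
  xi10 <- m10 - m00
  xi11 <- m11 - m00
  list(variance = ((n0 - 1) * xi01 + (n1 - 1) * xi10 + xi11) / (n0 * n1),
       xi01 = xi01, xi10 = xi10, xi11 = xi11)
}

# Variance/covariance building blocks for two models scored on a common test
# set. Kernel matrices are processed in column blocks to bound memory.
# Returns AUCs plus DeLong and U-statistics variances and covariances.
auc_compare_stats <- function(x1, y1, x2, y2) {
  n0 <- length(x1); n1 <- length(y1)
  block <- max(1L, floor(1e6 / n0))
  r1 <- numeric(n0); r2 <- numeric(n0)    # kernel row sums per model
  c1 <- numeric(n1); c2 <- numeric(n1)    # kernel column sums per model
  s2_1 <- 0; s2_2 <- 0; s2c <- 0          # sums of psi^2 and psi1*psi2
  j <- 1L
  while (j <= n1) {
    jj <- j:min(n1, j + block - 1L)
    p1 <- outer(x1, y1[jj], "<") + 0.5 * outer(x1, y1[jj], "==")
    p2 <- outer(x2, y2[jj], "<") + 0.5 * outer(x2, y2[jj], "==")
    r1 <- r1 + rowSums(p1); r2 <- r2 + rowSums(p2)
    c1[jj] <- colSums(p1); c2[jj] <- colSums(p2)
    s2_1 <- s2_1 + sum(p1 * p1); s2_2 <- s2_2 + sum(p2 * p2)
    s2c <- s2c + sum(p1 * p2)
    j <- j + block
  }
  p1_sum <- sum(c1); p2_sum <- sum(c2)
  a1 <- p1_sum / (n0 * n1); a2 <- p2_sum / (n0 * n1)

  # DeLong: sample (co)variances of the structural components
  v01_1 <- r1 / n1; v01_2 <- r2 / n1
  v10_1 <- c1 / n0; v10_2 <- c2 / n0
  var1_d <- stats::var(v01_1) / n0 + stats::var(v10_1) / n1
  var2_d <- stats::var(v01_2) / n0 + stats::var(v10_2) / n1
  cov_d <- stats::cov(v01_1, v01_2) / n0 + stats::cov(v10_1, v10_2) / n1

  # U-statistics: unbiased xi / cross-model zeta terms from the same sums
  ust <- function(qa, qb, s2, pa, pb) {
    m01 <- (qa - s2) / (n1 * n0 * (n0 - 1))
    m10 <- (qb - s2) / (n0 * n1 * (n1 - 1))
    m11 <- s2 / (n0 * n1)
    m00 <- (pa * pb - qa - qb + s2) / (n0 * (n0 - 1) * n1 * (n1 - 1))
    ((n0 - 1) * (m01 - m00) + (n1 - 1) * (m10 - m00) + (m11 - m00)) /
      (n0 * n1)
  }
  var1_u <- ust(sum(c1^2), sum(r1^2), s2_1, p1_sum, p1_sum)
  var2_u <- ust(sum(c2^2), sum(r2^2), s2_2, p2_sum, p2_sum)
  cov_u <- ust(sum(c1 * c2), sum(r1 * r2), s2c, p1_sum, p2_sum)

  list(auc1 = a1, auc2 = a2,
       delong = c(var1 = var1_d, var2 = var2_d, cov = cov_d),
       ustat = c(var1 = var1_u, var2 = var2_u, cov = cov_u))
}

# z test assembly shared by compare_auc() and the Monte Carlo harness
auc_z_test <- function(a1, a2, var1, var2, cov12) {
  diff <- a1 - a2
  se2 <- unname(var1 + var2 - 2 * cov12)
  if (!is.finite(se2) || se2 <= 0) {
    # clamped or degenerate comparison: no usable evidence of a difference
    return(list(diff = diff, se = 0, z = NA_real_, p = 1, degenerate = TRUE))
  }
  se <- sqrt(se2)
  z <- diff / se
  list(diff = diff, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
       degenerate = FALSE)
}

#' Compare two correlated AUCs on a common test set
#'
#' Tests equality of the true (conditional-on-training) AUCs of two fixed
#' models scored on the same subjects. The statistic is the AUC difference
#' divided by its standard error; the variance of the difference combines the
#' per-model variances and the cross-model covariance induced by the shared
#' test set, estimated either by the DeLong structural-components method or
#' by unbiased U-statistics. Two-sided p-value from the standard normal.
#'
#' Both models must be trained (or otherwise fixed) independently of the test
#' scores supplied here; the variance estimators account only for test-set
#' sampling, not for retraining.
#'
#' @param paired A [paired_score_sample()].
#' @param method `"delong"` (structural components, first-order) or `"ustat"`
#'   (unbiased U-statistics variance/covariance).
#' @return An object of classes `"auc_comparison"` and `"htest"`: AUCs,
#'   difference, standard error, `z`, two-sided `p.value`, and a `degenerate`
#'   flag (set when the clamped variance of the difference is zero, in which
#'   case `p.value = 1`).
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- rnorm(50) + 1
#' ps <- paired_score_sample(x, y, x + rnorm(50, sd = .3), y + rnorm(50, sd = .3))
#' compare_auc(ps, method = "delong")
#' @export
compare_auc <- function(paired, method = c("delong", "ustat")) {
  stopifnot(inherits(paired, "paired_score_sample"))
  method <- match.arg(method)
  if (paired$n0 < 2L || paired$n1 < 2L)
    stop("need at least 2 subjects per class to compare AUCs", call. = FALSE)
  st <- auc_compare_stats(paired$model1$neg_scores, paired$model1$pos_scores,
                          paired$model2$neg_scores, paired$model2$pos_scores)
  vv <- st[[method]]
  zt <- auc_z_test(st$auc1, st$auc2, vv["var1"], vv["var2"], vv["cov"])
  structure(
    list(statistic = c(z = zt$z),
         p.value = zt$p,
         estimate = c(`AUC model 1` = st$auc1, `AUC model 2` = st$auc2),
         auc_1 = st$auc1, auc_2 = st$auc2,
         diff = zt$diff, se_diff = zt$se,
         variance_1 = unname(vv["var1"]), variance_2 = unname(vv["var2"]),
         covariance = unname(vv["cov"]),
         degenerate = zt$degenerate,
         n0 = paired$n0, n1 = paired$n1,
         alternative = "two.sided",
         method = sprintf("Correlated AUC comparison (%s variance estimator)",
                          method),
         variance_method = method,
         data.name = sprintf("paired scores (N0 = %d, N1 = %d)",
                             paired$n0, paired$n1)),
    class = c("auc_comparison", "htest")
  )
}
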