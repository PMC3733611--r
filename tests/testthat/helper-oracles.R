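# Brute-force oracles, kept deliberately literal (double/quadruple loops over
# index tuples) and independent of the package's optimized implementations.

bf_kernel <- function(x, y) {
  if (x < y) 1 else if (x == y) 0.5 else 0
}

# all-pairs kernel average
bf_auc <- function(x, y) {
  s <- 0
  for (xi in x) for (yj in y) s <- s + bf_kernel(xi, yj)
  s / (length(x) * length(y))
}

bf_components <- function(x, y) {
  v01 <- vapply(x, function(xi) mean(vapply(y, function(yj)
    bf_kernel(xi, yj), 0)), 0)
  v10 <- vapply(y, function(yj) mean(vapply(x, function(xi)
    bf_kernel(xi, yj), 0)), 0)
  list(v01 = v01, v10 = v10)
}

bf_delong_variance <- function(x, y) {
  cmp <- bf_components(x, y)
  var(cmp$v01) / length(x) + var(cmp$v10) / length(y)
}

# literal index-tuple enumeration of the unbiased U-statistics variance
bf_ustat_variance <- function(x, y) {
  n0 <- length(x); n1 <- length(y)
  psi <- outer(x, y, Vectorize(bf_kernel))
  m01 <- 0; m10 <- 0; m11 <- 0; m00 <- 0
  for (i in 1:n0) for (ip in 1:n0) for (j in 1:n1) {
    if (i != ip) m01 <- m01 + psi[i, j] * psi[ip, j]
  }
  m01 <- m01 / (n0 * (n0 - 1) * n1)
  for (i in 1:n0) for (j in 1:n1) for (jp in 1:n1) {
    if (j != jp) m10 <- m10 + psi[i, j] * psi[i, jp]
  }
  m10 <- m10 / (n0 * n1 * (n1 - 1))
  m11 <- mean(psi^2)
  for (i in 1:n0) for (ip in 1:n0) for (j in 1:n1) for (jp in 1:n1) {
    if (i != ip && j != jp) m00 <- m00 + psi[i, j] * psi[ip, jp]
  }
  m00 <- m00 / (n0 * (n0 - 1) * n1 * (n1 - 1))
  xi01 <- m01 - m00; xi10 <- m10 - m00; xi11 <- m11 - m00
  list(variance = ((n0 - 1) * xi01 + (n1 - 1) * xi10 + xi11) / (n0 * n1),
       xi01 = xi01, xi10 = xi10, xi11 = xi11)
}

# literal enumeration of the unbiased cross-model covariance terms
bf_ustat_covariance <- function(x1, y1, x2, y2) {
  n0 <- length(x1); n1 <- length(y1)
  p1 <- outer(x1, y1, Vectorize(bf_kernel))
  p2 <- outer(x2, y2, Vectorize(bf_kernel))
  m01 <- 0; m10 <- 0; m00 <- 0
  for (i in 1:n0) for (ip in 1:n0) for (j in 1:n1) {
    if (i != ip) m01 <- m01 + p1[i, j] * p2[ip, j]
  }
  m01 <- m01 / (n0 * (n0 - 1) * n1)
  for (i in 1:n0) for (j in 1:n1) for (jp in 1:n1) {
    if (j != jp) m10 <- m10 + p1[i, j] * p2[i, jp]
  }
  m10 <- m10 / (n0 * n1 * (n1 - 1))
  m11 <- mean(p1 * p2)
  for (i in 1:n0) for (ip in 1:n0) for (j in 1:n1) for (jp in 1:n1) {
    if (i != ip && j != jp) m00 <- m00 + p1[i, j] * p2[ip, jp]
  }
  m00 <- m00 / (n0 * (n0 - 1) * n1 * (n1 - 1))
  ((n0 - 1) * (m01 - m00) + (n1 - 1) * (m10 - m00) + (m11 - m00)) / (n0 * n1)
}

# direct linear-algebra Mahalanobis oracle via explicit matrix inverse
bf_mahalanobis_sq <- function(neg, pos) {
  s <- ((nrow(neg) - 1) * cov(neg) + (nrow(pos) - 1) * cov(pos)) /
    (nrow(neg) + nrow(pos) - 2)
  d <- colMeans(pos) - colMeans(neg)
  drop(t(d) %*% solve(s) %*% d)
}

# independent ML oracle: direct numerical maximization of the hand-coded
# logistic log-likelihood (not IRLS)
bf_logistic_loglik <- function(x, y) {
  xm <- cbind(1, x)
  nll <- function(b) {
    eta <- drop(xm %*% b)
    -sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
  }
  fit <- optim(rep(0, ncol(xm)), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  -fit$value
}

# small random score sample with occasional ties
random_tied_sample <- function(n0, n1) {
  pool <- sample(seq_len(n0 + n1), n0 + n1, replace = TRUE) / 2
  list(x = pool[seq_len(n0)] + sample(c(0, 0.25), n0, replace = TRUE),
       y = pool[n0 + seq_len(n1)] + sample(c(0, 0.25), n1, replace = TRUE))
}
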