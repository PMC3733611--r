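# Monte Carlo summary container shared by the experiment drivers
mc_summary <- function(results, n_trials, alpha, seed, experiment, params) {
  results$mc_se <- sqrt(results$rejection_fraction *
                          (1 - results$rejection_fraction) / n_trials)
  structure(
    list(results = results, n_trials = n_trials, alpha = alpha,
         seed = seed, experiment = experiment, params = params),
    class = "mc_summary"
  )
}

#' @export
print.mc_summary <- function(x, ...) {
  cat("Monte Carlo experiment:", x$experiment, "\n")
  cat("  trials:", x$n_trials, " alpha:", x$alpha,
      if (!is.null(x$seed)) paste(" seed:", x$seed) else "", "\n")
  cat("  parameters:",
      paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
      "\n")
  df <- x$results
  df$rejection_fraction <- sprintf("%.4f", df$rejection_fraction)
  df$mc_se <- sprintf("%.4f", df$mc_se)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Type I error / power study of the nested-model added-value tests
#'
#' Repeats, for `n_trials` Monte Carlo trials: draw a two-class Gaussian
#' training sample from the 16-biomarker reference panel, then test whether
#' the 16th biomarker adds value to the first 15 with any subset of the
#' likelihood ratio, Wald, and exact F tests. All requested tests see the
#' identical drawn dataset within a trial. The fraction of p-values below
#' `alpha` is the observed type I error under the `"null"` scenario and the
#' power under `"alternative"`. Trials in which a logistic fit hit
#' separation or failed to converge are counted with their achieved
#' p-values and tallied in `flagged`; a test returning `NA` (degenerate
#' Wald covariance) counts as a non-rejection.
#'
#' @param n0,n1 Class sample sizes of each training draw.
#' @param scenario `"null"` or `"alternative"` (see [reference_panel_spec()]).
#' @param n_trials Number of Monte Carlo trials (20,000 for the full study).
#' @param alpha Significance level.
#' @param tests Subset of `c("lr", "wald", "f")`.
#' @param seed Optional integer seed; when supplied the run is exactly
#'   reproducible.
#' @param spec Alternative [gaussian_class_spec()]; defaults to the
#'   reference panel for the chosen scenario.
#' @param existing,new Biomarker index sets under test.
#' @return An `"mc_summary"` with one row per test: rejection fraction,
#'   binomial Monte Carlo standard error, flagged-trial count.
#' @export
run_added_value_experiment <- function(n0, n1,
                                       scenario = c("null", "alternative"),
                                       n_trials = 20000, alpha = 0.05,
                                       tests = c("lr", "wald", "f"),
                                       seed = NULL, spec = NULL,
                                       existing = 1:15, new = 16) {
  scenario <- match.arg(scenario)
  tests <- match.arg(tests, c("lr", "wald", "f"), several.ok = TRUE)
  stopifnot(n_trials >= 1, alpha > 0, alpha <= 1)
  if (is.null(spec)) spec <- reference_panel_spec(scenario)
  if (!is.null(seed)) set.seed(seed)
  existing <- as.integer(existing); new <- as.integer(new)
  idx_full <- c(existing, new)
  p <- length(existing); q <- length(new)
  need_logistic <- any(c("lr", "wald") %in% tests)
  need_partial_fit <- "lr" %in% tests
  rej <- stats::setNames(numeric(length(tests)), tests)
  flagged <- stats::setNames(integer(length(tests)), tests)
  y <- rep(c(0, 1), c(n0, n1))

  for (trial in seq_len(n_trials)) {
    dat <- generate_two_class_gaussian(spec, n0, n1)
    if ("f" %in% tests) {
      d2p <- if (p == 0) 0 else sample_mahalanobis_sq(dat, existing)
      d2f <- sample_mahalanobis_sq(dat, idx_full)
      ft <- rao_f_statistic(max(d2p, 0), max(d2f, d2p), n0, n1, p, q)
      if (ft$p.value < alpha) rej["f"] <- rej["f"] + 1
    }
    if (need_logistic) {
      xfull <- rbind(dat$neg_matrix[, idx_full, drop = FALSE],
                     dat$pos_matrix[, idx_full, drop = FALSE])
      full <- fit_logistic(xfull, y)
      if ("wald" %in% tests) {
        pos <- 1L + p + seq_len(q)
        vb <- full$coef_cov[pos, pos, drop = FALSE]
        if (anyNA(vb)) {
          flagged["wald"] <- flagged["wald"] + 1L
        } else {
          w <- full$coefficients[pos]
          pw <- if (q == 1L) 2 * stats::pnorm(-abs(w / sqrt(vb[1, 1])))
          else stats::pchisq(drop(crossprod(w, solve(vb, w))), q,
                             lower.tail = FALSE)
          if (is.finite(pw) && pw < alpha) rej["wald"] <- rej["wald"] + 1
          if (full$separation) flagged["wald"] <- flagged["wald"] + 1L
        }
      }
      if ("lr" %in% tests) {
        lr_flag <- full$separation
        ll_part <- if (p == 0) {
          ph <- mean(y)
          sum(y * log(ph) + (1 - y) * log(1 - ph))
        } else {
          partial <- fit_logistic(xfull[, seq_len(p), drop = FALSE], y)
          lr_flag <- lr_flag || partial$separation
          partial$log_likelihood
        }
        stat <- max(0, 2 * (full$log_likelihood - ll_part))
        if (stats::pchisq(stat, q, lower.tail = FALSE) < alpha)
          rej["lr"] <- rej["lr"] + 1
        if (lr_flag) flagged["lr"] <- flagged["lr"] + 1L
      }
    }
  }
  mc_summary(
    data.frame(test = tests, rejection_fraction = unname(rej[tests]) / n_trials,
               flagged = unname(flagged[tests])),
    n_trials, alpha, seed, "added-value (LR / Wald / F) study",
    list(n0 = n0, n1 = n1, scenario = scenario, p = p, q = q)
  )
}

#' Null-behavior study of the correlated-AUC comparison tests
#'
#' Repeats, for `n_trials` trials: draw a common test set of paired scores
#' for two fixed models from the bivariate binormal model (both models share
#' the same true AUC, so the comparison null hypothesis holds), apply the
#' correlated-AUC z test with the DeLong and/or unbiased U-statistics
#' variance estimators, and record the fraction of two-sided p-values below
#' `alpha` — the observed type I error. Degenerate comparisons (clamped zero
#' variance of the difference) count as non-rejections and are tallied.
#'
#' @param n0,n1 Class sizes of each drawn test set.
#' @param rho Within-class correlation of the two models' scores.
#' @param mu Common positive-class mean shift (true AUC `pnorm(mu/sqrt(2))`).
#' @param methods Subset of `c("delong", "ustat")`.
#' @inheritParams run_added_value_experiment
#' @return An `"mc_summary"` with one row per variance method.
#' @export
run_auc_comparison_experiment <- function(n0, n1, rho = 0, mu = 0,
                                          n_trials = 20000, alpha = 0.05,
                                          methods = c("delong", "ustat"),
                                          seed = NULL) {
  methods <- match.arg(methods, c("delong", "ustat"), several.ok = TRUE)
  stopifnot(n_trials >= 1, alpha > 0, alpha <= 1)
  spec <- binormal_pair_spec(rho = rho, mu = mu)
  if (!is.null(seed)) set.seed(seed)
  rej <- stats::setNames(numeric(length(methods)), methods)
  flagged <- stats::setNames(integer(length(methods)), methods)
  for (trial in seq_len(n_trials)) {
    ps <- generate_paired_binormal_scores(spec, n0, n1)
    st <- auc_compare_stats(ps$model1$neg_scores, ps$model1$pos_scores,
                            ps$model2$neg_scores, ps$model2$pos_scores)
    for (m in methods) {
      vv <- st[[m]]
      zt <- auc_z_test(st$auc1, st$auc2, vv["var1"], vv["var2"], vv["cov"])
      if (zt$degenerate) flagged[m] <- flagged[m] + 1L
      else if (zt$p < alpha) rej[m] <- rej[m] + 1
    }
  }
  mc_summary(
    data.frame(test = methods,
               rejection_fraction = unname(rej[methods]) / n_trials,
               flagged = unname(flagged[methods])),
    n_trials, alpha, seed, "correlated-AUC comparison null study",
    list(n0 = n0, n1 = n1, rho = rho, mu = mu)
  )
}

#' Learning-curve ("antler") study of AUC estimators
#'
#' Characterizes, as a function of training sample size, three estimators of
#' a trained logistic regression model's AUC: resubstitution (test on the
#' training data; optimistically biased for the ideal AUC), a small
#' independent test set, and a large independent test set (pessimistically
#' biased for the ideal AUC, since the finite training sample yields a
#' suboptimal model). Training data are drawn from the 15 existing
#' biomarkers of the reference panel, whose optimal linear model has ideal
#' AUC 0.8413; each training size is split equally between the classes.
#'
#' @param train_sizes Total training sizes (split equally between classes).
#' @param n_reps Monte Carlo repetitions per size (independent retraining).
#' @param small_test_per_class,large_test_per_class Per-class sizes of the
#'   two independent test sets.
#' @param n_markers Number of leading reference-panel biomarkers to use.
#' @param seed Optional integer seed.
#' @return An object of class `"learning_curve"`: a `summary` data frame
#'   (size, estimator, mean and SD of AUC), the `ideal_auc` reference,
#'   flagged (separated/nonconverged) fit counts per size, and the settings.
#' @export
run_learning_curve <- function(train_sizes = c(60, 120, 240, 360, 480),
                               n_reps = 1000,
                               small_test_per_class = 60,
                               large_test_per_class = 10000,
                               n_markers = 15, seed = NULL) {
  stopifnot(all(train_sizes >= 4), n_reps >= 1)
  spec16 <- reference_panel_spec("null")
  idx <- seq_len(n_markers)
  spec <- gaussian_class_spec(spec16$mean_neg[idx], spec16$mean_pos[idx],
                              spec16$cov[idx, idx, drop = FALSE])
  ideal <- mahalanobis_to_auc(
    drop(crossprod(spec$mean_pos - spec$mean_neg,
                   solve(spec$cov, spec$mean_pos - spec$mean_neg))))
  if (!is.null(seed)) set.seed(seed)
  estimators <- c("resubstitution", "small_test", "large_test")
  out <- vector("list", length(train_sizes))
  flagged <- integer(length(train_sizes))
  score_auc <- function(fit, dat) {
    w <- fit$coefficients[-1]
    score_sample(drop(dat$neg_matrix %*% w), drop(dat$pos_matrix %*% w))
  }
  for (k in seq_along(train_sizes)) {
    n_half <- floor(train_sizes[k] / 2)
    aucs <- matrix(NA_real_, n_reps, 3,
                   dimnames = list(NULL, estimators))
    for (r in seq_len(n_reps)) {
      train <- generate_two_class_gaussian(spec, n_half,
                                           train_sizes[k] - n_half)
      fit <- fit_logistic(rbind(train$neg_matrix, train$pos_matrix),
                          rep(c(0, 1), c(train$n0, train$n1)))
      if (fit$separation) flagged[k] <- flagged[k] + 1L
      small <- generate_two_class_gaussian(spec, small_test_per_class,
                                           small_test_per_class)
      large <- generate_two_class_gaussian(spec, large_test_per_class,
                                           large_test_per_class)
      aucs[r, ] <- c(estimate_auc(score_auc(fit, train)),
                     estimate_auc(score_auc(fit, small)),
                     estimate_auc(score_auc(fit, large)))
    }
    out[[k]] <- data.frame(
      train_size = train_sizes[k], estimator = estimators,
      mean_auc = colMeans(aucs), sd_auc = apply(aucs, 2, stats::sd),
      row.names = NULL)
  }
  structure(
    list(summary = do.call(rbind, out), ideal_auc = ideal,
         n_reps = n_reps, train_sizes = train_sizes,
         flagged_fits = stats::setNames(flagged, train_sizes),
         small_test_per_class = small_test_per_class,
         large_test_per_class = large_test_per_class, seed = seed),
    class = "learning_curve"
  )
}

#' @export
print.learning_curve <- function(x, ...) {
  cat("Learning-curve study:", x$n_reps, "repetitions per size; ideal AUC",
      sprintf("%.4f", x$ideal_auc), "\n")
  df <- x$summary
  df$mean_auc <- sprintf("%.4f", df$mean_auc)
  df$sd_auc <- sprintf("%.4f", df$sd_auc)
  print(df, row.names = FALSE)
  if (any(x$flagged_fits > 0))
    cat("  flagged (separated/nonconverged) fits per size:",
        paste(names(x$flagged_fits), x$flagged_fits, sep = ":",
              collapse = " "), "\n")
  invisible(x)
}

#' Plot a learning-curve study as an antler plot
#'
#' Mean AUC (error bars: +/- 1 SD) of the three estimators against training
#' size, with the ideal AUC as a horizontal reference. The resubstitution
#' branch sits above the reference and the independent-test branches below,
#' converging as the training sample grows.
#'
#' @param x A `"learning_curve"` object from [run_learning_curve()].
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot_learning_curve <- function(x, ...) {
  stopifnot(inherits(x, "learning_curve"))
  df <- x$summary
  ests <- c("resubstitution", "small_test", "large_test")
  cols <- c(resubstitution = "firebrick", small_test = "steelblue",
            large_test = "darkgreen")
  offs <- c(resubstitution = -4, small_test = 0, large_test = 4)
  ylim <- range(df$mean_auc - df$sd_auc, df$mean_auc + df$sd_auc, x$ideal_auc)
  graphics::plot(NA, xlim = range(df$train_size) + c(-10, 10), ylim = ylim,
                 xlab = "training sample size (total)", ylab = "AUC", ...)
  graphics::abline(h = x$ideal_auc, lty = 2)
  for (e in ests) {
    sub <- df[df$estimator == e, ]
    xs <- sub$train_size + offs[e]
    graphics::lines(xs, sub$mean_auc, col = cols[e], type = "b", pch = 19)
    graphics::arrows(xs, sub$mean_auc - sub$sd_auc,
                     xs, sub$mean_auc + sub$sd_auc,
                     angle = 90, code = 3, length = 0.03, col = cols[e])
  }
  graphics::legend("bottomright", legend = ests, col = cols[ests],
                   pch = 19, lty = 1, bty = "n")
  invisible(x)
}
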