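#' Two-class test-score sample
#'
#' Bundles the test scores of the actually negative subjects (`X_i`,
#' `i = 1..N0`) and the actually positive subjects (`Y_j`, `j = 1..N1`)
#' on which the nonparametric AUC and its variance are computed.
#'
#' @param neg_scores Numeric vector of scores for the actually negative class.
#' @param pos_scores Numeric vector of scores for the actually positive class.
#' @return An object of class `"score_sample"`: a list with elements
#'   `neg_scores`, `pos_scores`, `n0`, `n1`.
#' @seealso [estimate_auc()], [delong_variance()], [ustat_variance()]
#' @examples
#' s <- score_sample(c(1, 3), c(2, 4))
#' estimate_auc(s)
#' @export
score_sample <- function(neg_scores, pos_scores) {
  neg_scores <- as.numeric(neg_scores)
  pos_scores <- as.numeric(pos_scores)
  if (length(neg_scores) < 1L || length(pos_scores) < 1L)
    stop("both classes must contain at least one score", call. = FALSE)
  if (!all(is.finite(neg_scores)) || !all(is.finite(pos_scores)))
    stop("all scores must be finite", call. = FALSE)
  structure(
    list(neg_scores = neg_scores, pos_scores = pos_scores,
         n0 = length(neg_scores), n1 = length(pos_scores)),
    class = "score_sample"
  )
}

#' @export
print.score_sample <- function(x, ...) {
  cat("Two-class score sample: N0 =", x$n0, "negative, N1 =", x$n1,
      "positive\n")
  cat("  nonparametric AUC:", format(estimate_auc(x), digits = 4), "\n")
  invisible(x)
}

#' Paired scores of two models on a common test set
#'
#' Holds the test scores of two fixed classification models evaluated on the
#' same subjects, the setting in which two correlated AUCs are compared.
#' Pairing is by subject: `neg_scores_1[i]` and `neg_scores_2[i]` belong to
#' the same actually negative subject.
#'
#' @param neg_scores_1,pos_scores_1 Scores of model 1 per class.
#' @param neg_scores_2,pos_scores_2 Scores of model 2 per class.
#' @return An object of class `"paired_score_sample"`.
#' @seealso [compare_auc()]
#' @export
paired_score_sample <- function(neg_scores_1, pos_scores_1,
                                neg_scores_2, pos_scores_2) {
  s1 <- score_sample(neg_scores_1, pos_scores_1)
  s2 <- score_sample(neg_scores_2, pos_scores_2)
  if (s1$n0 != s2$n0 || s1$n1 != s2$n1)
    stop("the two models must score the same subjects (equal class sizes)",
         call. = FALSE)
  structure(list(model1 = s1, model2 = s2, n0 = s1$n0, n1 = s1$n1),
            class = "paired_score_sample")
}

#' @export
print.paired_score_sample <- function(x, ...) {
  cat("Paired score sample (common test set): N0 =", x$n0, ", N1 =", x$n1,
      "\n")
  cat("  AUC model 1:", format(estimate_auc(x$model1), digits = 4),
      " AUC model 2:", format(estimate_auc(x$model2), digits = 4), "\n")
  invisible(x)
}

#' Two-class multivariate biomarker data
#'
#' Raw biomarker measurements for the two classes, one row per subject and
#' one column per biomarker. Input container for the nested-model added-value
#' tests ([ideal_auc_f_test()], [lr_test()], [wald_test()]).
#'
#' @param neg_matrix Numeric matrix (N0 x d) for the actually negative class.
#' @param pos_matrix Numeric matrix (N1 x d) for the actually positive class.
#' @return An object of class `"two_class_data"`.
#' @export
two_class_data <- function(neg_matrix, pos_matrix) {
  neg_matrix <- as.matrix(neg_matrix)
  pos_matrix <- as.matrix(pos_matrix)
  storage.mode(neg_matrix) <- "double"
  storage.mode(pos_matrix) <- "double"
  if (ncol(neg_matrix) != ncol(pos_matrix))
    stop("both classes must have the same biomarkers (columns)", call. = FALSE)
  if (anyNA(neg_matrix) || anyNA(pos_matrix) ||
      !all(is.finite(neg_matrix)) || !all(is.finite(pos_matrix)))
    stop("biomarker data must be finite with no missing values", call. = FALSE)
  if (is.null(colnames(neg_matrix)))
    colnames(neg_matrix) <- colnames(pos_matrix) <-
      paste0("x", seq_len(ncol(neg_matrix)))
  structure(
    list(neg_matrix = neg_matrix, pos_matrix = pos_matrix,
         n0 = nrow(neg_matrix), n1 = nrow(pos_matrix), d = ncol(neg_matrix)),
    class = "two_class_data"
  )
}

#' @export
print.two_class_data <- function(x, ...) {
  cat("Two-class biomarker data: d =", x$d, "biomarkers, N0 =", x$n0,
      ", N1 =", x$n1, "\n")
  invisible(x)
}

# resolve biomarker index sets given names or integer indices
resolve_idx <- function(data, idx) {
  if (is.null(idx) || length(idx) == 0L) return(integer(0))
  if (is.character(idx)) {
    out <- match(idx, colnames(data$neg_matrix))
    if (anyNA(out))
      stop("unknown biomarker column(s): ",
           paste(idx[is.na(out)], collapse = ", "), call. = FALSE)
    return(out)
  }
  idx <- as.integer(idx)
  if (any(idx < 1L) || any(idx > data$d))
    stop("biomarker index out of range", call. = FALSE)
  idx
}
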