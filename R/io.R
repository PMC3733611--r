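# autodetect the delimiter of a small text table (tab, comma, or whitespace)
detect_sep <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  if (length(line) == 0L) stop("empty file: ", path, call. = FALSE)
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else ""
}

read_labeled_table <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!all(df$label %in% c(0, 1)))
    stop("label column must contain only 0 (negative) and 1 (positive)",
         call. = FALSE)
  if (length(unique(df$label)) < 2L)
    stop("file must contain both classes", call. = FALSE)
  df
}

#' Read a single-model score file
#'
#' Delimited text (comma or tab, autodetected) with a header row and columns
#' `label` (0 = actually negative, 1 = actually positive) and `score`.
#'
#' @param path Path to the file.
#' @return A [score_sample()].
#' @export
read_score_sample <- function(path) {
  df <- read_labeled_table(path, c("label", "score"))
  score_sample(df$score[df$label == 0], df$score[df$label == 1])
}

#' Read a paired-score file for two models on a common test set
#'
#' Delimited text with a header row and columns `label` (0/1), `score1`,
#' `score2`; each row is one subject scored by both models.
#'
#' @param path Path to the file.
#' @return A [paired_score_sample()].
#' @export
read_paired_scores <- function(path) {
  df <- read_labeled_table(path, c("label", "score1", "score2"))
  neg <- df$label == 0
  paired_score_sample(df$score1[neg], df$score1[!neg],
                      df$score2[neg], df$score2[!neg])
}

#' Read a labeled biomarker table
#'
#' Delimited text with a header row, a `label` column (0/1), and one numeric
#' column per biomarker.
#'
#' @param path Path to the file.
#' @return A [two_class_data()] with biomarker column names preserved.
#' @export
read_biomarker_data <- function(path) {
  df <- read_labeled_table(path, "label")
  markers <- setdiff(names(df), "label")
  if (length(markers) == 0L)
    stop("no biomarker columns found in ", path, call. = FALSE)
  m <- as.matrix(df[markers])
  if (!is.numeric(m)) stop("biomarker columns must be numeric", call. = FALSE)
  two_class_data(m[df$label == 0, , drop = FALSE],
                 m[df$label == 1, , drop = FALSE])
}
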