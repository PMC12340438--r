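#' Confusion-matrix metrics for binary seizure classification
#'
#' Computes TP/TN/FP/FN counts and the four standard metrics:
#' accuracy `(TP + TN) / n`, sensitivity (recall) `TP / (TP + FN)`,
#' specificity `TN / (TN + FP)`, and `F1 = 2 TP / (2 TP + FP + FN)`.
#'
#' The positive-class convention matters for sensitivity/specificity on
#' imbalanced data; it is therefore an explicit argument rather than an
#' assumption (default: label 1, the seizure class).
#'
#' @param predictions Binary vector of predicted labels.
#' @param labels Binary vector of true labels (same length).
#' @param positive_class Which label counts as positive (0 or 1). Default 1.
#' @return One-row tibble: `tp`, `tn`, `fp`, `fn`, `acc`, `sens`, `spec`,
#'   `f1`, `positive_class`. Undefined ratios (empty denominator) are `NaN`.
#' @examples
#' evaluate_metrics(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
evaluate_metrics <- function(predictions, labels, positive_class = 1) {
  if (length(predictions) == 0) stop("Empty input.", call. = FALSE)
  if (length(predictions) != length(labels)) {
    stop("`predictions` and `labels` lengths differ.", call. = FALSE)
  }
  predictions <- as.integer(predictions)
  labels <- as.integer(labels)
  if (!all(c(predictions, labels) %in% c(0L, 1L))) {
    stop("Labels and predictions must be binary (0/1).", call. = FALSE)
  }
  pos <- as.integer(positive_class)
  tp <- sum(predictions == pos & labels == pos)
  tn <- sum(predictions != pos & labels != pos)
  fp <- sum(predictions == pos & labels != pos)
  fn <- sum(predictions != pos & labels == pos)
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    acc = (tp + tn) / length(labels),
    sens = tp / (tp + fn),
    spec = tn / (tn + fp),
    f1 = 2 * tp / (2 * tp + fp + fn),
    positive_class = pos
  )
}

#' Paired t-test over repeated run metrics
#'
#' Standard paired t-statistic on the differences `a - b` with `R - 1`
#' degrees of freedom and a two-sided p-value. The degenerate case of
#' zero-variance differences is reported as `t = +/-Inf, p = 0` when the mean
#' difference is nonzero, and `t = 0, p = 1` when the runs are identical.
#'
#' @param a,b Numeric vectors of equal length `R >= 2` (one metric value per
#'   repeated train/test cycle).
#' @param alpha Significance level for the convenience flag. Default 0.05.
#' @return One-row tibble: `t_statistic`, `df`, `p_value`, `significant`,
#'   `mean_diff`.
#' @examples
#' paired_ttest(c(98.1, 98.4, 98.0), c(97.2, 97.5, 97.1))
#' @export
paired_ttest <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) stop("Run sets must have equal length.", call. = FALSE)
  R <- length(a)
  if (R < 2) stop("At least two paired runs are required.", call. = FALSE)
  d <- a - b
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    tstat <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
  } else {
    tstat <- md / (sdd / sqrt(R))
    p <- 2 * stats::pt(-abs(tstat), df = R - 1)
  }
  tibble::tibble(t_statistic = tstat, df = R - 1L, p_value = p,
                 significant = p < alpha, mean_diff = md)
}
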