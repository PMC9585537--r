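#' Confusion-matrix metrics for binary labels
#'
#' Counts TP/FP/TN/FN (positive class = 1) and derives accuracy,
#' sensitivity (recall on positives), specificity (recall on negatives),
#' precision and F-score (harmonic mean of precision and sensitivity).
#' Undefined ratios (zero denominators) are reported as 0 and flagged.
#'
#' @param y_true,y_pred equal-length vectors of 0/1 labels.
#' @return object of class `cardiodx_metrics`: list of counts and rates,
#'   with `degenerate = TRUE` when any ratio had a zero denominator.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!all(y_true %in% c(0L, 1L)) || !all(y_pred %in% c(0L, 1L))) {
    stop("labels must be 0/1")
  }
  tp <- sum(y_true == 1L & y_pred == 1L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  tn <- sum(y_true == 0L & y_pred == 0L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  safe <- function(num, den) if (den == 0) 0 else num / den
  degenerate <- (tp + fn == 0) || (tn + fp == 0) || (tp + fp == 0)
  sens <- safe(tp, tp + fn)
  spec <- safe(tn, tn + fp)
  prec <- safe(tp, tp + fp)
  f <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  if (degenerate) warning("degenerate confusion table: some rates reported as 0")
  structure(
    list(TP = tp, FP = fp, TN = tn, FN = fn,
         accuracy = (tp + tn) / length(y_true),
         sensitivity = sens, specificity = spec, precision = prec,
         f_score = f, degenerate = degenerate),
    class = "cardiodx_metrics"
  )
}

#' @export
print.cardiodx_metrics <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  cat(sprintf(
    "accuracy=%.4f sensitivity=%.4f specificity=%.4f precision=%.4f F=%.4f\n",
    x$accuracy, x$sensitivity, x$specificity, x$precision, x$f_score
  ))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a random
#' positive outscores a random negative, counting ties as one half. This is
#' exactly the trapezoidal area under the empirical ROC curve and is
#' invariant under strictly monotone transforms of the scores.
#'
#' @param scores real-valued classifier scores (higher = more positive).
#' @param y_true 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, y_true) {
  if (length(scores) != length(y_true)) stop("length mismatch")
  n_pos <- sum(y_true == 1L)
  n_neg <- sum(y_true == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Class counts and prevalence of a binarized table
#'
#' @param t a [feature_table] with 0/1 labels.
#' @return data.frame with one row per class (0 then 1): `class`, `count`,
#'   `percent` (100 * count / total, rounded half-even to 2 decimals), plus
#'   attribute `total`.
#' @export
dataset_summary <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  if (!all(t$y %in% c(0L, 1L))) stop("labels must be binarized first")
  total <- length(t$y)
  counts <- c(sum(t$y == 0L), sum(t$y == 1L))
  out <- data.frame(
    class = c(0L, 1L), count = counts,
    percent = round(100 * counts / total, 2L)
  )
  attr(out, "total") <- total
  out
}
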