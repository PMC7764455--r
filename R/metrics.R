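#' Multi-class classification metrics
#'
#' Precision, recall and F1 for diet-quality score predictions.
#' Per-class values are computed from the confusion matrix and averaged
#' weighted by class support in `truth` (macro averaging selectable);
#' the F1 is the harmonic mean of per-class precision and recall
#' *before* averaging. A class absent from the predictions contributes
#' precision 0 (and likewise recall for a class never recovered), so a
#' degenerate predictor scores 0 rather than aborting a run.
#'
#' @param pred,truth Equal-length vectors of score labels in `{1,2,3}`
#'   (any discrete labels work).
#' @param average `"weighted"` (by truth support, default) or
#'   `"macro"`.
#' @return Named numeric vector `c(precision, recall, F1)`.
#' @export
classification_metrics <- function(pred, truth,
                                   average = c("weighted", "macro")) {
  average <- match.arg(average)
  pred <- as.character(unlist(pred))
  truth <- as.character(unlist(truth))
  if (!length(truth) || length(pred) != length(truth))
    stop("pred and truth must be non-empty and of equal length",
         call. = FALSE)
  classes <- sort(unique(truth))
  per_class <- vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(precision = p, recall = r, F1 = f)
  }, numeric(3))
  w <- if (average == "weighted") {
    tabulate(match(truth, classes), length(classes)) / length(truth)
  } else rep(1 / length(classes), length(classes))
  c(precision = sum(per_class["precision", ] * w),
    recall = sum(per_class["recall", ] * w),
    F1 = sum(per_class["F1", ] * w))
}

#' Regression error metrics
#'
#' MAE, MSE, RMSE (`sqrt(MSE)`, exactly) and the coefficient of
#' determination R2 for amount predictions.
#'
#' @param pred,truth Equal-length finite numeric vectors, length >= 2
#'   (R2 is undefined below that).
#' @return Named numeric vector `c(MAE, MSE, RMSE, R2)`.
#' @export
regression_metrics <- function(pred, truth) {
  pred <- as.numeric(pred)
  truth <- as.numeric(truth)
  if (length(truth) < 2L || length(pred) != length(truth))
    stop("pred and truth must have equal length >= 2", call. = FALSE)
  if (any(!is.finite(pred)) || any(!is.finite(truth)))
    stop("metrics need finite values", call. = FALSE)
  err <- pred - truth
  mse <- mean(err^2)
  ss_tot <- sum((truth - mean(truth))^2)
  r2 <- if (ss_tot > 0) 1 - sum(err^2) / ss_tot
        else if (mse == 0) 1 else 0
  c(MAE = mean(abs(err)), MSE = mse, RMSE = sqrt(mse), R2 = r2)
}

#' Orientation of a performance measure
#'
#' @param measure Character vector of measure names.
#' @return `"max"` for precision/recall/F1/R2 (higher is better),
#'   `"min"` for MAE/MSE/RMSE.
#' @export
measure_orientation <- function(measure) {
  maximizing <- c("precision", "recall", "F1", "R2")
  minimizing <- c("MAE", "MSE", "RMSE")
  unknown <- setdiff(measure, c(maximizing, minimizing))
  if (length(unknown))
    stop("unknown measure(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  ifelse(measure %in% maximizing, "max", "min")
}
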