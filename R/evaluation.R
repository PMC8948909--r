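#' Confusion matrix for binary predictions
#'
#' Counts true/false positives and negatives under the convention 1 = case
#' (MS), 0 = control.
#'
#' @param truth 0/1 vector of true labels.
#' @param predicted 0/1 vector of predicted labels, same length.
#' @return An object of class `confusion_matrix`: list with `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have the same length.")
  }
  if (!all(truth %in% c(0, 1)) || !all(predicted %in% c(0, 1))) {
    abort("Labels must be binary {0, 1}.")
  }
  structure(
    list(
      tp = sum(truth == 1 & predicted == 1),
      fp = sum(truth == 0 & predicted == 1),
      tn = sum(truth == 0 & predicted == 0),
      fn = sum(truth == 1 & predicted == 0)
    ),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix>\n")
  cat(sprintf("            pred 1  pred 0\n"))
  cat(sprintf("  true 1  %7d %7d\n", x$tp, x$fn))
  cat(sprintf("  true 0  %7d %7d\n", x$fp, x$tn))
  invisible(x)
}

#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble(tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn)
}

#' Classification metrics from a confusion matrix
#'
#' Standard definitions: error rate = (fp + fn) / n, accuracy = 1 - error
#' rate, sensitivity = tp / (tp + fn), specificity = tn / (tn + fp).
#' Ratios with a zero denominator are reported as `NA` with a warning, never
#' silently as 0.
#'
#' @param cm A `confusion_matrix` from [confusion()], or a 0/1 `truth` vector
#'   (then `predicted` must be given).
#' @param predicted Optional 0/1 predicted labels when `cm` is a truth vector.
#' @return A one-row tibble: `error_rate`, `accuracy`, `sensitivity`,
#'   `specificity`, `n_test`.
#' @export
classification_metrics <- function(cm, predicted = NULL) {
  if (!inherits(cm, "confusion_matrix")) cm <- confusion(cm, predicted)
  n <- cm$tp + cm$fp + cm$tn + cm$fn
  if (n == 0) abort("Empty confusion matrix.")
  sens <- if (cm$tp + cm$fn == 0) {
    warn("No positive cases: sensitivity undefined.")
    NA_real_
  } else {
    cm$tp / (cm$tp + cm$fn)
  }
  spec <- if (cm$tn + cm$fp == 0) {
    warn("No negative cases: specificity undefined.")
    NA_real_
  } else {
    cm$tn / (cm$tn + cm$fp)
  }
  err <- (cm$fp + cm$fn) / n
  tibble(
    error_rate = err, accuracy = 1 - err,
    sensitivity = sens, specificity = spec, n_test = n
  )
}

#' ROC curve and AUC
#'
#' Sweeps classification thresholds over the unique predicted probabilities
#' (predict positive when probability >= threshold) and computes the area
#' under the ROC curve by the trapezoid rule. With ties this equals the
#' Mann-Whitney probability that a random case outranks a random control,
#' ties counting one half.
#'
#' @param truth 0/1 vector of true labels (both classes must be present).
#' @param probabilities Predicted case probabilities.
#' @return An object of class `ms_roc`: list with `curve` (tibble
#'   `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(truth, probabilities) {
  if (length(truth) != length(probabilities)) {
    abort("`truth` and `probabilities` must have the same length.")
  }
  if (!all(truth %in% c(0, 1))) abort("Labels must be binary {0, 1}.")
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) {
    warn("Only one class present: ROC undefined.")
    return(structure(
      list(curve = tibble(threshold = numeric(), fpr = numeric(), tpr = numeric()),
           auc = NA_real_),
      class = "ms_roc"
    ))
  }
  thresholds <- c(Inf, sort(unique(probabilities), decreasing = TRUE))
  tpr <- vapply(thresholds, function(t) sum(truth == 1 & probabilities >= t) / n1,
    numeric(1)
  )
  fpr <- vapply(thresholds, function(t) sum(truth == 0 & probabilities >= t) / n0,
    numeric(1)
  )
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(
    list(curve = tibble(threshold = thresholds, fpr = fpr, tpr = tpr), auc = auc),
    class = "ms_roc"
  )
}

#' @export
print.ms_roc <- function(x, ...) {
  cat(sprintf("<ms_roc> AUC = %.4f over %d threshold points\n",
    x$auc, nrow(x$curve)))
  invisible(x)
}

#' Evaluate a trained network on held-out samples
#'
#' Convenience wrapper: predicts on the feature block's test half and returns
#' the full metrics row including AUC.
#'
#' @param model An `ms_net`.
#' @param features A `feature_block` from [build_features()].
#' @return A one-row tibble: `error_rate`, `accuracy`, `sensitivity`,
#'   `specificity`, `auc`, `n_test`.
#' @export
evaluate_model <- function(model, features) {
  pred <- predict(model, features$x_test)
  metrics <- classification_metrics(confusion(features$y_test, pred$.label))
  roc <- suppressWarnings(roc_auc(features$y_test, pred$.prob))
  dplyr::mutate(metrics, auc = roc$auc, .before = "n_test")
}
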