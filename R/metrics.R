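#' ROC area under the curve
#'
#' Computed as the Mann-Whitney probability that a randomly chosen positive
#' outscores a randomly chosen negative, with ties counting one half
#' (rank-sum formulation with midranks).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1 = positive); both classes required.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics from scores
#'
#' Thresholds the scores (ties at the threshold classify as positive),
#' tabulates the confusion counts and reports sensitivity, specificity and
#' global accuracy as percentages plus ROC AUC as a proportion. With a
#' single-class label vector the undefined rate is reported as `NA`
#' (flagged missing), not as 0, and AUC is `NA`.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1 = positive case).
#' @param threshold Decision threshold (default 0.5).
#' @return A `metrics_record`: list with `sensitivity`, `specificity`,
#'   `global_accuracy` (percent), `roc_auc` (proportion) and
#'   `confusion = c(TP, FN, TN, FP)`.
#' @export
confusion_and_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  sens <- if (tp + fn == 0L) NA_real_ else 100 * tp / (tp + fn)
  spec <- if (tn + fp == 0L) NA_real_ else 100 * tn / (tn + fp)
  acc <- 100 * (tp + tn) / length(labels)
  auc <- if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L)
    NA_real_ else roc_auc(scores, labels)
  structure(list(sensitivity = sens, specificity = spec,
                 global_accuracy = acc, roc_auc = auc,
                 confusion = c(TP = tp, FN = fn, TN = tn, FP = fp)),
            class = "metrics_record")
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf(
    "<metrics_record> sens %.2f%%  spec %.2f%%  acc %.2f%%  AUC %.3f  (TP %d FN %d TN %d FP %d)\n",
    x$sensitivity, x$specificity, x$global_accuracy, x$roc_auc,
    x$confusion["TP"], x$confusion["FN"], x$confusion["TN"],
    x$confusion["FP"]))
  invisible(x)
}
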