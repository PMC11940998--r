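# Confusion-matrix metrics and ROC/AUC on continuous scores.  The ROC is
# built at every distinct score threshold (rule: positive iff score >=
# threshold) with (0,0)/(1,1) sentinels; trapezoidal AUC then equals the
# Mann-Whitney concordance probability with ties counted 1/2.

#' Confusion-matrix metrics for binary predictions
#'
#' @param labels_true,labels_pred Equal-length binary label vectors.
#' @param positive_label The label treated as positive (default 1).
#' @return A `fold_metrics` list: `tp`, `fp`, `tn`, `fn`, `sensitivity`
#'   (positive-class recall), `specificity` (negative-class recall),
#'   `accuracy`.
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
confusion <- function(labels_true, labels_pred, positive_label = 1) {
  if (length(labels_true) == 0)
    stop_("confusion: empty input")
  if (length(labels_true) != length(labels_pred))
    stop_("confusion: length mismatch (%d vs %d)",
          length(labels_true), length(labels_pred))
  pos_t <- labels_true == positive_label
  pos_p <- labels_pred == positive_label
  tp <- sum(pos_t & pos_p);  fn <- sum(pos_t & !pos_p)
  fp <- sum(!pos_t & pos_p); tn <- sum(!pos_t & !pos_p)
  if (tp + fn == 0)
    stop_("confusion: no positive ('%s') truths; sensitivity undefined",
          positive_label)
  if (tn + fp == 0)
    stop_("confusion: no negative truths; specificity undefined")
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 accuracy = (tp + tn) / length(labels_true)),
            class = "fold_metrics")
}

#' @export
print.fold_metrics <- function(x, ...) {
  cat(sprintf("sensitivity %.3f  specificity %.3f  accuracy %.3f  (tp %d fp %d tn %d fn %d)\n",
              x$sensitivity, x$specificity, x$accuracy,
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' ROC curve and AUC from continuous scores
#'
#' Operating points are computed at every distinct score value (positive
#' call iff `score >= threshold`; higher scores mean more positive),
#' bracketed by `Inf`/`-Inf` sentinels so the curve runs from (0,0) to
#' (1,1).  The AUC is the trapezoidal area, which under this
#' construction equals the probability that a random positive outscores
#' a random negative, ties counted one half.
#'
#' @param scores Continuous classifier scores.
#' @param labels_true Binary truth labels.
#' @param positive_label Label treated as positive (default 1).
#' @return An object of class `roc_result`: `thresholds`, `fpr`, `tpr`
#'   (nondecreasing), `auc`.
#' @export
roc_curve <- function(scores, labels_true, positive_label = 1) {
  if (length(scores) != length(labels_true))
    stop_("roc_curve: length mismatch")
  pos <- labels_true == positive_label
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop_("roc_curve: both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) sum(scores[pos] >= t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!pos] >= t) / n_neg, numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f over %d operating points\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "false positive rate", ylab = "true positive rate",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  abline(0, 1, lty = 3)
  invisible(x)
}

#' Export ROC operating points as CSV
#' @param roc A `roc_result`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_roc <- function(roc, path) {
  write.csv(data.frame(threshold = roc$thresholds, fpr = roc$fpr,
                       tpr = roc$tpr),
            path, row.names = FALSE)
  invisible(path)
}
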