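# Threshold-free and thresholded classification metrics. AUROC uses the
# rank (pairwise-comparison) statistic with ties contributing one half;
# AUPR uses step-wise precision-recall integration with tied scores
# processed as one block (no linear interpolation between PR points).

#' Area under the ROC curve
#'
#' Rank-based AUROC, equal to the probability that a random positive
#' outscores a random negative with ties counted one half.
#'
#' @param probs Numeric scores.
#' @param labels Binary labels (0/1).
#' @return AUROC in \[0, 1\]; `NA` with a warning if one class is absent.
#' @export
auroc <- function(probs, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warning("AUROC undefined with a single class")
    return(NA_real_)
  }
  r <- rank(probs)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise integration (average precision): scores sorted descending,
#' tied scores processed as one block, precision at each recall increment.
#'
#' @param probs Numeric scores.
#' @param labels Binary labels (0/1).
#' @return AUPR in \[0, 1\]; `NA` with a warning if no positives.
#' @export
aupr <- function(probs, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  if (n1 == 0 || all(labels == 1)) {
    warning("AUPR undefined with a single class")
    return(NA_real_)
  }
  ord <- order(probs, decreasing = TRUE)
  p <- probs[ord]
  y <- labels[ord]
  # block boundaries at distinct score values
  ends <- which(c(p[-length(p)] != p[-1], TRUE))
  tp <- cumsum(y)[ends]
  n_seen <- ends
  recall <- tp / n1
  precision <- tp / n_seen
  sum(diff(c(0, recall)) * precision)
}

#' Confusion matrix and thresholded metrics
#'
#' @param probs Numeric scores.
#' @param labels Binary labels (0/1).
#' @param tau Decision threshold; predicted positive iff `probs >= tau`.
#' @return List with counts (tp, fp, tn, fn), the 2x2 `confusion` matrix
#'   (counts) and `confusion_pct` (percent of total), and sensitivity,
#'   specificity, precision, f1, accuracy.
#' @export
confusion_metrics <- function(probs, labels, tau) {
  labels <- as.integer(labels)
  pred <- as.integer(probs >= tau)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  n <- length(labels)
  cm <- matrix(c(tn, fp, fn, tp), nrow = 2, byrow = TRUE,
               dimnames = list(truth = c("0", "1"),
                               predicted = c("0", "1")))
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       confusion = cm, confusion_pct = 100 * cm / n,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else
         NA_real_,
       accuracy = (tp + tn) / n)
}

#' ROC curve points
#' @param probs Numeric scores.
#' @param labels Binary labels.
#' @return data.frame with threshold, fpr, tpr (one row per distinct score
#'   plus boundary points).
#' @export
roc_points <- function(probs, labels) {
  labels <- as.integer(labels)
  thr <- c(Inf, sort(unique(probs), decreasing = TRUE))
  do.call(rbind, lapply(thr, function(tt) {
    pred <- probs >= tt
    data.frame(threshold = tt,
               fpr = sum(pred & labels == 0) / max(1, sum(labels == 0)),
               tpr = sum(pred & labels == 1) / max(1, sum(labels == 1)))
  }))
}

#' Precision-recall curve points
#' @param probs Numeric scores.
#' @param labels Binary labels.
#' @return data.frame with threshold, recall, precision.
#' @export
pr_points <- function(probs, labels) {
  labels <- as.integer(labels)
  thr <- sort(unique(probs), decreasing = TRUE)
  do.call(rbind, lapply(thr, function(tt) {
    pred <- probs >= tt
    tp <- sum(pred & labels == 1)
    data.frame(threshold = tt, recall = tp / max(1, sum(labels == 1)),
               precision = if (sum(pred) > 0) tp / sum(pred) else 1)
  }))
}

#' Full evaluation report at one resolution
#'
#' @param probs Numeric scores.
#' @param labels Binary labels.
#' @param tau Operating threshold.
#' @return List with auroc, aupr, thresholded metrics, confusion matrices
#'   and ROC/PR curve points.
#' @export
evaluate_predictions <- function(probs, labels, tau) {
  c(list(auroc = auroc(probs, labels), aupr = aupr(probs, labels),
         tau = tau, n = length(labels)),
    confusion_metrics(probs, labels, tau),
    list(roc = roc_points(probs, labels), pr = pr_points(probs, labels)))
}
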