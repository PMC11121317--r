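# Classification metrics for scored pairs.

#' Evaluate scores against binary labels
#'
#' Balanced accuracy and Matthews correlation coefficient at the given
#' threshold; AUROC (via pROC) and area under the precision-recall curve
#' (step-wise average precision) as threshold-independent metrics.
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param labels 0/1 labels.
#' @param threshold Decision threshold for BAC/MCC.
#' @return One-row tibble: `bac`, `mcc`, `auroc`, `auprc`, `threshold`, `n`.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2) {
    abort("both classes must be present to compute the metrics")
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  bac <- (tp / (tp + fn) + tn / (tn + fp)) / 2
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  auroc <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores,
    levels = c(0, 1), direction = "<", quiet = TRUE
  )))
  tibble(bac = bac, mcc = mcc, auroc = auroc,
         auprc = .average_precision(scores, labels),
         threshold = threshold, n = length(labels))
}

# step-wise average precision: sum over positives, in descending-score order,
# of precision at each recall increment
.average_precision <- function(scores, labels) {
  ord <- order(-scores, labels)  # ties: negatives first (conservative)
  y <- labels[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  sum(prec[y == 1]) / sum(y)
}
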