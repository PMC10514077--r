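#' Confusion counts for a binary prediction
#'
#' Positive = disease, negative = health.  TP: predicted disease matching
#' true disease; TN: predicted health matching true health; FP: healthy
#' samples predicted diseased; FN: diseased samples predicted healthy.
#'
#' @param truth,pred Label vectors of equal length, coerced via
#'   [normalize_label()].
#' @return One-row tibble with columns `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- normalize_label(truth)
  pred <- normalize_label(pred)
  if (length(truth) != length(pred)) abort("`truth` and `pred` lengths differ.")
  tibble(
    tp = sum(truth == "positive" & pred == "positive"),
    tn = sum(truth == "negative" & pred == "negative"),
    fp = sum(truth == "negative" & pred == "positive"),
    fn = sum(truth == "positive" & pred == "negative")
  )
}

# 0/0 -> 0: keeps sweep loops alive on tiny or one-class validation folds;
# flagged so callers can tell a true zero from a degenerate one.
safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' Threshold metrics from confusion counts
#'
#' Precision `TP/(TP+FP)`, specificity `TN/(TN+FP)`, sensitivity (recall)
#' `TP/(TP+FN)`, accuracy `(TP+TN)/N`, Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, and the F1 score
#' (harmonic mean of precision and recall).  Any 0/0 returns 0 and sets
#' `degenerate = TRUE`.
#'
#' @param counts One-row tibble from [confusion_counts()].
#' @return One-row tibble: `precision`, `specificity`, `sensitivity`, `mcc`,
#'   `accuracy`, `f1`, `degenerate`.
#' @export
#' @examples
#' compute_metrics(confusion_counts(c("P","P","N","N"), c("P","N","P","N")))
compute_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  n <- tp + tn + fp + fn
  degenerate <- any(c(tp + fp, tp + fn, tn + fp, tn + fn, n) == 0)

  precision <- safe_ratio(tp, tp + fp)
  specificity <- safe_ratio(tn, tn + fp)
  sensitivity <- safe_ratio(tp, tp + fn)
  accuracy <- safe_ratio(tp + tn, n)
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  f1 <- if (precision + sensitivity == 0) 0 else
    2 * precision * sensitivity / (precision + sensitivity)

  tibble(precision = precision, specificity = specificity,
         sensitivity = sensitivity, mcc = mcc, accuracy = accuracy,
         f1 = f1, degenerate = degenerate)
}

#' Rank-based AUC (Mann-Whitney estimator)
#'
#' \deqn{AUC = (\sum_{i \in pos} rank_i - M(M+1)/2) / (M N)}
#' with ranks ascending over the pooled scores, mid-ranks for ties, M
#' positives and N negatives.  Identical to the fraction of concordant
#' (positive, negative) score pairs, counting ties as 1/2 — the Mann-Whitney
#' U statistic divided by MN.
#'
#' @param scores Real-valued scores; higher means more likely positive.
#' @param labels Class labels, coerced via [normalize_label()].
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc_rank(c(0.9, 0.4, 0.8, 0.1), c("P", "P", "N", "N"))  # 0.75
auc_rank <- function(scores, labels) {
  labels <- normalize_label(labels)
  if (length(scores) != length(labels)) abort("`scores` and `labels` lengths differ.")
  m <- sum(labels == "positive")
  n <- sum(labels == "negative")
  if (m == 0 || n == 0) abort("Both classes must be present to compute AUC.")
  r <- rank(scores)  # mid-ranks for ties
  (sum(r[labels == "positive"]) - m * (m + 1) / 2) / (m * n)
}

#' Full seven-metric report for one evaluation
#'
#' @param truth True labels; `pred` predicted labels; `scores` optional
#'   positive-class scores for AUC (AUC is `NA` when absent or when the
#'   evaluated set has a single class).
#' @param pred,scores See above.
#' @return One-row tibble: `precision`, `specificity`, `sensitivity`, `mcc`,
#'   `accuracy`, `f1`, `auc`, `degenerate`.
#' @export
metric_report <- function(truth, pred, scores = NULL) {
  truth <- normalize_label(truth)
  out <- compute_metrics(confusion_counts(truth, pred))
  out$auc <- if (!is.null(scores) && length(unique(truth)) == 2) {
    auc_rank(scores, truth)
  } else {
    NA_real_
  }
  dplyr::relocate(out, "auc", .after = "f1")
}
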