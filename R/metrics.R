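# Evaluation measures for binary sequence classification.

#' Confusion counts
#'
#' @param tp,tn,fp,fn non-negative integer counts (true/false
#'   positives/negatives).
#' @return a `confusion_counts` list.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  cnt <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(cnt), class = "confusion_counts")
}

#' Confusion counts from predicted and true labels
#'
#' @param pred,truth vectors of labels in {0, 1}.
#' @return a `confusion_counts` list.
#' @export
count_predictions <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  confusion_counts(tp = sum(pred == 1 & truth == 1),
                   tn = sum(pred == 0 & truth == 0),
                   fp = sum(pred == 1 & truth == 0),
                   fn = sum(pred == 0 & truth == 1))
}

#' Area under the ROC curve by trapezoidal integration
#'
#' Sweeps all score thresholds (including the +/- infinity endpoints),
#' grouping tied scores at one threshold, and integrates TPR over FPR with
#' the trapezoid rule. Equivalent to the Mann-Whitney U statistic divided by
#' the number of positive-negative pairs, with ties counted 1/2.
#'
#' @param scores real-valued scores, larger = more positive.
#' @param labels true labels in {0, 1}.
#' @return AUC-ROC in [0, 1].
#' @export
auc_roc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0L || N == 0L) stop("need both classes for AUC", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group tied scores: one ROC vertex per distinct threshold
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  keep <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[keep] / P); fpr <- c(0, fp[keep] / N)
  sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
}

#' Evaluation measures from confusion counts
#'
#' ACC, sensitivity (SN), specificity (SP), false positive rate
#' (FPR = 1 - SP), F1 and MCC; AUC-ROC is added when per-sample scores and
#' labels are supplied. MCC with a zero denominator is reported as 0 with
#' the `mcc_degenerate` flag set.
#'
#' @param counts a `confusion_counts` object.
#' @param scores optional real scores for AUC-ROC.
#' @param labels labels matching `scores`.
#' @return named list with ACC, SN, SP, FPR, F1, MCC, AUCROC (NA without
#'   scores) and `mcc_degenerate`.
#' @export
compute_metrics <- function(counts, scores = NULL, labels = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  tot <- tp + tn + fp + fn
  if (tot < 1L) stop("no evaluated samples", call. = FALSE)
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  z <- sqrt(as.double(tp + fn)) * sqrt(as.double(tp + fp)) *
       sqrt(as.double(tn + fp)) * sqrt(as.double(tn + fn))
  degenerate <- z == 0
  mcc <- if (degenerate) 0 else
    (as.double(tp) * tn - as.double(fp) * fn) / z
  auc <- if (!is.null(scores)) auc_roc(scores, labels) else NA_real_
  list(ACC = (tp + tn) / tot,
       SN = sn, SP = sp,
       FPR = if (is.na(sp)) NA_real_ else 1 - sp,
       F1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0,
       MCC = mcc, AUCROC = auc, mcc_degenerate = degenerate)
}
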