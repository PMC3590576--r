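# Confusion-based quality measures and threshold-free ROC/AUC for
# per-residue turn prediction, with 't' as the positive class.

#' Confusion counts of predicted vs true turn labels
#'
#' @param pred_labels,true_labels Label strings or character vectors over
#'   \{t,n\} of equal length; 't' is the positive class.
#' @return Object of class `confusion_counts`: list with `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion <- function(pred_labels, true_labels) {
  p <- if (length(pred_labels) == 1L && nchar(pred_labels[1]) > 1L)
    strsplit(pred_labels, "")[[1]] else pred_labels
  t <- if (length(true_labels) == 1L && nchar(true_labels[1]) > 1L)
    strsplit(true_labels, "")[[1]] else true_labels
  if (length(p) != length(t)) stop("prediction and truth must have equal length")
  if (any(!c(p, t) %in% c("t", "n"))) stop("labels must be over {t,n}")
  structure(list(TP = sum(p == "t" & t == "t"),
                 TN = sum(p == "n" & t == "n"),
                 FP = sum(p == "t" & t == "n"),
                 FN = sum(p == "n" & t == "t")),
            class = "confusion_counts")
}

#' Quality measures from confusion counts
#'
#' Computes the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))` and the
#' percentage measures `Q_total` (accuracy), `Q_predicted` (precision),
#' `Q_observed` (sensitivity/coverage) and `specificity`.  Any measure with
#' a zero denominator is undefined and reported as `NA` (never coerced
#' to 0).
#'
#' @param cc A `confusion_counts` object (or list with TP/TN/FP/FN).
#' @return One-row data frame with columns `mcc`, `q_total`, `q_predicted`,
#'   `q_observed`, `specificity` (percentages in \[0,100\], mcc in
#'   \[-1,1\]).
#' @export
compute_metrics <- function(cc) {
  TP <- as.numeric(cc$TP); TN <- as.numeric(cc$TN)
  FP <- as.numeric(cc$FP); FN <- as.numeric(cc$FN)
  n <- TP + TN + FP + FN
  if (n < 1L) stop("empty confusion counts")
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  denom2 <- (TP + FN) * (TN + FP) * (TP + FP) * (TN + FN)
  mcc <- if (denom2 > 0) (TP * TN - FP * FN) / sqrt(denom2) else NA_real_
  data.frame(mcc = mcc,
             q_total = 100 * (TP + TN) / n,
             q_predicted = ratio(TP, TP + FP),
             q_observed = ratio(TP, TP + FN),
             specificity = ratio(TN, TN + FP))
}

#' ROC curve and AUC from raw turn probabilities
#'
#' Sweeps thresholds over the unique probabilities (plus the endpoints) and
#' reports (FPR, TPR) points including (0,0) and (1,1); AUC is the
#' trapezoidal area.  Intended for the raw, pre-smoothing probabilities,
#' since the state-changing rules are threshold-dependent.
#'
#' @param probs Numeric vector of turn probabilities.
#' @param true_labels Labels over \{t,n\} (string or vector), both classes
#'   present.
#' @return List with `roc` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(probs, true_labels) {
  t <- if (length(true_labels) == 1L && nchar(true_labels[1]) > 1L)
    strsplit(true_labels, "")[[1]] else true_labels
  if (length(probs) != length(t)) stop("probabilities and truth must have equal length")
  is_pos <- t == "t"
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  ord <- order(probs, decreasing = TRUE)
  pp <- probs[ord]; yy <- is_pos[ord]
  cum_tp <- cumsum(yy)
  cum_fp <- cumsum(!yy)
  last <- c(pp[-1] != pp[-length(pp)], TRUE)  # last index of each tied block
  tpr <- c(0, cum_tp[last] / n_pos)
  fpr <- c(0, cum_fp[last] / n_neg)
  thr <- c(Inf, pp[last])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}
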