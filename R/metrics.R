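# Imbalance-aware evaluation: confusion counts and the five headline metrics
# (precision_0, recall_1, macro-F1, G-mean, FPR), with class 1 = high
# ideation as the positive class. Any ratio with a zero denominator is
# defined as 0 (and an F1 with precision + recall = 0 as 0), so an
# all-negative predictor yields recall_1 = G-mean = 0 rather than NaN.

#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred Binary 0/1 vectors of equal length; class 1 (high
#'   ideation) is the positive class.
#' @return A list of class `tdt_confusion` with integer fields `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("inputs must be binary 0/1")
  }
  structure(
    list(
      TP = sum(y_true == 1 & y_pred == 1),
      TN = sum(y_true == 0 & y_pred == 0),
      FP = sum(y_true == 0 & y_pred == 1),
      FN = sum(y_true == 1 & y_pred == 0)
    ),
    class = "tdt_confusion"
  )
}

#' @export
print.tdt_confusion <- function(x, ...) {
  cat(sprintf("<confusion> TP=%d FN=%d FP=%d TN=%d\n", x$TP, x$FN, x$FP, x$TN))
  invisible(x)
}

.safe_div <- function(num, den) if (den == 0) 0 else num / den

.f1 <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)

#' Metric report from confusion counts
#'
#' Computes per-class precision and recall, per-class F1, macro-F1
#' (unweighted mean of the two F1 scores), G-mean (geometric mean of the two
#' recalls) and the false positive rate, all as proportions in \[0, 1\].
#'
#' @param c A `tdt_confusion` (or a list with `TP`, `TN`, `FP`, `FN`).
#' @return A one-row tibble with columns `TP`, `TN`, `FP`, `FN`,
#'   `precision_0`, `recall_0`, `precision_1`, `recall_1`, `F1_0`, `F1_1`,
#'   `macro_F1`, `G_mean`, `FPR`.
#' @examples
#' report(confusion(c(1, 1, 0, 0), c(1, 0, 0, 1)))
#' @export
report <- function(c) {
  stopifnot(all(c("TP", "TN", "FP", "FN") %in% names(c)))
  precision_0 <- .safe_div(c$TN, c$TN + c$FN)
  recall_0 <- .safe_div(c$TN, c$TN + c$FP)
  precision_1 <- .safe_div(c$TP, c$TP + c$FP)
  recall_1 <- .safe_div(c$TP, c$TP + c$FN)
  F1_0 <- .f1(precision_0, recall_0)
  F1_1 <- .f1(precision_1, recall_1)
  tibble::tibble(
    TP = c$TP, TN = c$TN, FP = c$FP, FN = c$FN,
    precision_0 = precision_0, recall_0 = recall_0,
    precision_1 = precision_1, recall_1 = recall_1,
    F1_0 = F1_0, F1_1 = F1_1,
    macro_F1 = (F1_0 + F1_1) / 2,
    G_mean = sqrt(recall_1 * recall_0),
    FPR = .safe_div(c$FP, c$FP + c$TN)
  )
}

#' Round half-up on the percentage scale
#'
#' Display convention for metric tables: proportions are reported as
#' percentages with 2 decimals, ties rounded up (so 0.19715 -> 19.72), unlike
#' base R's round-half-to-even.
#'
#' @param p Proportion in \[0, 1\].
#' @param digits Decimal places on the percentage scale (default 2).
#' @return Numeric percentage.
#' @export
as_percent <- function(p, digits = 2) {
  floor(p * 100 * 10^digits + 0.5) / 10^digits
}

#' Reconstruct confusion counts from printed recall and FPR
#'
#' Utility for working backwards from published metric tables: given the
#' positive-class recall, the false positive rate and the class sizes of the
#' evaluated set, recover the integer confusion counts by rounding.
#'
#' @param recall_1 Positive-class recall as a proportion.
#' @param fpr False positive rate as a proportion.
#' @param n_pos,n_neg Number of true positives/negatives in the evaluated set.
#' @return A `tdt_confusion`.
#' @examples
#' reconstruct_confusion(0.5263, 0.1972, 19, 142) # TP=10, FP=28
#' @export
reconstruct_confusion <- function(recall_1, fpr, n_pos, n_neg) {
  stopifnot(
    recall_1 >= 0, recall_1 <= 1, fpr >= 0, fpr <= 1,
    n_pos >= 0, n_neg >= 0
  )
  TP <- as.integer(floor(recall_1 * n_pos + 0.5))
  FP <- as.integer(floor(fpr * n_neg + 0.5))
  structure(
    list(TP = TP, TN = as.integer(n_neg) - FP, FP = FP, FN = as.integer(n_pos) - TP),
    class = "tdt_confusion"
  )
}

#' Evaluate binary predictions into a metric report row
#'
#' Convenience composition of [confusion()] and [report()].
#'
#' @inheritParams confusion
#' @return One-row tibble as in [report()].
#' @export
evaluate_predictions <- function(y_true, y_pred) {
  report(confusion(y_true, y_pred))
}
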