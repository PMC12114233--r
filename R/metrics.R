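#' Confusion counts from labels and predictions
#'
#' @param labels,predictions binary 0/1 vectors of equal length.
#' @return object of class `confusion_counts` with fields `tp`, `tn`, `fp`,
#'   `fn`.
#' @export
confusion_counts <- function(labels, predictions) {
  stopifnot(length(labels) == length(predictions),
            all(labels %in% c(0, 1)), all(predictions %in% c(0, 1)))
  structure(list(tp = sum(labels == 1 & predictions == 1),
                 tn = sum(labels == 0 & predictions == 0),
                 fp = sum(labels == 0 & predictions == 1),
                 fn = sum(labels == 1 & predictions == 0)),
            class = "confusion_counts")
}

as_counts <- function(c) {
  if (inherits(c, "confusion_counts")) return(c)
  stopifnot(all(c("tp", "tn", "fp", "fn") %in% names(c)))
  structure(as.list(c[c("tp", "tn", "fp", "fn")]), class = "confusion_counts")
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the
#' balanced binary-classification metric that is high only when both classes
#' are predicted well. If any denominator factor is zero the value is
#' defined as 0, with a warning.
#'
#' @param c a [confusion_counts] (or named list/vector with tp, tn, fp, fn).
#' @return number in \[-1, 1\].
#' @export
mcc <- function(c) {
  c <- as_counts(c)
  tp <- as.numeric(c$tp); tn <- as.numeric(c$tn)
  fp <- as.numeric(c$fp); fn <- as.numeric(c$fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) {
    warning("MCC denominator has a zero factor; returning 0")
    return(0)
  }
  (tp * tn - fp * fn) / sqrt(den)
}

#' Balanced accuracy
#'
#' Arithmetic mean of sensitivity `TP/(TP+FN)` and specificity
#' `TN/(TN+FP)`; insensitive to class imbalance.
#'
#' @inheritParams mcc
#' @return number in \[0, 1\].
#' @export
balanced_accuracy <- function(c) {
  c <- as_counts(c)
  if (c$tp + c$fn == 0 || c$tn + c$fp == 0)
    stop("balanced accuracy undefined: a class is absent", call. = FALSE)
  0.5 * (c$tp / (c$tp + c$fn) + c$tn / (c$tn + c$fp))
}

#' Rank-based ROC AUC
#'
#' The probability that a randomly chosen active outranks a randomly chosen
#' inactive, with ties counting one half. `orientation` states which end of
#' the score scale is the active end.
#'
#' @param scores numeric vector.
#' @param labels binary 0/1 vector.
#' @param orientation `"lower_is_active"` (docking convention) or
#'   `"higher_is_active"`.
#' @return number in \[0, 1\].
#' @export
roc_auc <- function(scores, labels,
                    orientation = c("lower_is_active", "higher_is_active")) {
  orientation <- match.arg(orientation)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_a <- sum(labels == 1)
  n_i <- sum(labels == 0)
  if (n_a == 0 || n_i == 0)
    stop("ROC AUC needs both classes present", call. = FALSE)
  s <- if (orientation == "lower_is_active") -scores else scores
  r <- rank(s)
  (sum(r[labels == 1]) - n_a * (n_a + 1) / 2) / (n_a * n_i)
}

#' Enrichment factor in the top-scored fraction
#'
#' `EF = (actives in top m / m) / (actives / N)` with
#' `m = ceiling(fraction * N)`. The top set is taken after ordering by score
#' on the active side (stable order breaks ties at the cutoff rank).
#'
#' @inheritParams roc_auc
#' @param fraction screened fraction, default 0.10.
#' @return non-negative number.
#' @export
enrichment_factor <- function(scores, labels, fraction = 0.10,
                              orientation = c("lower_is_active",
                                              "higher_is_active")) {
  orientation <- match.arg(orientation)
  n <- length(scores)
  if (n == 0L) stop("empty input", call. = FALSE)
  stopifnot(length(labels) == n, all(labels %in% c(0, 1)),
            fraction > 0, fraction <= 1)
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0)
    stop("enrichment factor needs both classes present", call. = FALSE)
  s <- if (orientation == "lower_is_active") scores else -scores
  m <- ceiling(fraction * n)
  top <- order(s)[seq_len(m)]
  (sum(labels[top]) / m) / (sum(labels) / n)
}
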