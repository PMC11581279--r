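#' Confusion matrix for five-year survival classification
#'
#' Cross-tabulates predicted against true Alive/Dead labels. The positive
#' class is Alive (surviving five years), matching the layout of the study's
#' reporting tables: `tp` = predicted Alive & truly Alive, `fp` = predicted
#' Alive & truly Dead, `tn` = predicted Dead & truly Dead, `fn` = predicted
#' Dead & truly Alive. Indeterminate truths must be excluded upstream.
#'
#' @param predicted,truth Equal-length vectors of `"Alive"`/`"Dead"` labels
#'   (character or factor).
#' @return An object of class `"confusion_matrix"`: list with integer
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_matrix <- function(predicted, truth) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (length(predicted) != length(truth)) stop("length mismatch")
  if (length(truth) < 1L) stop("need at least one pair")
  if (!all(c(predicted, truth) %in% c("Alive", "Dead")))
    stop("labels must be 'Alive' or 'Dead' (exclude Indeterminate upstream)")
  structure(list(tp = sum(predicted == "Alive" & truth == "Alive"),
                 fp = sum(predicted == "Alive" & truth == "Dead"),
                 tn = sum(predicted == "Dead" & truth == "Dead"),
                 fn = sum(predicted == "Dead" & truth == "Alive")),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(predicted = c("Alive", "Dead"),
                              truth = c("Alive", "Dead")))
  print(m)
  cat(sprintf("accuracy: %.2f%%\n", 100 * accuracy(x)))
  invisible(x)
}

#' Classification accuracy
#'
#' `(TP + TN) / (TP + FP + TN + FN)`.
#'
#' @param cm A [confusion_matrix()], or a list with fields `tp`, `fp`, `tn`,
#'   `fn`.
#' @return Proportion in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  if (total < 1L) stop("empty confusion matrix")
  (cm$tp + cm$tn) / total
}

#' ROC curve over observed score thresholds
#'
#' Sweeps the decision threshold over the unique observed scores (predicting
#' Alive when `score >= threshold`; tied scores grouped) and records one
#' operating point per threshold, from `(0, 0)` at threshold `+Inf` to
#' `(1, 1)` at the minimum score.
#'
#' @param scores Numeric scores oriented so larger means more likely Alive
#'   (e.g. survival probabilities or posteriors).
#' @param truth Alive/Dead labels; both classes must be present.
#' @return Data frame of class `"roc_curve"` with `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.character(truth)
  if (length(scores) != length(truth)) stop("length mismatch")
  pos <- truth == "Alive"; neg <- truth == "Dead"
  if (!any(pos) || !any(neg)) stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  out <- data.frame(threshold = thr,
                    fpr = vapply(thr, function(t) mean(scores[neg] >= t), 0),
                    tpr = vapply(thr, function(t) mean(scores[pos] >= t), 0))
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Area under the ROC curve
#'
#' Trapezoidal area under a [roc_curve()]; equal to the Mann-Whitney
#' probability that a random Alive record scores above a random Dead record,
#' with tied scores counted one half.
#'
#' @param curve A [roc_curve()].
#' @return Value in `[0, 1]`.
#' @export
auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}

#' Youden-optimal decision threshold
#'
#' Exhaustive search over the observed scores for the threshold maximizing
#' Youden's `J = sensitivity + specificity - 1` (predicting Alive when
#' `score >= threshold`); among maximizers the smallest threshold is
#' returned.
#'
#' @inheritParams roc_curve
#' @return The selected threshold (one of the observed scores).
#' @export
youden_threshold <- function(scores, truth) {
  truth <- as.character(truth)
  pos <- truth == "Alive"; neg <- truth == "Dead"
  if (!any(pos) || !any(neg)) stop("both classes must be present")
  thr <- sort(unique(scores))
  j <- vapply(thr, function(t)
    mean(scores[pos] >= t) - mean(scores[neg] >= t), numeric(1))
  thr[which(j == max(j))[1L]]   # thresholds ascending: first max = smallest
}

#' Harrell's concordance index
#'
#' Definitional pair enumeration for censored survival data: a pair `(i, j)`
#' is comparable when `time_i < time_j` and record `i` experienced the event
#' (a censored-earlier record cannot be ordered against a later one).
#' A comparable pair is concordant when the earlier-dying record carries the
#' higher risk score; risk ties count one half.
#'
#' @param risk Per-record risk scores, larger = higher risk of earlier death
#'   (Cox linear predictor; TAN posterior death probability).
#' @param time Follow-up months.
#' @param event Binary event indicators.
#' @return Concordant fraction in `[0, 1]`.
#' @export
harrell_c_index <- function(risk, time, event) {
  n <- length(risk)
  stopifnot(length(time) == n, length(event) == n)
  conc <- 0; comp <- 0
  for (i in seq_len(n)) {
    if (event[i] != 1L) next
    later <- which(time > time[i])
    if (!length(later)) next
    comp <- comp + length(later)
    conc <- conc + sum(risk[i] > risk[later]) + 0.5 * sum(risk[i] == risk[later])
  }
  if (comp == 0) stop("no comparable pairs")
  conc / comp
}
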