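#' Construct a binary confusion matrix
#'
#' Either supply the four counts directly, or `truth` and `pred` vectors
#' in \{-1, +1\} (class +1 is "positive").
#'
#' @param tp,fn,fp,tn non-negative counts.
#' @param truth,pred alternative input: label vectors in \{-1, +1\}.
#' @returns An object of class `confusion_matrix` (list of the four
#'   counts).
#' @examples
#' confusion_matrix(tp = 4, fn = 0, fp = 1, tn = 11)
#' @export
confusion_matrix <- function(tp = NULL, fn = NULL, fp = NULL, tn = NULL,
                             truth = NULL, pred = NULL) {
  if (!is.null(truth)) {
    if (length(truth) != length(pred))
      stopf("truth and pred differ in length")
    tp <- sum(truth == 1L & pred == 1L)
    fn <- sum(truth == 1L & pred == -1L)
    fp <- sum(truth == -1L & pred == 1L)
    tn <- sum(truth == -1L & pred == -1L)
  }
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(is.na(counts)) || any(counts < 0))
    stopf("confusion-matrix counts must be non-negative numbers")
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("actual +", "actual -"),
                              c("pred +", "pred -")))
  print(m)
  invisible(x)
}

#' @export
`+.confusion_matrix` <- function(e1, e2) {
  confusion_matrix(tp = e1$tp + e2$tp, fn = e1$fn + e2$fn,
                   fp = e1$fp + e2$fp, tn = e1$tn + e2$tn)
}

#' Class-prevalence-weighted TPR and FPR
#'
#' Treats each class in turn as positive, computes that class's true- and
#' false-positive rates, and averages the two weighted by the class's
#' share of the actual samples.  For binary problems the weighted TPR is
#' identical to the accuracy fraction.
#'
#' @param cm a [confusion_matrix()] with at least one sample.
#' @returns Named numeric vector `c(weighted_tpr, weighted_fpr)`.
#' @examples
#' weighted_rates(confusion_matrix(tp = 3, fn = 1, fp = 2, tn = 10))
#' @export
weighted_rates <- function(cm) {
  total <- cm$tp + cm$fn + cm$fp + cm$tn
  if (total == 0) stopf("empty confusion matrix")
  n_pos <- cm$tp + cm$fn
  n_neg <- cm$fp + cm$tn
  tpr_pos <- if (n_pos > 0) cm$tp / n_pos else 0
  tpr_neg <- if (n_neg > 0) cm$tn / n_neg else 0
  fpr_pos <- if (n_neg > 0) cm$fp / n_neg else 0
  fpr_neg <- if (n_pos > 0) cm$fn / n_pos else 0
  c(weighted_tpr = (n_pos * tpr_pos + n_neg * tpr_neg) / total,
    weighted_fpr = (n_pos * fpr_pos + n_neg * fpr_neg) / total)
}

#' Scalar classification metrics from a confusion matrix
#'
#' Computes sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `100 (TP+TN)/total` (a percentage), the Matthews correlation
#' coefficient
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FN)(TP+FP)(TN+FN)(TN+FP)}}}
#' and the class-prevalence-weighted TPR/FPR of [weighted_rates()].  When
#' any factor of the MCC denominator is zero the MCC is reported as 0 with
#' `mcc_undefined = TRUE` (a documented convention, since the coefficient
#' is 0/0 in that case).
#'
#' @param cm a [confusion_matrix()] with at least one sample.
#' @returns An object of class `metrics_report`: a list with `accuracy`
#'   (percent), `sensitivity`, `specificity`, `mcc`, `mcc_undefined`,
#'   `weighted_tpr`, `weighted_fpr` and the input counts.
#' @examples
#' binary_metrics(confusion_matrix(tp = 4, fn = 0, fp = 1, tn = 11))
#' @export
binary_metrics <- function(cm) {
  total <- cm$tp + cm$fn + cm$fp + cm$tn
  if (total == 0) stopf("empty confusion matrix")
  sens <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else NA_real_
  spec <- if (cm$tn + cm$fp > 0) cm$tn / (cm$tn + cm$fp) else NA_real_
  denom <- prod(c(cm$tp + cm$fn, cm$tp + cm$fp, cm$tn + cm$fn, cm$tn + cm$fp))
  mcc_undefined <- denom == 0
  mcc <- if (mcc_undefined) 0 else
    (cm$tp * cm$tn - cm$fp * cm$fn) / sqrt(denom)
  wr <- weighted_rates(cm)
  structure(list(accuracy = 100 * (cm$tp + cm$tn) / total,
                 sensitivity = sens, specificity = spec,
                 mcc = mcc, mcc_undefined = mcc_undefined,
                 weighted_tpr = unname(wr["weighted_tpr"]),
                 weighted_fpr = unname(wr["weighted_fpr"]),
                 cm = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  sensitivity %.3f  specificity %.3f  mcc %.3f%s\n",
              x$accuracy, x$sensitivity, x$specificity, x$mcc,
              if (x$mcc_undefined) " (undefined, reported 0)" else ""))
  cat(sprintf("weighted TPR %.3f  weighted FPR %.3f\n",
              x$weighted_tpr, x$weighted_fpr))
  invisible(x)
}

#' Round for report display
#'
#' Rounds half away from zero (the convention of the published tables and
#' of most ML toolkits), unlike base `round()`'s round-half-even: a
#' weighted TPR of 0.8125 displays as 0.813.  Default 3 decimals for
#' rates; use `digits = 2` for percentages.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @returns Rounded numeric.
#' @export
round_report <- function(x, digits = 3L) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

# ROC points (fpr, tpr) from continuous scores where available, else the
# single operating point of the hard predictions.
roc_points <- function(truth, pred, scores = NULL) {
  if (!is.null(scores) && length(unique(scores)) > 2L &&
      length(unique(truth)) == 2L) {
    r <- pROC::roc(response = factor(truth, levels = c(-1L, 1L)),
                   predictor = scores, quiet = TRUE,
                   direction = "<", levels = c("-1", "1"))
    data.frame(fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities))
  } else {
    cm <- confusion_matrix(truth = truth, pred = pred)
    fpr <- if (cm$fp + cm$tn > 0) cm$fp / (cm$fp + cm$tn) else 0
    tpr <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else 0
    data.frame(fpr = fpr, tpr = tpr)
  }
}
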