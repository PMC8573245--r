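#' Confusion counts with respect to a designated positive class
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param positive_class The label counted as positive (default 1, the
#'   high-risk group).
#' @return An object of class `confusion_counts` with integer fields
#'   `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(y_true, y_pred, positive_class = 1L) {
  if (length(y_true) != length(y_pred) || length(y_true) < 1L) {
    stop("y_true and y_pred must have equal nonzero length", call. = FALSE)
  }
  tpos <- y_true == positive_class
  ppos <- y_pred == positive_class
  structure(list(tp = sum(tpos & ppos),
                 tn = sum(!tpos & !ppos),
                 fp = sum(!tpos & ppos),
                 fn = sum(tpos & !ppos)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d tn=%d fp=%d fn=%d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

# ratio with NaN (not 0, not an error) when the denominator is zero
safe_ratio <- function(num, den) if (den == 0) NaN else num / den

#' Seven-metric classification report
#'
#' Computes accuracy, sensitivity (recall on positives), specificity,
#' precision (PE), negative predictive value, F-score (harmonic mean of
#' sensitivity and precision) and the Matthews correlation coefficient
#' from a confusion matrix. Every metric whose defining denominator is
#' zero is `NaN` — degenerate predictors (e.g. an all-positive model,
#' which has SN = 1, Spec = 0, NPV = NaN, MCC = NaN) keep their NaNs
#' rather than being coerced to 0.
#'
#' Metrics are stored as fractions in \[0, 1\] (MCC in \[-1, 1\]);
#' percentage rendering happens only at the reporting boundary
#' ([format_metric_report()]). The MCC denominator is factored as a
#' product of square roots so large counts cannot overflow.
#'
#' @param cc A [confusion_counts()] object with positive total.
#' @return An object of class `metric_report` with fields `acc`, `sn`,
#'   `spec`, `pe`, `npv`, `fscore`, `mcc`.
#' @examples
#' compute_metrics(confusion_counts(c(1, 1, 0, 0), c(1, 1, 1, 1)))
#' @export
compute_metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  tp <- as.numeric(cc$tp); tn <- as.numeric(cc$tn)
  fp <- as.numeric(cc$fp); fn <- as.numeric(cc$fn)
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  sn <- safe_ratio(tp, tp + fn)
  pe <- safe_ratio(tp, tp + fp)
  mcc_den <- sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tp + fp) * sqrt(tn + fn)
  structure(list(acc = (tp + tn) / total,
                 sn = sn,
                 spec = safe_ratio(tn, tn + fp),
                 pe = pe,
                 npv = safe_ratio(tn, tn + fn),
                 fscore = if (is.nan(sn) || is.nan(pe) || sn + pe == 0) NaN
                          else 2 * sn * pe / (sn + pe),
                 mcc = if (mcc_den == 0) NaN
                       else (tp * tn - fp * fn) / mcc_den),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  print(format_metric_report(x), row.names = FALSE)
  invisible(x)
}

#' Render metric reports as a percentage table
#'
#' One row per report, columns `MCC`, `ACC(%)`, `SN(%)`, `Spec(%)`,
#' `PE(%)`, `NPV(%)`, `F_score`; percentages are `100 x` the stored
#' fractions, rounded to 2 decimals; MCC and F-score stay on their
#' natural scales. `NaN` is rendered as `NaN`.
#'
#' @param reports A `metric_report` or a list of them.
#' @param row_names Optional row labels (e.g. method names).
#' @return A `data.frame`.
#' @export
format_metric_report <- function(reports, row_names = NULL) {
  if (inherits(reports, "metric_report")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(MCC = round(r$mcc, 4),
               `ACC(%)` = round(100 * r$acc, 2),
               `SN(%)` = round(100 * r$sn, 2),
               `Spec(%)` = round(100 * r$spec, 2),
               `PE(%)` = round(100 * r$pe, 2),
               `NPV(%)` = round(100 * r$npv, 2),
               F_score = round(r$fscore, 4),
               check.names = FALSE)
  }))
  if (!is.null(row_names)) df <- cbind(method = row_names, df)
  df
}
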