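#' Confusion counts for the binary MP / non-MP task
#'
#' @param tp,fn,fp,tn Non-negative integer counts; MP is the positive class.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  v <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(v < 0) || any(v != round(v))) {
    stop_data("confusion counts must be non-negative integers")
  }
  structure(as.list(v), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d fn=%d fp=%d tn=%d (P=%d, N=%d)\n",
              x$tp, x$fn, x$fp, x$tn, x$tp + x$fn, x$tn + x$fp))
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, correct classification
#' rate `100*(tp+tn)/total` (a percentage), and the Matthews correlation
#' coefficient. All values are kept at full precision; `print()` displays
#' CCR to 2 decimals and the rest to 4. When any MCC denominator factor is
#' zero the MCC is undefined and flagged (`mcc = NA`, `mcc_undefined = TRUE`)
#' rather than silently zeroed.
#'
#' @param counts A `confusion_counts`.
#' @return An object of class `class_metrics` with `sensitivity`,
#'   `specificity`, `ccr` (percent), `mcc`, `mcc_undefined`, `counts`.
#' @export
metrics_from_counts <- function(counts) {
  if (!inherits(counts, "confusion_counts")) {
    stop_param("counts must be a confusion_counts object")
  }
  tp <- counts$tp; fn <- counts$fn; fp <- counts$fp; tn <- counts$tn
  P <- tp + fn
  N <- tn + fp
  if (P == 0) stop_degenerate("sensitivity undefined: no positive examples")
  if (N == 0) stop_degenerate("specificity undefined: no negative examples")
  denom_factors <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc_undefined <- any(denom_factors == 0)
  mcc <- if (mcc_undefined) NA_real_ else {
    (tp * tn - fp * fn) / sqrt(prod(denom_factors))
  }
  structure(
    list(sensitivity = tp / P,
         specificity = tn / N,
         ccr = 100 * (tp + tn) / (P + N),
         mcc = mcc,
         mcc_undefined = mcc_undefined,
         counts = counts),
    class = "class_metrics"
  )
}

#' @export
print.class_metrics <- function(x, ...) {
  mcc <- if (x$mcc_undefined) "UNDEFINED" else sprintf("%.4f", x$mcc)
  cat(sprintf(paste0("<class_metrics> sensitivity %.4f, specificity %.4f, ",
                     "CCR %.2f%%, MCC %s\n"),
              x$sensitivity, x$specificity, x$ccr, mcc))
  invisible(x)
}

#' Confusion counts of predicted vs true labels
#'
#' @param predicted,truth Character vectors of `"MP"` / `"NON_MP"`.
#' @return A `confusion_counts`.
#' @export
count_confusion <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop_data("predicted and truth must have equal length")
  }
  confusion_counts(tp = sum(predicted == "MP" & truth == "MP"),
                   fn = sum(predicted == "NON_MP" & truth == "MP"),
                   fp = sum(predicted == "MP" & truth == "NON_MP"),
                   tn = sum(predicted == "NON_MP" & truth == "NON_MP"))
}

#' Reconstruct a confusion matrix from printed summary statistics
#'
#' Published reports often print the misclassification counts (`fn`, `fp`)
#' together with rounded sensitivity and specificity but not the full
#' matrix. This utility enumerates integer class totals `P` near
#' `fn/(1-sensitivity)` and `N` near `fp/(1-specificity)` whose recomputed
#' statistics round (at `rounding_digits`) to the printed values. If several
#' candidates survive and a printed CCR percentage is supplied, the
#' candidate whose CCR rounds to it (2 digits) is kept. A unique survivor is
#' returned; none is an inconsistency error, several an ambiguity error.
#'
#' @param fn,fp Printed misclassification counts.
#' @param sensitivity,specificity Printed rounded statistics, in (0, 1).
#' @param ccr Optional printed CCR percentage used as a tie-break.
#' @param rounding_digits Digits at which the printed statistics were rounded.
#' @return A `confusion_counts`.
#' @export
reconstruct_confusion <- function(fn, fp, sensitivity, specificity,
                                  ccr = NULL, rounding_digits = 4) {
  if (sensitivity >= 1 || specificity >= 1) {
    stop_data("ambiguous: a statistic of 1 is consistent with any class total")
  }
  if (sensitivity <= 0 || specificity <= 0) {
    stop_data("sensitivity and specificity must be in (0, 1)")
  }
  cand_totals <- function(err_count, stat) {
    est <- err_count / (1 - stat)
    lo <- max(err_count + 1, floor(est / 2))
    hi <- ceiling(est * 2) + 1
    tot <- lo:hi
    tot[round((tot - err_count) / tot, rounding_digits) ==
          round(stat, rounding_digits)]
  }
  Ps <- cand_totals(fn, sensitivity)
  Ns <- cand_totals(fp, specificity)
  if (!length(Ps) || !length(Ns)) {
    stop_data("no integer class totals are consistent with the printed values")
  }
  grid <- expand.grid(P = Ps, N = Ns)
  if (nrow(grid) > 1L && !is.null(ccr)) {
    cc <- round(100 * ((grid$P - fn) + (grid$N - fp)) / (grid$P + grid$N), 2)
    grid <- grid[cc == round(ccr, 2), , drop = FALSE]
  }
  if (nrow(grid) == 0L) {
    stop_data("no candidate matches the printed CCR")
  }
  if (nrow(grid) > 1L) {
    stop_data(sprintf(
      "ambiguous reconstruction; surviving (P, N) candidates: %s",
      paste(sprintf("(%d, %d)", grid$P, grid$N), collapse = " ")))
  }
  confusion_counts(tp = grid$P[1L] - fn, fn = fn, fp = fp,
                   tn = grid$N[1L] - fp)
}
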