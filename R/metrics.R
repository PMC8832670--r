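# Confusion-matrix accumulation and the SN/SP/MCC/Q9 indices.

#' Build a confusion summary from counts
#'
#' Derives sensitivity `SN = TP/(TP+FN)`, specificity `SP = TN/(TN+FP)`,
#' the Matthews correlation coefficient, and the class-ratio-independent
#' global accuracy `Q9 = (1 + q9)/2`, where `q9` is
#' `1 - sqrt(2) * sqrt((FN/(TP+FN))^2 + (FP/(TN+FP))^2)` when both classes
#' are present, and `(TN-FP)/(TN+FP)` resp. `(TP-FN)/(TP+FN)` when one
#' class is absent from the truth. An MCC denominator with a zero factor
#' yields `MCC = 0` by convention. Counts may be non-integer (e.g. scaled
#' negatives); `Q9` is invariant under any positive rescaling of the
#' negative-class counts.
#'
#' @param tp,fp,tn,fn Non-negative counts.
#' @return Object of class `chidt_confusion` with the counts and derived
#'   indices.
#' @export
confusion_summary <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  cnt <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(cnt < 0)) stop("counts must be non-negative")
  if (sum(cnt) <= 0) stop("empty confusion table")
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  denom <- (tp + fn) * (tp + fp) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fn * fp) / sqrt(denom) else 0
  q9 <- if (tp + fn == 0) {
    (tn - fp) / (tn + fp)
  } else if (tn + fp == 0) {
    (tp - fn) / (tp + fn)
  } else {
    1 - sqrt(2) * sqrt((fn / (tp + fn))^2 + (fp / (tn + fp))^2)
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sn = sn, sp = sp, mcc = mcc, q9 = (1 + q9) / 2),
            class = "chidt_confusion")
}

#' Summarize predictions against truth
#'
#' @param labels True binary labels (0/1).
#' @param predictions Predicted binary labels (0/1), same length.
#' @return A `chidt_confusion` (see [confusion_summary()]).
#' @export
summarize_predictions <- function(labels, predictions) {
  if (!length(labels)) stop("empty input")
  if (length(labels) != length(predictions)) stop("lengths differ")
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  if (anyNA(labels) || anyNA(predictions)) stop("labels/predictions contain NA")
  if (!all(labels %in% 0:1) || !all(predictions %in% 0:1))
    stop("labels and predictions must be binary 0/1")
  confusion_summary(tp = sum(labels == 1L & predictions == 1L),
                    fp = sum(labels == 0L & predictions == 1L),
                    tn = sum(labels == 0L & predictions == 0L),
                    fn = sum(labels == 1L & predictions == 0L))
}

# round half away from zero, the convention used for reported indices
round_half_away <- function(x, digits = 3L) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' @export
print.chidt_confusion <- function(x, digits = 3L, ...) {
  cat(sprintf("TP %s  FP %s  TN %s  FN %s\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("SN%%  %.2f   SP%%  %.2f   MCC  %.3f   Q9  %.3f\n",
              100 * x$sn, 100 * x$sp,
              round_half_away(x$mcc, digits), round_half_away(x$q9, digits)))
  invisible(x)
}

#' Write an evaluation report as a tab-separated table
#'
#' Columns `SN_pct`, `SP_pct`, `MCC`, `Q9` (percentages to 2 decimals,
#' indices rounded half-away-from-zero to 3 decimals).
#'
#' @param confusion A `chidt_confusion`.
#' @param path Output path.
#' @export
write_metrics <- function(confusion, path) {
  df <- data.frame(SN_pct = round_half_away(100 * confusion$sn, 2L),
                   SP_pct = round_half_away(100 * confusion$sp, 2L),
                   MCC = round_half_away(confusion$mcc, 3L),
                   Q9 = round_half_away(confusion$q9, 3L))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
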