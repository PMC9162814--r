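#' Confusion counts for binary classification
#'
#' @param tp,tn,fp,fn Non-negative integer counts of true positives, true
#'   negatives, false positives and false negatives.
#' @param beta Weight balancing precision and recall in the F-score;
#'   `beta = 1` gives the harmonic mean.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn = 0, fp = 0, fn = 0, beta = 1) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) < 1) {
    stop("at least one count must be positive", call. = FALSE)
  }
  if (beta <= 0) stop("`beta` must be > 0", call. = FALSE)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn, beta = beta),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Computes accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, the weighted F-score
#' `(1+beta^2) P R / (beta^2 P + R)`, and false-negative / false-positive
#' rates `FN/total` and `FP/total`. A metric whose denominator is zero is
#' reported as `NA` (explicitly undefined), never silently coerced to 0.
#'
#' @param counts A [confusion_counts()].
#' @return A list of class `metrics_report` with elements `accuracy`,
#'   `precision`, `recall`, `f_score`, `fn_rate`, `fp_rate` (fractions in
#'   `[0, 1]` or `NA`).
#' @export
#' @examples
#' classification_metrics(confusion_counts(tp = 90, tn = 85, fp = 5, fn = 10))
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- safe_div(counts$tp, counts$tp + counts$fp)
  recall <- safe_div(counts$tp, counts$tp + counts$fn)
  b2 <- counts$beta^2
  f_score <- if (!is.na(precision) && !is.na(recall) &&
                 (b2 * precision + recall) > 0) {
    (1 + b2) * precision * recall / (b2 * precision + recall)
  } else {
    NA_real_
  }
  structure(
    list(accuracy = safe_div(counts$tp + counts$tn, total),
         precision = precision,
         recall = recall,
         f_score = f_score,
         fn_rate = safe_div(counts$fn, total),
         fp_rate = safe_div(counts$fp, total)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undef" else sprintf("%.4f", v)
  cat(sprintf(
    "<metrics_report> acc %s | prec %s | rec %s | F %s | FN %s | FP %s\n",
    fmt(x$accuracy), fmt(x$precision), fmt(x$recall), fmt(x$f_score),
    fmt(x$fn_rate), fmt(x$fp_rate)))
  invisible(x)
}

#' Tolerance-based matching of detected against reference R peaks
#'
#' Greedy one-to-one matching in time order: each predicted peak is matched to
#' the nearest still-unmatched reference peak within `tolerance_ms`.
#' Unmatched predictions count as false positives, unmatched references as
#' false negatives; true negatives are 0 by convention (there is no "negative
#' event" in peak detection).
#'
#' @param predicted,reference [rpeak_annotation] objects at the same sampling
#'   rate.
#' @param tolerance_ms Matching tolerance in milliseconds (default 75, the
#'   conventional QRS-benchmarking window).
#' @return A [confusion_counts()] with `tn = 0`.
#' @export
match_peaks <- function(predicted, reference, tolerance_ms = 75) {
  stopifnot(inherits(predicted, "rpeak_annotation"),
            inherits(reference, "rpeak_annotation"))
  if (length(predicted) > 0 && length(reference) > 0 &&
      predicted$fs != reference$fs) {
    stop("annotations must share a sampling rate", call. = FALSE)
  }
  fs <- if (length(reference) > 0) reference$fs else predicted$fs
  tol <- tolerance_ms * fs / 1000
  p <- predicted$indices
  r <- reference$indices
  used <- logical(length(r))
  tp <- 0L
  for (i in seq_along(p)) {
    if (length(r) == 0) break
    d <- abs(r - p[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) == 1 && d[j] <= tol) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- length(p) - tp
  fn <- length(r) - tp
  if (tp + fp + fn == 0) {
    # both empty: vacuous perfect agreement
    return(confusion_counts(tp = 0, tn = 1, fp = 0, fn = 0))
  }
  confusion_counts(tp = tp, tn = 0, fp = fp, fn = fn)
}

#' Unweighted mean of per-group percentage rates
#'
#' Averages per-group rates (accuracies, false-negative rates, ...) across
#' groups with equal weight and reports the result rounded to 2 decimals, the
#' convention for cross-sport aggregate accuracy reporting.
#'
#' @param per_group_values Non-empty numeric vector of percentages.
#' @return The arithmetic mean, rounded to 2 decimal places.
#' @export
#' @examples
#' average_rates(c(87.5, 90.625, 100, 93.75))  # 92.97
average_rates <- function(per_group_values) {
  if (length(per_group_values) == 0) {
    stop("`per_group_values` must be non-empty", call. = FALSE)
  }
  round(mean(per_group_values), 2)
}
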