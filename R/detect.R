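#' Sliding-window detection configuration
#'
#' @param stride Hop between scored window centres, in samples (default 1:
#'   dense scoring; larger strides trade recall for speed).
#' @param prob_threshold Minimum `P(R)` for a centre to become a candidate.
#' @param refractory_ms Minimum spacing between retained peaks in
#'   milliseconds; within that spacing only the higher-probability peak
#'   survives. Physiological refractoriness suggests about 200 ms.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(stride = 1L, prob_threshold = 0.5,
                             refractory_ms = 200) {
  if (stride < 1) stop("`stride` must be >= 1", call. = FALSE)
  if (prob_threshold <= 0 || prob_threshold >= 1) {
    stop("`prob_threshold` must lie in (0, 1)", call. = FALSE)
  }
  if (refractory_ms <= 0) stop("`refractory_ms` must be > 0", call. = FALSE)
  structure(list(stride = as.integer(stride),
                 prob_threshold = prob_threshold,
                 refractory_ms = refractory_ms),
            class = "detection_config")
}

#' Detect R peaks on a continuous signal with the window classifier
#'
#' Slides a window of length `2 * half_width + 1` along the signal at the
#' configured stride, scores every centre with the classifier (each window
#' per-segment z-score normalised, matching training), groups consecutive
#' above-threshold centres, keeps the maximum-probability centre of each
#' group, and finally suppresses any peak within the refractory interval of a
#' higher-probability peak.
#'
#' Coverage matches the training convention: only centres whose full window
#' lies inside the record are scored, so beats closer than `half_width`
#' samples to either boundary cannot be detected. When scoring a detector,
#' restrict the reference to [interior_peaks()] of the same half-width.
#'
#' @param model A trained [build_model()] network.
#' @param signal An [ecg_signal] longer than one window.
#' @param half_width Window half-width in samples; must match the training
#'   windows.
#' @param config A [detection_config()].
#' @return An [rpeak_annotation] of strictly increasing detected peaks.
#' @export
detect_rpeaks <- function(model, signal, half_width,
                          config = detection_config()) {
  stopifnot(inherits(signal, "ecg_signal"))
  n <- length(signal$samples)
  win_len <- 2L * half_width + 1L
  if (n < win_len + 1L) {
    stop("signal shorter than one window", call. = FALSE)
  }
  # only centres whose full window fits are scored; beats closer than
  # half_width to the boundary are outside the detector's coverage (the same
  # convention the window-dataset builder applies to training peaks)
  centers <- seq.int(half_width, n - 1L - half_width, by = config$stride)

  # build the windows matrix in chunks to bound memory
  probs <- numeric(length(centers))
  chunk <- 2048L
  for (start in seq(1, length(centers), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(centers))
    m <- matrix(0, length(idx), win_len)
    for (k in seq_along(idx)) {
      c0 <- centers[idx[k]]
      m[k, ] <- signal$samples[(c0 - half_width + 1L):(c0 + half_width + 1L)]
    }
    p <- predict_proba(model, normalize_segments(m))
    # a zero-variance window carries no beat: never a candidate
    p[apply(m, 1, function(r) max(r) == min(r))] <- 0
    probs[idx] <- p
  }

  above <- probs >= config$prob_threshold
  if (!any(above)) return(rpeak_annotation(integer(0), signal$fs))

  # group runs of consecutive above-threshold centres; argmax prob per group
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  peaks <- integer(0)
  peak_p <- numeric(0)
  for (g in which(runs$values)) {
    sel <- starts[g]:ends[g]
    best <- sel[which.max(probs[sel])]
    peaks <- c(peaks, centers[best])
    peak_p <- c(peak_p, probs[best])
  }

  # refractory suppression: greedily keep higher-probability peaks
  refr <- config$refractory_ms * signal$fs / 1000
  ord <- order(peak_p, decreasing = TRUE)
  keep <- logical(length(peaks))
  for (i in ord) {
    if (!any(keep & abs(peaks - peaks[i]) < refr)) keep[i] <- TRUE
  }
  rpeak_annotation(sort(peaks[keep]), signal$fs)
}

#' Restrict an annotation to peaks a full window can cover
#'
#' Drops peaks closer than `half_width` samples to either record boundary —
#' the positions a sliding window classifier of that half-width can never
#' centre on. Used to align detection scoring with detector coverage.
#'
#' @param annotation An [rpeak_annotation].
#' @param signal_length Record length in samples.
#' @param half_width Window half-width in samples.
#' @return An [rpeak_annotation] of the interior peaks.
#' @export
interior_peaks <- function(annotation, signal_length, half_width) {
  stopifnot(inherits(annotation, "rpeak_annotation"))
  keep <- annotation$indices >= half_width &
    annotation$indices < signal_length - half_width
  rpeak_annotation(annotation$indices[keep], annotation$fs)
}

#' RR intervals from an R-peak annotation
#'
#' @param peaks An [rpeak_annotation] with at least 2 peaks.
#' @param epoch_id Optional identifier carried on the result.
#' @return An object of class `rr_series`: list with `intervals_ms`
#'   (successive R-to-R intervals in milliseconds) and `epoch_id`.
#' @export
#' @examples
#' rr_from_peaks(rpeak_annotation(c(0L, 360L, 720L), fs = 360))
rr_from_peaks <- function(peaks, epoch_id = "") {
  stopifnot(inherits(peaks, "rpeak_annotation"))
  if (length(peaks) < 2) {
    stop("need at least 2 peaks to form RR intervals", call. = FALSE)
  }
  structure(
    list(intervals_ms = diff(peaks$indices) * 1000 / peaks$fs,
         epoch_id = as.character(epoch_id)),
    class = "rr_series"
  )
}

#' Time-domain heart-rate-variability features of an RR series
#'
#' The canonical time-domain HRV set: mean RR, mean heart rate
#' (`60000 / mean RR`), SDNN (standard deviation of RR), RMSSD (root mean
#' square of successive RR differences), pNN50 (fraction of successive
#' differences exceeding 50 ms) and CV-RR (SDNN / mean RR). These summarise
#' autonomic state and scale with exercise intensity, which is what the
#' downstream classifier exploits.
#'
#' @param rr An [rr_from_peaks()] series with at least 3 intervals.
#' @return Named numeric vector with elements `mean_hr_bpm`, `mean_rr_ms`,
#'   `sdnn_ms`, `rmssd_ms`, `pnn50`, `cv_rr`.
#' @export
hrv_features <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$intervals_ms
  if (length(x) < 3) {
    stop("need at least 3 RR intervals for difference statistics",
         call. = FALSE)
  }
  d <- diff(x)
  mean_rr <- mean(x)
  c(mean_hr_bpm = 60000 / mean_rr,
    mean_rr_ms = mean_rr,
    sdnn_ms = stats::sd(x),
    rmssd_ms = sqrt(mean(d^2)),
    pnn50 = mean(abs(d) > 50),
    cv_rr = stats::sd(x) / mean_rr)
}

#' HRV feature vectors for successive epochs of a record
#'
#' Tiles the record into epochs of `epoch_s` seconds with the given overlap,
#' computes [hrv_features()] from the peaks falling inside each epoch, and
#' drops (with a warning) epochs containing fewer than 4 peaks, which cannot
#' support difference statistics.
#'
#' @param signal The [ecg_signal] the peaks refer to (defines the record
#'   duration).
#' @param peaks An [rpeak_annotation].
#' @param epoch_s Epoch length in seconds (> 0).
#' @param overlap Fractional overlap between successive epochs, in `[0, 1)`.
#' @return A data frame with one row per retained epoch: `epoch_start_s` plus
#'   the six feature columns.
#' @export
featurize_epochs <- function(signal, peaks, epoch_s = 60, overlap = 0.5) {
  stopifnot(inherits(signal, "ecg_signal"),
            inherits(peaks, "rpeak_annotation"))
  if (epoch_s <= 0) stop("`epoch_s` must be > 0", call. = FALSE)
  if (overlap < 0 || overlap >= 1) {
    stop("`overlap` must lie in [0, 1)", call. = FALSE)
  }
  dur <- length(signal$samples) / signal$fs
  hop <- epoch_s * (1 - overlap)
  starts <- seq(0, dur - epoch_s, by = hop)
  if (length(starts) == 0 && dur >= epoch_s) starts <- 0
  times <- peaks$indices / peaks$fs
  rows <- list()
  dropped <- 0L
  for (s0 in starts) {
    inside <- peaks$indices[times >= s0 & times < s0 + epoch_s]
    if (length(inside) < 4) {
      dropped <- dropped + 1L
      next
    }
    fv <- hrv_features(rr_from_peaks(
      rpeak_annotation(inside, peaks$fs),
      epoch_id = sprintf("%s@%gs", signal$record_id, s0)))
    rows[[length(rows) + 1L]] <- c(epoch_start_s = s0, fv)
  }
  if (dropped > 0) {
    warning(sprintf("dropped %d epoch(s) with fewer than 4 peaks", dropped))
  }
  if (length(rows) == 0) {
    return(data.frame(epoch_start_s = numeric(0), mean_hr_bpm = numeric(0),
                      mean_rr_ms = numeric(0), sdnn_ms = numeric(0),
                      rmssd_ms = numeric(0), pnn50 = numeric(0),
                      cv_rr = numeric(0)))
  }
  as.data.frame(do.call(rbind, rows))
}
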