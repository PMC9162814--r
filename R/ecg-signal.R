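#' ECG signal container
#'
#' A uniformly sampled single-channel voltage series in millivolts, with its
#' sampling rate and provenance. This is the common currency of the package:
#' the synthetic generator, the WFDB reader, the filters and the detector all
#' consume and produce `ecg_signal` objects.
#'
#' @param samples Numeric vector of voltages in mV. Must be finite and
#'   non-empty.
#' @param fs Sampling rate in Hz (> 0).
#' @param record_id Character scalar naming the record (free-form).
#' @param channel Character scalar naming the lead/channel (e.g. `"MLII"`).
#'
#' @return An object of class `ecg_signal`: a list with elements `samples`,
#'   `fs`, `record_id`, `channel`.
#' @export
#' @examples
#' sig <- ecg_signal(sin(2 * pi * 1 * seq(0, 1, by = 1 / 360)), fs = 360)
#' sig
ecg_signal <- function(samples, fs, record_id = "synthetic", channel = "I") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("`samples` must contain at least one value", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("`samples` must be finite", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive scalar (Hz)", call. = FALSE)
  }
  structure(
    list(
      samples = samples,
      fs = as.numeric(fs),
      record_id = as.character(record_id)[1L],
      channel = as.character(channel)[1L]
    ),
    class = "ecg_signal"
  )
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf(
    "<ecg_signal> record '%s' channel '%s': %d samples @ %g Hz (%.1f s)\n",
    x$record_id, x$channel, length(x$samples), x$fs,
    length(x$samples) / x$fs
  ))
  invisible(x)
}

#' @export
length.ecg_signal <- function(x) length(x$samples)

#' R-peak annotation
#'
#' Sorted sample indices (0-based, matching WFDB sample numbering) of R-wave
#' peaks, either ground truth or detections, together with the sampling rate
#' needed to convert them to times.
#'
#' @param indices Integer vector of 0-based sample positions, strictly
#'   increasing.
#' @param fs Sampling rate in Hz of the signal the indices refer to.
#'
#' @return An object of class `rpeak_annotation` with elements `indices`
#'   (integer) and `fs`.
#' @export
#' @examples
#' ann <- rpeak_annotation(c(360L, 720L, 1080L), fs = 360)
#' ann
rpeak_annotation <- function(indices, fs) {
  if (length(indices) > 0) {
    if (any(indices != round(indices))) {
      stop("`indices` must be whole sample numbers", call. = FALSE)
    }
    indices <- as.integer(round(indices))
    if (any(indices < 0L)) {
      stop("`indices` must be non-negative", call. = FALSE)
    }
    if (is.unsorted(indices, strictly = TRUE)) {
      stop("`indices` must be strictly increasing", call. = FALSE)
    }
  } else {
    indices <- integer(0)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive scalar (Hz)", call. = FALSE)
  }
  structure(list(indices = indices, fs = as.numeric(fs)),
            class = "rpeak_annotation")
}

#' @export
print.rpeak_annotation <- function(x, ...) {
  cat(sprintf("<rpeak_annotation> %d peaks @ %g Hz\n",
              length(x$indices), x$fs))
  invisible(x)
}

#' @export
length.rpeak_annotation <- function(x) length(x$indices)
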