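#' Configuration for the synthetic ECG generator
#'
#' Describes a synthetic single-channel ECG: duration, sampling rate, heart
#' rate and its beat-to-beat variability, the morphology of one beat as five
#' Gaussian bumps (P, Q, R, S, T), and the additive noise mix. Defaults give a
#' clean 360 Hz recording (the MIT-BIH rate) at 70 bpm with a standard minimal
#' beat phantom.
#'
#' @param duration_s Recording length in seconds (> 0).
#' @param fs Sampling rate in Hz. Default 360 (MIT-BIH).
#' @param mean_hr_bpm Mean heart rate in beats per minute, in `[20, 240]`.
#' @param hr_sd_bpm Beat-to-beat heart-rate standard deviation in bpm (>= 0);
#'   converted to RR jitter around the mean RR interval.
#' @param wave_amplitudes Named numeric vector of P, Q, R, S, T amplitudes in
#'   mV. The R amplitude must be strictly largest in magnitude.
#' @param wave_widths Named numeric vector of per-wave Gaussian standard
#'   deviations in seconds.
#' @param wave_offsets Named numeric vector of per-wave centre offsets in
#'   seconds relative to the R peak.
#' @param noise A [noise_config()] object describing additive noise.
#' @param seed Integer seed; the generator is a pure function of
#'   (configuration, seed).
#'
#' @return An object of class `synthetic_config`.
#' @seealso [generate_clean_ecg()], [add_noise()]
#' @export
synthetic_config <- function(duration_s = 60,
                             fs = 360,
                             mean_hr_bpm = 70,
                             hr_sd_bpm = 3,
                             wave_amplitudes = c(P = 0.15, Q = -0.1, R = 1.0,
                                                 S = -0.25, T = 0.35),
                             wave_widths = c(P = 0.025, Q = 0.01, R = 0.012,
                                             S = 0.012, T = 0.04),
                             wave_offsets = c(P = -0.2, Q = -0.05, R = 0,
                                              S = 0.05, T = 0.3),
                             noise = noise_config(),
                             seed = 1L) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("`duration_s` must be > 0", call. = FALSE)
  }
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be > 0", call. = FALSE)
  if (mean_hr_bpm < 20 || mean_hr_bpm > 240) {
    stop("`mean_hr_bpm` must lie in [20, 240]", call. = FALSE)
  }
  if (hr_sd_bpm < 0) stop("`hr_sd_bpm` must be >= 0", call. = FALSE)
  waves <- c("P", "Q", "R", "S", "T")
  for (nm in c("wave_amplitudes", "wave_widths", "wave_offsets")) {
    v <- get(nm)
    if (!all(waves %in% names(v))) {
      stop(sprintf("`%s` must name all of P, Q, R, S, T", nm), call. = FALSE)
    }
  }
  if (any(abs(wave_amplitudes[setdiff(waves, "R")]) >=
          abs(wave_amplitudes[["R"]]))) {
    stop("R amplitude must be strictly largest in magnitude", call. = FALSE)
  }
  if (any(wave_widths[waves] <= 0)) {
    stop("wave widths must be positive", call. = FALSE)
  }
  stopifnot(inherits(noise, "noise_config"))
  # noise bands must be representable at this sampling rate
  if (noise$powerline_amplitude > 0 && fs <= 2 * noise$powerline_freq) {
    stop("`fs` must exceed twice the powerline frequency", call. = FALSE)
  }
  structure(
    list(duration_s = duration_s, fs = fs, mean_hr_bpm = mean_hr_bpm,
         hr_sd_bpm = hr_sd_bpm,
         wave_amplitudes = wave_amplitudes[waves],
         wave_widths = wave_widths[waves],
         wave_offsets = wave_offsets[waves],
         noise = noise, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Configuration for the three additive ECG noise classes
#'
#' The three classical contaminants of wearable ECG: electromyographic (EMG)
#' noise modelled as band-limited white noise between 40 Hz and Nyquist,
#' powerline interference as a 50 or 60 Hz sinusoid, and baseline wander as a
#' slow sinusoid between 0.05 and 2.0 Hz.
#'
#' @param emg_amplitude EMG noise standard deviation in mV (>= 0).
#' @param powerline_amplitude Powerline sinusoid amplitude in mV (>= 0).
#' @param powerline_freq Powerline frequency in Hz; 50 or 60.
#' @param baseline_amplitude Baseline-wander sinusoid amplitude in mV (>= 0).
#' @param baseline_freq Baseline-wander frequency in Hz, in `[0.05, 2.0]`.
#'
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(emg_amplitude = 0,
                         powerline_amplitude = 0,
                         powerline_freq = 50,
                         baseline_amplitude = 0,
                         baseline_freq = 0.3) {
  if (emg_amplitude < 0 || powerline_amplitude < 0 || baseline_amplitude < 0) {
    stop("noise amplitudes must be >= 0", call. = FALSE)
  }
  if (!powerline_freq %in% c(50, 60)) {
    stop("`powerline_freq` must be 50 or 60 Hz", call. = FALSE)
  }
  if (baseline_freq < 0.05 || baseline_freq > 2.0) {
    stop("`baseline_freq` must lie in [0.05, 2.0] Hz", call. = FALSE)
  }
  structure(
    list(emg_amplitude = emg_amplitude,
         powerline_amplitude = powerline_amplitude,
         powerline_freq = powerline_freq,
         baseline_amplitude = baseline_amplitude,
         baseline_freq = baseline_freq),
    class = "noise_config"
  )
}

#' Generate a clean synthetic ECG with known R-peak positions
#'
#' Draws RR intervals as `60 / mean_hr_bpm` seconds plus zero-mean Gaussian
#' jitter (sd derived from `hr_sd_bpm`), truncated below at 0.25 s, then
#' renders each beat as the sum of five Gaussian bumps at fixed offsets from
#' the R position. The returned annotation holds the exact R sample of every
#' beat whose R peak falls inside the record. Identical configuration and seed
#' give bit-identical output.
#'
#' @param config A [synthetic_config()].
#'
#' @return A list with elements `signal` ([ecg_signal]) and `annotation`
#'   ([rpeak_annotation]). The signal has `round(duration_s * fs)` samples and
#'   is noise-free; apply [add_noise()] for contaminated records.
#' @export
#' @examples
#' out <- generate_clean_ecg(synthetic_config(duration_s = 10, hr_sd_bpm = 0))
#' out$signal
#' out$annotation
generate_clean_ecg <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  fs <- config$fs
  n <- round(config$duration_s * fs)
  mean_rr <- 60 / config$mean_hr_bpm
  if (config$duration_s < mean_rr) {
    stop("duration too short to contain one beat", call. = FALSE)
  }
  # jitter sd in seconds: d(60/hr)/d(hr) = -60/hr^2, local linearisation
  rr_sd <- 60 * config$hr_sd_bpm / config$mean_hr_bpm^2

  set.seed(config$seed)
  # draw generously many beats, then keep those inside the record
  n_max <- ceiling(config$duration_s / 0.25) + 2L
  rr <- mean_rr + stats::rnorm(n_max, 0, rr_sd)
  rr <- pmax(rr, 0.25)
  r_times <- cumsum(c(mean_rr / 2, rr))
  r_times <- r_times[r_times < config$duration_s]
  r_idx <- round(r_times * fs)
  r_idx <- r_idx[r_idx >= 0 & r_idx < n]
  r_idx <- unique(r_idx)
  if (length(r_idx) < 1L) {
    stop("duration too short to contain one beat", call. = FALSE)
  }

  t <- (seq_len(n) - 1L) / fs
  x <- numeric(n)
  amps <- config$wave_amplitudes
  wids <- config$wave_widths
  offs <- config$wave_offsets
  for (r in r_idx / fs) {
    for (w in names(amps)) {
      mu <- r + offs[[w]]
      s <- wids[[w]]
      # only touch samples within 4 sd of the bump centre
      lo <- max(1L, floor((mu - 4 * s) * fs) + 1L)
      hi <- min(n, ceiling((mu + 4 * s) * fs) + 1L)
      if (lo <= hi) {
        idx <- lo:hi
        x[idx] <- x[idx] + amps[[w]] * exp(-(t[idx] - mu)^2 / (2 * s^2))
      }
    }
  }

  list(
    signal = ecg_signal(x, fs, record_id = "synthetic", channel = "I"),
    annotation = rpeak_annotation(r_idx, fs)
  )
}

#' Add the three classical noise types to an ECG signal
#'
#' Adds, sample-wise: band-limited white EMG noise (40 Hz to Nyquist, scaled
#' to unit standard deviation before multiplication by `emg_amplitude`), a
#' powerline sinusoid, and a baseline-wander sinusoid. Length and sampling
#' rate are unchanged; zero amplitudes return the input unchanged.
#'
#' @param signal An [ecg_signal].
#' @param noise A [noise_config()].
#' @param seed Integer seed for the EMG noise draw.
#'
#' @return An [ecg_signal] of the same length and sampling rate.
#' @export
add_noise <- function(signal, noise, seed = 1L) {
  stopifnot(inherits(signal, "ecg_signal"), inherits(noise, "noise_config"))
  fs <- signal$fs
  nyq <- fs / 2
  if (noise$powerline_freq >= nyq && noise$powerline_amplitude > 0) {
    stop("powerline frequency must be below Nyquist", call. = FALSE)
  }
  n <- length(signal$samples)
  t <- (seq_len(n) - 1L) / fs
  x <- signal$samples

  if (noise$emg_amplitude > 0) {
    set.seed(as.integer(seed))
    w <- stats::rnorm(n)
    # band-pass 40 Hz..Nyquist via FFT masking: exact band confinement
    w_band <- .fft_bandpass(w, fs, 40, nyq)
    sdv <- stats::sd(w_band)
    if (sdv > 0) w_band <- w_band / sdv
    x <- x + noise$emg_amplitude * w_band
  }
  if (noise$powerline_amplitude > 0) {
    x <- x + noise$powerline_amplitude * sin(2 * pi * noise$powerline_freq * t)
  }
  if (noise$baseline_amplitude > 0) {
    x <- x + noise$baseline_amplitude * sin(2 * pi * noise$baseline_freq * t)
  }
  ecg_signal(x, fs, record_id = signal$record_id, channel = signal$channel)
}

# zero out FFT bins outside [f_lo, f_hi]; returns a real series
.fft_bandpass <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  X <- stats::fft(x)
  freq <- (seq_len(n) - 1L) * fs / n
  freq <- pmin(freq, fs - freq)  # fold to [0, fs/2]
  keep <- freq >= f_lo & freq <= f_hi
  X[!keep] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Generate labelled per-epoch ECG sessions with MET-dependent heart rate
#'
#' Emulates an exercise session monitored by an accelerometer-based MET
#' (metabolic equivalent of task) logger worn alongside the ECG patch: each
#' epoch's MET value is drawn uniformly from its intensity-class range and the
#' epoch's ECG is generated with mean heart rate `rest_hr + slope * MET`.
#' Labels come from [met_to_class()] applied to the drawn MET, so downstream
#' classifiers can be scored against exact ground truth.
#'
#' @param n_epochs Number of epochs; divided as evenly as possible across the
#'   three classes (balanced when divisible by 3).
#' @param met_ranges Named list of `c(lo, hi)` MET intervals for classes
#'   `low`, `medium`, `high`. Defaults cover the standard cutpoints
#'   (<=3 / 3-6 / >=6) without gaps.
#' @param fs Sampling rate in Hz.
#' @param epoch_s Epoch duration in seconds.
#' @param hr_model List with `rest_hr` (bpm) and `slope` (bpm per MET, > 0)
#'   giving the linear MET-to-heart-rate map.
#' @param hr_sd_bpm Beat-to-beat heart-rate variability passed to the
#'   generator (bpm).
#' @param noise A [noise_config()] applied to every epoch.
#' @param seed Integer seed.
#'
#' @return A list of epochs, each a list with elements `signal`, `annotation`,
#'   `met` (numeric), `label` (factor level among low/medium/high).
#' @export
generate_intensity_sessions <- function(n_epochs = 300,
                                        met_ranges = list(
                                          low = c(1, 3),
                                          medium = c(3, 6),
                                          high = c(6, 10)),
                                        fs = 360,
                                        epoch_s = 60,
                                        hr_model = list(rest_hr = 60,
                                                        slope = 10),
                                        hr_sd_bpm = 2,
                                        noise = noise_config(),
                                        seed = 1L) {
  if (hr_model$slope <= 0) {
    stop("`slope` must be > 0: labels would be unrecoverable", call. = FALSE)
  }
  classes <- c("low", "medium", "high")
  if (!all(classes %in% names(met_ranges))) {
    stop("`met_ranges` must name low, medium, high", call. = FALSE)
  }
  # each range must lie inside its class so the drawn label is well-defined
  if (met_ranges$low[1] < 0 || met_ranges$low[2] > 3 ||
      met_ranges$medium[1] < 3 || met_ranges$medium[2] > 6 ||
      met_ranges$high[1] < 6) {
    stop("`met_ranges` must lie within the class intervals [0,3], [3,6], [6,Inf)",
         call. = FALSE)
  }
  per <- rep(n_epochs %/% 3L, 3L)
  extra <- n_epochs - sum(per)
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L

  set.seed(as.integer(seed))
  epoch_seeds <- sample.int(.Machine$integer.max, n_epochs)
  class_of <- rep(classes, times = per)
  mets <- numeric(n_epochs)
  for (i in seq_len(n_epochs)) {
    rg <- met_ranges[[class_of[i]]]
    mets[i] <- stats::runif(1, rg[1], rg[2])
  }
  # keep draws off the class boundaries so the label is well-defined
  mets[class_of == "medium"] <- pmin(pmax(mets[class_of == "medium"],
                                          3 + 1e-6), 6 - 1e-6)

  lapply(seq_len(n_epochs), function(i) {
    hr <- hr_model$rest_hr + hr_model$slope * mets[i]
    cfg <- synthetic_config(duration_s = epoch_s, fs = fs, mean_hr_bpm = hr,
                            hr_sd_bpm = hr_sd_bpm, noise = noise,
                            seed = epoch_seeds[i])
    out <- generate_clean_ecg(cfg)
    if (noise$emg_amplitude > 0 || noise$powerline_amplitude > 0 ||
        noise$baseline_amplitude > 0) {
      out$signal <- add_noise(out$signal, noise, seed = epoch_seeds[i])
    }
    list(signal = out$signal, annotation = out$annotation,
         met = mets[i], label = met_to_class(mets[i]))
  })
}
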