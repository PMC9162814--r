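# Shared fixtures built in code. The toy classifier is trained once per test
# run and reused across files (window half-width 50, clean synthetic beats).

.fixture_env <- new.env(parent = emptyenv())

make_synth_records <- function(n, duration_s = 30, mean_hr_bpm = 75,
                               hr_sd_bpm = 3, seed0 = 100L,
                               noise = NULL) {
  lapply(seq_len(n), function(i) {
    out <- generate_clean_ecg(synthetic_config(
      duration_s = duration_s, mean_hr_bpm = mean_hr_bpm,
      hr_sd_bpm = hr_sd_bpm, seed = seed0 + i))
    sig <- out$signal
    if (!is.null(noise)) sig <- add_noise(sig, noise, seed = seed0 + i)
    sig$record_id <- sprintf("fix%02d", i)
    list(signal = sig, annotation = out$annotation, clean = out$signal)
  })
}

# small trained window classifier (length 101) shared across test files
get_toy_model <- function() {
  if (!is.null(.fixture_env$toy)) return(.fixture_env$toy)
  recs <- make_synth_records(2, duration_s = 30, seed0 = 200L)
  ds <- suppressWarnings(build_window_dataset(recs, half_width = 50,
                                              seed = 11))
  model <- build_model(101, seed = 12)
  trained <- train_model(model, ds, train_config(epochs = 8, seed = 13))
  .fixture_env$toy <- list(model = trained$model, history = trained$history,
                           dataset = ds, half_width = 50L)
  .fixture_env$toy
}

# FFT amplitude of a real series at (approximately) frequency f_hz
fft_amplitude_at <- function(x, fs, f_hz) {
  n <- length(x)
  sp <- Mod(stats::fft(x)) / n * 2
  bin <- round(f_hz * n / fs) + 1L
  sp[bin]
}

# fraction of total power of x inside [f_lo, f_hi] (one-sided)
band_power_fraction <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  freq <- (seq_len(n) - 1L) * fs / n
  freq <- pmin(freq, fs - freq)
  sum(p[freq >= f_lo & freq <= f_hi]) / sum(p)
}
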