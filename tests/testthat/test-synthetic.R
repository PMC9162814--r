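test_that("zero-jitter generation places R peaks at exact periodic spacing", {
  out <- generate_clean_ecg(synthetic_config(
    duration_s = 10, fs = 360, mean_hr_bpm = 60, hr_sd_bpm = 0, seed = 1))
  expect_equal(length(out$signal$samples), 3600)
  spacing <- unique(diff(out$annotation$indices))
  expect_equal(spacing, 360L)
  expect_true(abs(length(out$annotation$indices) - 10) <= 1)
})

test_that("generation is a pure function of config and seed", {
  cfg <- synthetic_config(duration_s = 15, mean_hr_bpm = 80, hr_sd_bpm = 4,
                          seed = 42)
  a <- generate_clean_ecg(cfg)
  b <- generate_clean_ecg(cfg)
  expect_identical(a$signal$samples, b$signal$samples)
  expect_identical(a$annotation$indices, b$annotation$indices)
})

test_that("annotated mean RR recovers the configured heart rate", {
  out <- generate_clean_ecg(synthetic_config(
    duration_s = 60, mean_hr_bpm = 120, hr_sd_bpm = 2, seed = 3))
  rr_s <- diff(out$annotation$indices) / 360
  # oracle: sample mean of returned indices vs configured 0.5 s
  se <- sd(rr_s) / sqrt(length(rr_s))
  expect_lt(abs(mean(rr_s) - 0.5), 3 * max(se, 1 / 360))
})

test_that("every annotated index is a local maximum of the clean signal", {
  out <- generate_clean_ecg(synthetic_config(
    duration_s = 30, mean_hr_bpm = 90, hr_sd_bpm = 5, seed = 7))
  x <- out$signal$samples
  for (i in out$annotation$indices) {
    lo <- max(0, i - 2); hi <- min(length(x) - 1, i + 2)
    window_max <- max(x[(lo + 1):(hi + 1)])
    expect_equal(x[i + 1], window_max)
  }
})

test_that("generation errors when the duration cannot hold one beat", {
  expect_error(
    generate_clean_ecg(synthetic_config(duration_s = 0.3,
                                        mean_hr_bpm = 60, seed = 1)),
    "duration")
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(mean_hr_bpm = 300), "20, 240")
  expect_error(synthetic_config(hr_sd_bpm = -1), ">= 0")
  expect_error(
    synthetic_config(wave_amplitudes = c(P = 0.15, Q = -0.1, R = 0.2,
                                         S = -0.25, T = 0.35)),
    "largest")
  expect_error(noise_config(powerline_freq = 45), "50 or 60")
  expect_error(noise_config(baseline_freq = 3), "0.05")
  expect_error(noise_config(emg_amplitude = -0.1), ">= 0")
})

test_that("zero-amplitude noise is the additive identity", {
  out <- generate_clean_ecg(synthetic_config(duration_s = 5, seed = 2))
  noisy <- add_noise(out$signal, noise_config(), seed = 9)
  expect_identical(noisy$samples, out$signal$samples)
})

test_that("powerline noise appears as a single dominant FFT bin", {
  out <- generate_clean_ecg(synthetic_config(duration_s = 10, seed = 2))
  noisy <- add_noise(out$signal,
                     noise_config(powerline_amplitude = 0.1,
                                  powerline_freq = 50), seed = 1)
  d <- noisy$samples - out$signal$samples
  amp50 <- fft_amplitude_at(d, 360, 50)
  expect_equal(amp50, 0.1, tolerance = 1e-6)
  sp <- Mod(stats::fft(d))
  half <- sp[2:1800]
  expect_equal(which.max(half) + 1L, round(50 * 3600 / 360) + 1L)
})

test_that("baseline noise crosses zero at the expected rate", {
  out <- generate_clean_ecg(synthetic_config(duration_s = 20, seed = 2))
  noisy <- add_noise(out$signal,
                     noise_config(baseline_amplitude = 0.4,
                                  baseline_freq = 0.3), seed = 1)
  d <- noisy$samples - out$signal$samples
  crossings <- sum(diff(sign(d)) != 0)
  # a 0.3 Hz sinusoid over 20 s crosses zero ~2 * 0.3 * 20 = 12 times
  expect_true(abs(crossings - 12) <= 1)
})

test_that("each noise class keeps >= 90% of its power in its stated band", {
  out <- generate_clean_ecg(synthetic_config(duration_s = 20, seed = 5))
  cases <- list(
    list(noise_config(emg_amplitude = 0.1), c(40, 180)),
    list(noise_config(powerline_amplitude = 0.1), c(49, 51)),
    list(noise_config(baseline_amplitude = 0.3, baseline_freq = 0.5),
         c(0.05, 2)))
  for (cs in cases) {
    d <- add_noise(out$signal, cs[[1]], seed = 3)$samples -
      out$signal$samples
    expect_gte(band_power_fraction(d, 360, cs[[2]][1], cs[[2]][2]), 0.90)
  }
})

test_that("powerline frequency at or above Nyquist is rejected", {
  sig <- ecg_signal(rnorm(100), fs = 90)
  expect_error(add_noise(sig, noise_config(powerline_amplitude = 0.1,
                                           powerline_freq = 50), 1),
               "Nyquist")
})

test_that("intensity sessions map MET linearly to heart rate and balance classes", {
  sessions <- generate_intensity_sessions(
    n_epochs = 30, epoch_s = 20, hr_model = list(rest_hr = 60, slope = 10),
    hr_sd_bpm = 0.5, seed = 21)
  labs <- vapply(sessions, function(s) as.character(s$label), character(1))
  expect_equal(as.vector(table(factor(labs, c("low", "medium", "high")))),
               c(10, 10, 10))
  for (s in sessions) {
    # recovered mean HR should sit near rest_hr + slope * MET
    hr_cfg <- 60 + 10 * s$met
    rr_s <- diff(s$annotation$indices) / 360
    expect_lt(abs(60 / mean(rr_s) - hr_cfg), 0.05 * hr_cfg)
    expect_equal(as.character(s$label),
                 as.character(met_to_class(s$met)))
  }
})

test_that("a MET draw of 7 is labelled high intensity", {
  sessions <- generate_intensity_sessions(
    n_epochs = 3, epoch_s = 15,
    met_ranges = list(low = c(1, 3), medium = c(3, 6), high = c(7, 7)),
    seed = 4)
  high <- sessions[[3]]
  expect_equal(high$met, 7)
  expect_equal(as.character(high$label), "high")
})

test_that("non-positive HR slope is rejected as unrecoverable", {
  expect_error(generate_intensity_sessions(
    n_epochs = 3, hr_model = list(rest_hr = 60, slope = 0), seed = 1),
    "slope")
})
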