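t20 <- (0:7199) / 360
tone <- function(f_hz) ecg_signal(sin(2 * pi * f_hz * t20), 360)
rms_ratio <- function(filtered, input) {
  sd(filtered$samples) / sd(input$samples)
}

test_that("EMG low-pass passes the ECG band and kills high frequencies", {
  f <- filter_config()
  dc <- ecg_signal(rep(0.7, 3600), 360)
  expect_lt(max(abs(lowpass_emg(dc, f)$samples - 0.7)), 1e-6)
  expect_lte(rms_ratio(lowpass_emg(tone(100), f), tone(100)), 0.1)
  expect_lt(abs(rms_ratio(lowpass_emg(tone(10), f), tone(10)) - 1), 0.05)
  # band-edge contract: within 5% at 0.8 * cutoff, >= 20 dB at 2 * cutoff
  expect_lt(abs(rms_ratio(lowpass_emg(tone(32), f), tone(32)) - 1), 0.05)
  expect_lte(rms_ratio(lowpass_emg(tone(80), f), tone(80)), 0.1)
  expect_error(lowpass_emg(ecg_signal(rnorm(50), 60), f), "Nyquist")
})

test_that("powerline notch attenuates 50 Hz >= 20 dB with a flat passband", {
  f <- filter_config()
  expect_lte(rms_ratio(notch_powerline(tone(50), f), tone(50)), 0.1)
  expect_lt(abs(rms_ratio(notch_powerline(tone(10), f), tone(10)) - 1), 0.1)
  expect_lt(abs(rms_ratio(notch_powerline(tone(40), f), tone(40)) - 1), 0.1)
  expect_lt(abs(rms_ratio(notch_powerline(tone(60), f), tone(60)) - 1), 0.1)
  zero <- ecg_signal(rep(0, 2000), 360)
  expect_equal(max(abs(notch_powerline(zero, f)$samples)), 0)
})

test_that("60 Hz notch configuration targets 60 Hz", {
  f <- filter_config(notch_freq = 60)
  expect_lte(rms_ratio(notch_powerline(tone(60), f), tone(60)), 0.1)
  expect_lt(abs(rms_ratio(notch_powerline(tone(50), f), tone(50)) - 1), 0.1)
})

test_that("baseline correction removes drift but not the beat content", {
  f <- filter_config()
  out <- generate_clean_ecg(synthetic_config(duration_s = 30, seed = 7))
  drift <- 0.5 * sin(2 * pi * 0.3 * (seq_along(out$signal$samples) - 1) / 360)
  noisy <- ecg_signal(out$signal$samples + drift, 360)
  rec <- correct_baseline(noisy, f)
  # reconstruction-error oracle against the known clean signal
  expect_lte(sqrt(mean((rec$samples - out$signal$samples)^2)), 0.15)

  # zero-mean noise above 1 Hz is essentially unchanged
  set.seed(8)
  w <- rnorm(7200)
  keep <- {
    X <- stats::fft(w)
    fr <- (seq_along(w) - 1) * 360 / length(w)
    fr <- pmin(fr, 360 - fr)
    X[fr < 1] <- 0
    Re(stats::fft(X, inverse = TRUE)) / length(w)
  }
  sw <- ecg_signal(keep, 360)
  expect_lt(abs(rms_ratio(correct_baseline(sw, f), sw) - 1), 0.1)

  const <- ecg_signal(rep(1, 3600), 360)
  expect_lt(max(abs(correct_baseline(const, f)$samples)), 0.01)
})

test_that("the full chain composes the three filters and keeps length", {
  f <- filter_config()
  out <- generate_clean_ecg(synthetic_config(duration_s = 20, seed = 9))
  noisy <- add_noise(out$signal,
                     noise_config(emg_amplitude = 0.05,
                                  powerline_amplitude = 0.15,
                                  baseline_amplitude = 0.4), seed = 10)
  y <- preprocess_chain(noisy, f)
  expect_equal(length(y$samples), length(noisy$samples))
  y2 <- correct_baseline(notch_powerline(lowpass_emg(noisy, f), f), f)
  expect_equal(y$samples, y2$samples)
  zero <- ecg_signal(rep(0, 2000), 360)
  expect_equal(max(abs(preprocess_chain(zero, f)$samples)), 0)
})

test_that("the chain preserves R-peak positions of a clean ECG", {
  out <- generate_clean_ecg(synthetic_config(duration_s = 30,
                                             mean_hr_bpm = 80, seed = 11))
  y <- preprocess_chain(out$signal)$samples
  ok <- vapply(out$annotation$indices, function(i) {
    lo <- max(0, i - 5); hi <- min(length(y) - 1, i + 5)
    j <- (lo:hi)[which.max(y[(lo:hi) + 1])]
    abs(j - i) <= 2
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})

test_that("the chain improves SNR on signals carrying all three noise types", {
  out <- generate_clean_ecg(synthetic_config(duration_s = 20, seed = 12))
  clean <- out$signal$samples
  noisy <- add_noise(out$signal,
                     noise_config(emg_amplitude = 0.08,
                                  powerline_amplitude = 0.2,
                                  baseline_amplitude = 0.5), seed = 13)
  filtered <- preprocess_chain(noisy)
  snr <- function(x) 10 * log10(sum(clean^2) / sum((x - clean)^2))
  expect_gt(snr(filtered$samples), snr(noisy$samples))
})

test_that("all three filters are linear operators", {
  f <- filter_config()
  set.seed(14)
  x <- rnorm(2000); y <- rnorm(2000)
  a <- 1.7; b <- -0.4
  for (op in list(lowpass_emg, notch_powerline, correct_baseline)) {
    lhs <- op(ecg_signal(a * x + b * y, 360), f)$samples
    rhs <- a * op(ecg_signal(x, 360), f)$samples +
      b * op(ecg_signal(y, 360), f)$samples
    expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-6)
  }
})

test_that("filtering is zero-phase: no lag against the input", {
  out <- generate_clean_ecg(synthetic_config(duration_s = 20, seed = 15))
  y <- preprocess_chain(out$signal)$samples
  x <- out$signal$samples
  lags <- -10:10
  cc <- vapply(lags, function(l) {
    if (l >= 0) cor(x[1:(length(x) - l)], y[(1 + l):length(y)])
    else cor(x[(1 - l):length(x)], y[1:(length(y) + l)])
  }, numeric(1))
  expect_equal(lags[which.max(cc)], 0)
})

test_that("inconsistent cutoff ordering is rejected", {
  expect_error(filter_config(baseline_cutoff = 45), "baseline_cutoff")
  expect_error(filter_config(notch_numtaps = 100), "odd")
})
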