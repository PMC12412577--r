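mk_sine <- function(f, fs, dur = 2, amp = 1) {
  recording(amp * sin(2 * pi * f * seq(0, dur, by = 1 / fs)), fs,
            unit = "uV", kind = "neural")
}

test_that("neural band-pass keeps in-band tones and rejects out-of-band", {
  s <- mk_sine(100, 16000)
  y <- bandpass_neural(s)
  expect_equal(length(y$samples), length(s$samples))
  mid <- 8000:24000
  amp <- sqrt(2) * sqrt(mean(y$samples[mid]^2))
  expect_lt(abs(amp - 1), 0.02)
  hi <- mk_sine(5000, 16000)
  yh <- bandpass_neural(hi)
  expect_lt(sqrt(mean(yh$samples[mid]^2)) / sqrt(mean(hi$samples[mid]^2)),
            0.05)
  dc <- recording(rep(10, 32000), 16000, unit = "uV", kind = "neural")
  expect_lt(abs(mean(bandpass_neural(dc)$samples[mid])), 0.5)
  low <- recording(rnorm(8000), 2000, unit = "uV", kind = "neural")
  expect_error(bandpass_neural(low), "Nyquist")
})

test_that("EMG high-pass rejects slow drift and keeps fast content", {
  slow <- mk_sine(1, 4000, dur = 4)
  fast <- mk_sine(100, 4000, dur = 4)
  mid <- 4000:12000
  expect_lt(sqrt(mean(highpass_emg(slow)$samples[mid]^2)), 0.05)
  expect_gt(sqrt(mean(highpass_emg(fast)$samples[mid]^2)), 0.65)
  expect_equal(length(highpass_emg(slow)$samples), length(slow$samples))
})

test_that("50 Hz notch attenuates mains and passes neighbours", {
  s50 <- mk_sine(50, 16000, dur = 4)
  s30 <- mk_sine(30, 16000, dur = 4)
  mid <- 16000:48000
  att_db <- 20 * log10(sqrt(mean(bandstop_50(s50)$samples[mid]^2)) /
                         sqrt(mean(s50$samples[mid]^2)))
  expect_lt(att_db, -20)
  expect_gt(sqrt(mean(bandstop_50(s30)$samples[mid]^2)), 0.6)
  twice <- bandstop_50(bandstop_50(s30))
  expect_lt(max(abs(twice$samples[mid] - bandstop_50(s30)$samples[mid])), 0.1)
})

test_that("envelope tracks amplitude modulation and stays non-negative", {
  fs <- 4000
  t <- seq(0, 4, by = 1 / fs)
  A <- 1 + 0.5 * sin(2 * pi * 2 * t)
  am <- recording(A * sin(2 * pi * 300 * t), fs, unit = "uV", kind = "neural")
  env <- envelope(am, smooth_hz = 10)
  expect_true(all(env$samples >= 0))
  expect_equal(length(env$samples), length(am$samples))
  mid <- 4000:12000
  expect_lt(max(abs(env$samples[mid] - A[mid]) / A[mid]), 0.1)
  const <- recording(rep(-3, 1000), fs, unit = "uV", kind = "neural")
  expect_lt(max(abs(envelope(const, smooth_hz = NA)$samples - 3)), 1e-6)
})

test_that("zero-phase filtering preserves a symmetric pulse's centre", {
  fs <- 4000
  x <- numeric(7999)
  x[3500:4500] <- exp(-((-500:500) / 150)^2)  # Gaussian bump at sample 4000
  r <- recording(x, fs, unit = "uV", kind = "neural")
  for (f in list(bandpass_neural(r, c(10, 1500)), highpass_emg(r, 10),
                 bandstop_50(r))) {
    y2 <- f$samples^2
    com <- sum(seq_along(y2) * y2) / sum(y2)
    expect_lt(abs(com - 4000), 1)  # centre of mass within one sample
  }
})

test_that("envelope cross-correlation recovers constructed lags", {
  fs <- 125
  set.seed(2)
  base <- abs(stats::filter(rnorm(2000), rep(1, 25), sides = 2))
  base[is.na(base)] <- 0
  a <- recording(base, fs, unit = "normalized", kind = "trajectory")
  attr(a, "envelope") <- TRUE
  expect_equal(align_by_envelope_xcorr(a, a, 0.5), 0)
  lagged <- recording(c(rep(0, 50), base[1:1950]), fs,
                      unit = "normalized", kind = "trajectory")
  attr(lagged, "envelope") <- TRUE
  # `a` leads the delayed copy by 50 samples
  expect_equal(align_by_envelope_xcorr(a, lagged, 1), 50 / fs)
  expect_equal(align_by_envelope_xcorr(lagged, a, 1),
               -align_by_envelope_xcorr(a, lagged, 1))
  flat <- recording(rep(1, 2000), fs, unit = "normalized", kind = "trajectory")
  attr(flat, "envelope") <- TRUE
  expect_error(align_by_envelope_xcorr(flat, a, 1), "zero-variance")
})

test_that("movement-segment extraction finds constructed bouts", {
  fs <- 125
  flat <- recording(rep(0.5, 1250), fs, unit = "normalized",
                    kind = "trajectory")
  expect_equal(nrow(extract_movement_segments(flat)), 0)
  p <- subject_profile(bout_rate_hz = 0, rng_seed = 1)
  t <- seq(0, 10, by = 1 / fs)
  y <- rep(0.5, length(t))
  bout <- t >= 4 & t < 6
  y[bout] <- 0.5 + 0.3 * (0.6 + 0.4 * sin(2 * pi * 7 * t[bout]))
  tr <- recording(pmin(y, 1), fs, unit = "normalized", kind = "trajectory")
  iv <- extract_movement_segments(tr)
  expect_equal(nrow(iv), 1)
  expect_gt(interval_total_s(iv), 0.9 * 2)
  expect_true(iv$start_s >= 3.5 && iv$end_s <= 6.5)
})

test_that("segment extraction intervals are sorted and disjoint on synthetic whisking", {
  fx <- fx_subject()
  iv <- extract_movement_segments(fx$traj)
  expect_gt(nrow(iv), 1)
  expect_true(all(diff(iv$start_s) > 0))
  expect_true(all(iv$start_s[-1] >= iv$end_s[-nrow(iv)]))
  # each generated bout is covered: gathered movement has higher deviation
  mv <- gather_movement_signal(fx$traj, iv)
  expect_gt(mean(abs(mv$samples - 0.5)), 5 * mean(abs(
    gather_movement_signal(fx$traj,
                           interval_complement(iv, duration_s(fx$traj)))$samples - 0.5)))
})
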