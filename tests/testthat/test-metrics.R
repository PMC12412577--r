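test_that("sliding RMS and Vpp match closed forms", {
  fs <- 1000
  const <- recording(rep(-2, 3000), fs, unit = "uV", kind = "neural")
  w <- window_spec(0.2, 0.1)
  r <- sliding_rms(const, w)
  expect_true(all(abs(r$value - 2) < 1e-12))
  expect_equal(nrow(r), (3000 - 200) %/% 100 + 1)
  expect_true(all(abs(sliding_vpp(const, w)$value) < 1e-12))
  t <- seq(0, 3, by = 1 / fs)
  sine <- recording(3 * sin(2 * pi * 50 * t), fs, unit = "uV", kind = "neural")
  expect_lt(max(abs(sliding_rms(sine, w)$value - 3 / sqrt(2)) / (3 / sqrt(2))),
            0.02)
  expect_lt(max(abs(sliding_vpp(sine, w)$value - 6) / 6), 0.02)
  expect_true(all(sliding_vpp(sine, w)$value >= 0))
})

test_that("SNR formula is 10*log10 of the RMS ratio as printed", {
  expect_equal(snr_db(1, 1), 0)
  expect_equal(snr_db(2, 1), 10 * log10(2))
  expect_equal(snr_db(2, 1), 3.0103, tolerance = 1e-4)
  expect_equal(snr_db(2, 1, power = TRUE), 20 * log10(2))
  expect_true(all(diff(snr_db(c(1, 2, 5, 10), 1)) > 0))
  expect_error(snr_db(0, 1), "positive")
  expect_error(snr_db(1, -1), "positive")
})

test_that("trial SNR needs 10 s of rest and is ~0 dB for identical statistics", {
  fs <- 4000
  set.seed(1)
  x <- recording(rnorm(fs * 30), fs, unit = "uV", kind = "neural")
  move <- interval_set(c(0, 20), c(10, 25))
  rest <- interval_set(c(10, 25), c(20, 30))
  s <- trial_snr(x, move, rest)
  expect_lt(abs(mean(s$value)), 0.5)
  expect_error(trial_snr(x, move, interval_set(10, 15)),
               "at least 10 s")
})

test_that("persistence spectrum concentrates a stationary tone", {
  fs <- 4000
  t <- seq(0, 10, by = 1 / fs)
  s <- recording(sin(2 * pi * 250 * t), fs, unit = "uV", kind = "neural")
  ps <- persistence_spectrum(s)
  expect_true(all(rowSums(ps$counts) == ps$n_segments))  # occupancy conserved
  # the bin holding the highest occupied power level is the tone's bin ...
  top_level <- apply(ps$counts, 1, function(cnt) max(which(cnt > 0)))
  tone_bin <- which.max(top_level)
  expect_lt(abs(ps$freq_hz[tone_bin] - 250), diff(ps$freq_hz[1:2]))
  # ... and its occupancy is concentrated at that level
  occupied <- which(ps$counts[tone_bin, ] > 0)
  expect_lt(diff(range(occupied)), 8)
  tiny <- recording(rnorm(100), fs, unit = "uV", kind = "neural")
  expect_error(persistence_spectrum(tiny), "too short")
})

test_that("in-band power ratio separates in-band and out-of-band tones", {
  fs <- 16000
  t <- seq(0, 6, by = 1 / fs)
  inb <- recording(sin(2 * pi * 100 * t), fs, unit = "uV", kind = "neural")
  out <- recording(sin(2 * pi * 3000 * t), fs, unit = "uV", kind = "neural")
  mix <- recording(sin(2 * pi * 100 * t) + sin(2 * pi * 3000 * t), fs,
                   unit = "uV", kind = "neural")
  r_in <- in_band_power_ratio(inb)$value
  r_out <- in_band_power_ratio(out)$value
  r_mix <- in_band_power_ratio(mix)$value
  expect_true(all(r_in > 0.97))
  expect_true(all(r_out < 0.03))
  expect_true(all(abs(r_mix - 0.5) < 0.05))  # Parseval on the equal-power mix
  expect_true(all(r_in <= 1 & r_out >= 0))
})

test_that("envelope correlation hits the closed-form cases", {
  fs <- 125
  set.seed(3)
  a <- recording(abs(rnorm(1250)) + 0.1, fs, unit = "uV", kind = "neural")
  attr(a, "envelope") <- TRUE
  w <- window_spec(1, 0.5)
  expect_true(all(abs(envelope_correlation(a, a, w)$value - 1) < 1e-12))
  neg <- recording(max(a$samples) - a$samples, fs, unit = "uV", kind = "neural")
  expect_true(all(abs(envelope_correlation(a, neg, w)$value + 1) < 1e-12))
  b <- recording(abs(rnorm(60 * fs)) + 0.1, fs, unit = "uV", kind = "neural")
  c2 <- recording(abs(rnorm(60 * fs)) + 0.1, fs, unit = "uV", kind = "neural")
  expect_lt(mean(abs(envelope_correlation(b, c2, w)$value)), 0.2)
  flat <- recording(rep(1, 1250), fs, unit = "uV", kind = "neural")
  expect_true(all(is.na(envelope_correlation(a, flat, w)$value)))
})

test_that("concordance matches direct evaluation of the formula", {
  y <- c(0, 1, 2, 3, 4)
  r <- concordance_cc(y, y + 1)
  expect_equal(r$rho_c, 0.8)          # 2*2 / (2 + 2 + 1), population variance
  expect_equal(r$rho, 1)
  expect_equal(concordance_cc(y, y)$rho_c, 1)
  y0 <- y - mean(y)
  expect_equal(concordance_cc(y0, -y0)$rho_c, -1)
  expect_equal(concordance_cc(y0, -y0)$rho_c, ref_ccc(y0, -y0))
  expect_error(concordance_cc(y, rep(1, 5)), "zero variance")
  expect_error(concordance_cc(y, y[1:3]), "equal length")
})

test_that("concordance is symmetric, bounded and scale-consistent", {
  set.seed(4)
  for (i in 1:20) {
    y <- rnorm(50)
    yh <- 0.6 * y + rnorm(50, sd = 0.5)
    a <- concordance_cc(y, yh)
    b <- concordance_cc(yh, y)
    expect_equal(a$rho_c, b$rho_c, tolerance = 1e-12)
    expect_lte(abs(a$rho_c), 1)
    expect_lte(abs(a$rho_c), abs(a$rho) + 1e-12)
    # identical positive affine rescaling of both sequences leaves rho_c
    s <- runif(1, 0.5, 3); m <- rnorm(1)
    expect_equal(concordance_cc(s * y + m, s * yh + m)$rho_c, a$rho_c,
                 tolerance = 1e-9)
    expect_equal(a$rho_c, ref_ccc(y, yh), tolerance = 1e-12)
  }
})

test_that("sliding metrics agree with the brute-force oracle", {
  set.seed(5)
  fs <- 2000
  for (i in 1:10) {
    x <- rnorm(round(runif(1, 1.2, 2.5) * fs))
    rec <- recording(x, fs, unit = "uV", kind = "neural")
    w <- window_spec(0.2, 0.1)
    expect_equal(sliding_rms(rec, w)$value,
                 ref_sliding(x, fs, 0.2, 0.1, ref_rms), tolerance = 1e-12)
    expect_equal(sliding_vpp(rec, w)$value,
                 ref_sliding(x, fs, 0.2, 0.1, ref_vpp), tolerance = 1e-12)
  }
})
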