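test_that("cohort generation does the length bookkeeping", {
  cohort <- make_cohort(4, 60, base_seed = 7, heterogeneity = 0.3)
  expect_length(cohort, 4)
  for (ds in cohort) {
    expect_equal(length(ds$neural$samples), 60 * 16000)
    expect_equal(length(ds$trajectory$samples), 60 * 125)
    expect_true(all(ds$trajectory$samples >= 0 & ds$trajectory$samples <= 1))
  }
  expect_error(make_cohort(4, 5), ">= 10")
  expect_error(make_cohort(0, 60), ">= 1")
})

test_that("zero heterogeneity gives identical profiles up to the seed", {
  cohort <- make_cohort(3, 10, base_seed = 2, heterogeneity = 0)
  pr <- attr(cohort, "profiles")
  ref <- pr[[1]]; ref$subject_id <- NULL; ref$rng_seed <- NULL
  for (p in pr[-1]) {
    q <- p; q$subject_id <- NULL; q$rng_seed <- NULL
    expect_equal(q, ref)
  }
  expect_false(pr[[1]]$rng_seed == pr[[2]]$rng_seed)
})

test_that("generation is bit-exact under a fixed seed", {
  a <- make_cohort(2, 10, base_seed = 9, heterogeneity = 0.3)
  b <- make_cohort(2, 10, base_seed = 9, heterogeneity = 0.3)
  expect_identical(a[[1]]$neural$samples, b[[1]]$neural$samples)
  expect_identical(a[[2]]$trajectory$samples, b[[2]]$trajectory$samples)
  p <- subject_profile(rng_seed = 3)
  expect_identical(synthesize_offnerve(p, 5)$samples,
                   synthesize_offnerve(p, 5)$samples)
})

test_that("trajectory respects its range and bout contracts", {
  p0 <- subject_profile(bout_rate_hz = 0, rng_seed = 1)
  flat <- synthesize_trajectory(p0, 20)
  expect_true(all(flat$samples == 0.5))
  fx <- fx_subject()
  expect_true(all(abs(fx$traj$samples - 0.5) <= 0.5))
  expect_error(synthesize_trajectory(p0, -1), "positive")
})

test_that("neural synthesis calibrates movement and rest RMS", {
  fx <- fx_subject()
  iv <- extract_movement_segments(fx$traj)
  rest <- interval_complement(iv, duration_s(fx$traj))
  mv <- gather_movement_signal(fx$neural, iv)
  rs <- gather_movement_signal(fx$neural, rest)
  move_rms <- sqrt(mean(mv$samples^2))
  rest_rms <- sqrt(mean(rs$samples^2))
  expect_lt(abs(move_rms - fx$profile$movement_rms_uv) /
              fx$profile$movement_rms_uv, 0.2)
  expect_lt(abs(rest_rms - fx$profile$noise_rms_uv) /
              fx$profile$noise_rms_uv, 0.2)
  # gain 0 switches modulation off entirely
  p0 <- fx$profile; p0$neural_gain <- 0
  n0 <- synthesize_neural(p0, fx$traj)
  expect_lt(abs(sqrt(mean(n0$samples^2)) - p0$noise_rms_uv) / p0$noise_rms_uv,
            0.1)
})

test_that("neural envelope correlates with the trajectory envelope", {
  p <- subject_profile(rng_seed = 21)
  tr <- synthesize_trajectory(p, 60)
  neu <- synthesize_neural(p, tr)
  env_n <- envelope(bandpass_neural(neu))
  env_t <- envelope(tr)
  r_global <- envelope_correlation(env_n, env_t, window_spec(60, 0))$value
  expect_gte(r_global, 0.7)
})

test_that("injected motor latency is recovered by envelope alignment", {
  p <- subject_profile(motor_latency_ms = 20, rng_seed = 8)
  tr <- synthesize_trajectory(p, 60)
  neu <- synthesize_neural(p, tr)
  lag_ms <- 1000 * align_by_envelope_xcorr(neu, tr, max_lag_s = 0.2)
  expect_lt(abs(lag_ms - 20), 1000 / p$fs_traj_hz)  # within one traj sample
  expect_error(synthesize_neural(subject_profile(motor_latency_ms = 90000), tr),
               "longer than the recording")
})

test_that("off-nerve recordings are uncoupled broadband noise", {
  p <- subject_profile(rng_seed = 12)
  tr <- synthesize_trajectory(p, 60)
  off <- synthesize_offnerve(p, 60)
  env_o <- envelope(bandpass_neural(off))
  env_t <- envelope(tr)
  r <- envelope_correlation(env_o, env_t, window_spec(60, 0))$value
  expect_lt(abs(r), 0.2)
  # SNR ~0 dB for off-nerve, clearly positive on-nerve, gap > 3 dB
  neu <- synthesize_neural(p, tr)
  iv <- extract_movement_segments(tr)
  rest <- interval_complement(iv, 60)
  snr_on <- median(trial_snr(neu, iv, rest)$value)
  snr_off <- median(trial_snr(off, iv, rest)$value)
  expect_lt(abs(snr_off), 1)
  expect_gt(snr_on - snr_off, 3)
})

test_that("in-band concentration is movement-specific on-nerve only", {
  p <- subject_profile(rng_seed = 31)
  tr <- synthesize_trajectory(p, 40)
  neu <- synthesize_neural(p, tr)
  off <- synthesize_offnerve(p, 40)
  iv <- extract_movement_segments(tr)
  rest <- interval_complement(iv, 40)
  ibr_state <- function(rec, set) {
    g <- gather_movement_signal(rec, set)
    mean(in_band_power_ratio(g, window_spec(2, 1))$value, na.rm = TRUE)
  }
  expect_gt(ibr_state(neu, iv), ibr_state(neu, rest))
  expect_lt(abs(ibr_state(off, iv) - ibr_state(off, rest)), 0.05)
})

test_that("profile invariants are enforced", {
  expect_error(subject_profile(noise_rms_uv = 20, movement_rms_uv = 10),
               "below the movement RMS")
  expect_error(subject_profile(motor_latency_ms = -5), "non-negative")
  expect_error(subject_profile(band_edges_hz = c(100, 9000)), "Nyquist")
  expect_error(subject_profile(traj_amplitude_mm = 20), "<= 14")
})
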