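#' Generative parameters of one synthetic subject
#'
#' Describes one synthetic animal: how strongly its nerve signal is modulated
#' by whisking, its resting noise floor, the lag between neural activity and
#' the movement it drives (neural leads), and the statistics of its whisking
#' bouts. The defaults reproduce the study conditions of awake-rabbit
#' extraneural recordings: movement-period RMS about 13.3 uV over a rest
#' floor of about 5.6 uV, whisking energy concentrated below 1500 Hz, and a
#' trajectory normalized to 0--1 (rest baseline 0.5, full scale 0--28 mm).
#'
#' @param subject_id subject label.
#' @param neural_gain uV per unit envelope; `NA` (default) calibrates the
#'   gain so the movement-period RMS hits `movement_rms_uv`.
#' @param motor_latency_ms signal-to-motor lag in ms (neural leads; >= 0).
#' @param noise_rms_uv resting noise floor RMS in uV.
#' @param movement_rms_uv target total RMS during movement in uV; must
#'   exceed `noise_rms_uv`.
#' @param bout_rate_hz expected movement bouts per second.
#' @param bout_duration_s mean bout length in seconds.
#' @param whisk_freq_hz protraction/retraction frequency within a bout, Hz.
#' @param band_edges_hz length-2 neural carrier band in Hz.
#' @param traj_amplitude_mm peak whisker excursion in mm (full scale 28 mm).
#' @param direction `+1` or `-1`: orientation of the whisking excursion
#'   along the measurement axis (whether protraction moves the measured
#'   position above or below the 0.5 rest baseline). A categorical subject
#'   trait set by whisker/sensor geometry; the nerve signal envelope is
#'   unsigned, so the decoder must learn it per subject.
#' @param fs_neural_hz,fs_traj_hz,fs_emg_hz channel sampling rates in Hz.
#' @param rng_seed integer seed; every sample drawn for this subject derives
#'   from it.
#' @return a `subject_profile` list.
#' @export
subject_profile <- function(subject_id = "S1",
                            neural_gain = NA_real_,
                            motor_latency_ms = 20,
                            noise_rms_uv = 5.58,
                            movement_rms_uv = 13.31,
                            bout_rate_hz = 0.25,
                            bout_duration_s = 1.5,
                            whisk_freq_hz = 7,
                            band_edges_hz = c(100, 1500),
                            traj_amplitude_mm = 11.2,
                            direction = 1,
                            fs_neural_hz = 16000,
                            fs_traj_hz = 125,
                            fs_emg_hz = 4000,
                            rng_seed = 1L) {
  if (noise_rms_uv >= movement_rms_uv)
    stop("noise floor must be below the movement RMS", call. = FALSE)
  if (motor_latency_ms < 0)
    stop("motor latency must be non-negative", call. = FALSE)
  if (band_edges_hz[1] <= 0 || band_edges_hz[2] >= fs_neural_hz / 2 ||
      band_edges_hz[1] >= band_edges_hz[2])
    stop("band edges must satisfy 0 < low < high < Nyquist", call. = FALSE)
  if (traj_amplitude_mm < 0 || traj_amplitude_mm > 14)
    stop("trajectory amplitude must keep |trace - 0.5| <= 0.5 (<= 14 mm)",
         call. = FALSE)
  if (!direction %in% c(-1, 1))
    stop("`direction` must be +1 or -1", call. = FALSE)
  structure(list(
    subject_id = subject_id, neural_gain = neural_gain,
    motor_latency_ms = motor_latency_ms, noise_rms_uv = noise_rms_uv,
    movement_rms_uv = movement_rms_uv, bout_rate_hz = bout_rate_hz,
    bout_duration_s = bout_duration_s, whisk_freq_hz = whisk_freq_hz,
    band_edges_hz = band_edges_hz, traj_amplitude_mm = traj_amplitude_mm,
    direction = direction,
    fs_neural_hz = fs_neural_hz, fs_traj_hz = fs_traj_hz,
    fs_emg_hz = fs_emg_hz, rng_seed = as.integer(rng_seed)),
    class = "subject_profile")
}

# evaluate FUN under a local, restored RNG state seeded by `seed`
with_local_seed <- function(seed, FUN) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  FUN()
}

#' Synthesize a whisker trajectory
#'
#' Alternating rest (value 0.5) and whisking bouts. Within a bout the whisker
#' protracts to an offset and oscillates at `whisk_freq_hz` with smooth
#' raised-cosine on/off ramps, mimicking protraction-biased whisking so that
#' the movement envelope carries the trajectory's low-frequency content. The
#' subject's `direction` trait sets whether the excursion is measured above
#' or below the 0.5 baseline.
#'
#' @param profile a [subject_profile].
#' @param duration_s duration in seconds (> 0).
#' @return a normalized trajectory [recording] at `profile$fs_traj_hz`.
#' @export
synthesize_trajectory <- function(profile, duration_s) {
  stopifnot(inherits(profile, "subject_profile"))
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("`duration_s` must be positive", call. = FALSE)
  fs <- profile$fs_traj_hz
  n <- round(duration_s * fs)
  y <- rep(0.5, n)
  amp <- profile$traj_amplitude_mm / 28  # normalized peak deviation
  if (profile$bout_rate_hz > 0 && amp > 0) {
    with_local_seed(profile$rng_seed * 13L + 1L, function() {
      mean_cycle <- 1 / profile$bout_rate_hz
      mean_gap <- max(mean_cycle - profile$bout_duration_s, 0.5)
      t <- runif(1, 0, mean_gap)  # first bout onset
      while (t < duration_s) {
        blen <- max(0.4, rnorm(1, profile$bout_duration_s,
                               0.2 * profile$bout_duration_s))
        i0 <- floor(t * fs) + 1
        i1 <- min(floor((t + blen) * fs), n)
        if (i1 - i0 + 1 >= 4) {
          tt <- (seq.int(i0, i1) - i0) / fs
          ramp_len <- min(0.15, blen / 4)
          ramp <- pmin(1, pmin(tt, blen - tt) / ramp_len)
          ramp <- 0.5 - 0.5 * cos(pi * pmax(ramp, 0))
          osc <- 0.6 + 0.4 * sin(2 * pi * profile$whisk_freq_hz * tt - pi / 2)
          y[i0:i1] <<- 0.5 + profile$direction * amp * ramp * osc
        }
        gap <- max(0.5, rnorm(1, mean_gap, 0.3 * mean_gap))
        t <- t + blen + gap
      }
    })
  }
  y <- pmin(pmax(y, 0), 1)
  recording(y, fs, unit = "normalized", kind = "trajectory")
}

# low-pass movement envelope of a normalized trajectory (10 Hz, |x - 0.5|)
trajectory_envelope <- function(traj, smooth_hz = 10) {
  dev <- abs(traj$samples - 0.5)
  if (length(dev) >= 24L)
    dev <- pmax(butter_filtfilt(dev, traj$fs_hz, "low", smooth_hz), 0)
  recording(dev, traj$fs_hz, unit = "normalized", kind = "trajectory")
}

# band-limited unit-RMS Gaussian carrier
bandlimited_carrier <- function(n, fs, band) {
  w <- rnorm(n)
  x <- butter_filtfilt(w, fs, "pass", band)
  x / sqrt(mean(x^2))
}

# 1/f-shaped unit-RMS noise via FFT spectral shaping
pink_noise <- function(n) {
  w <- rnorm(n)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)           # symmetric frequency index
  shape <- 1 / sqrt(pmax(f, 1))
  x <- Re(fft(fft(w) * shape, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

#' Synthesize an on-nerve extraneural recording
#'
#' Band-limited Gaussian carrier amplitude-modulated by the trajectory's
#' movement envelope (advanced by the subject's signal-to-motor latency:
#' neural leads movement), plus a white-and-pink noise floor at
#' `noise_rms_uv`. When `neural_gain` is `NA` the modulation gain is
#' calibrated so the total movement-period RMS matches `movement_rms_uv`.
#'
#' @param profile a [subject_profile].
#' @param trajectory a normalized trajectory [recording] from
#'   [synthesize_trajectory()].
#' @return a neural [recording] in uV at `profile$fs_neural_hz`.
#' @export
synthesize_neural <- function(profile, trajectory) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(trajectory, "recording"))
  if (min(trajectory$samples) < -1e-9 || max(trajectory$samples) > 1 + 1e-9)
    stop("trajectory must be normalized to 0-1", call. = FALSE)
  dur <- duration_s(trajectory)
  lat_s <- profile$motor_latency_ms / 1000
  if (lat_s >= dur)
    stop("motor latency longer than the recording", call. = FALSE)
  fs <- profile$fs_neural_hz
  n <- round(dur * fs)
  env_tr <- trajectory_envelope(trajectory)
  # neural envelope leads the movement: env_n(t) = env_traj(t + latency)
  t_neu <- (seq_len(n) - 1) / fs
  env_n <- approx(x = (seq_along(env_tr$samples) - 1) / env_tr$fs_hz,
                  y = env_tr$samples, xout = t_neu + lat_s, rule = 2)$y
  with_local_seed(profile$rng_seed * 13L + 2L, function() {
    carrier <- bandlimited_carrier(n, fs, profile$band_edges_hz)
    wn <- rnorm(n)
    pk <- pink_noise(n)
    noise <- profile$noise_rms_uv * (wn + pk) / sqrt(mean((wn + pk)^2))
    gain <- profile$neural_gain
    if (is.na(gain)) {
      mask <- env_n > 0.2 * max(env_n) & max(env_n) > 0
      target <- sqrt(max(profile$movement_rms_uv^2 - profile$noise_rms_uv^2, 0))
      mod_rms <- sqrt(mean((carrier[mask] * env_n[mask])^2))
      gain <- if (any(mask) && mod_rms > 0) target / mod_rms else 0
    }
    recording(gain * carrier * env_n + noise, fs, unit = "uV", kind = "neural")
  })
}

#' Synthesize a whisker-pad EMG recording
#'
#' A second amplitude-modulated channel: broadband carrier (30 Hz to just
#' below Nyquist) modulated by the same movement envelope at roughly half the
#' neural latency, at electromyographic amplitudes (an order of magnitude
#' above the nerve signal).
#'
#' @param profile a [subject_profile].
#' @param trajectory a normalized trajectory [recording].
#' @param movement_rms_uv,noise_rms_uv EMG amplitude targets in uV.
#' @return an EMG [recording] in uV at `profile$fs_emg_hz`.
#' @export
synthesize_emg <- function(profile, trajectory,
                           movement_rms_uv = 120, noise_rms_uv = 8) {
  stopifnot(inherits(profile, "subject_profile"))
  fs <- profile$fs_emg_hz
  dur <- duration_s(trajectory)
  n <- round(dur * fs)
  env_tr <- trajectory_envelope(trajectory)
  lat_s <- profile$motor_latency_ms / 2000
  t_emg <- (seq_len(n) - 1) / fs
  env_e <- approx(x = (seq_along(env_tr$samples) - 1) / env_tr$fs_hz,
                  y = env_tr$samples, xout = t_emg + lat_s, rule = 2)$y
  with_local_seed(profile$rng_seed * 13L + 3L, function() {
    carrier <- bandlimited_carrier(n, fs, c(30, 0.45 * fs))
    noise <- rnorm(n)
    noise <- noise_rms_uv * noise / sqrt(mean(noise^2))
    mask <- env_e > 0.2 * max(env_e) & max(env_e) > 0
    target <- sqrt(max(movement_rms_uv^2 - noise_rms_uv^2, 0))
    mod_rms <- if (any(mask)) sqrt(mean((carrier[mask] * env_e[mask])^2)) else 0
    gain <- if (mod_rms > 0) target / mod_rms else 0
    recording(gain * carrier * env_e + noise, fs, unit = "uV", kind = "emg")
  })
}

#' Synthesize an off-nerve control recording
#'
#' Broadband white noise with no coupling to the trajectory: the electrode-
#' in-connective-tissue control. Its in-band energy ratio follows the flat-
#' spectrum expectation and its movement-vs-rest SNR is about 0 dB.
#'
#' @param profile a [subject_profile].
#' @param duration_s duration in seconds.
#' @return a neural [recording] in uV at `profile$fs_neural_hz`.
#' @export
synthesize_offnerve <- function(profile, duration_s) {
  stopifnot(inherits(profile, "subject_profile"), duration_s > 0)
  fs <- profile$fs_neural_hz
  n <- round(duration_s * fs)
  with_local_seed(profile$rng_seed * 13L + 4L, function() {
    x <- rnorm(n)
    recording(profile$noise_rms_uv * x / sqrt(mean(x^2)), fs,
              unit = "uV", kind = "neural")
  })
}

#' Time-aligned per-subject dataset
#'
#' @param subject_id label.
#' @param neural neural [recording].
#' @param trajectory trajectory [recording].
#' @param emg optional EMG [recording].
#' @param ground_truth_latency_ms generator-injected latency (for recovery
#'   tests); `NA` for real data.
#' @return a `subject_dataset` list.
#' @export
subject_dataset <- function(subject_id, neural, trajectory, emg = NULL,
                            ground_truth_latency_ms = NA_real_) {
  stopifnot(inherits(neural, "recording"), inherits(trajectory, "recording"))
  if (abs(duration_s(neural) - duration_s(trajectory)) > 1 / trajectory$fs_hz)
    stop("neural and trajectory durations differ by more than one trajectory sample",
         call. = FALSE)
  ratio <- neural$fs_hz / trajectory$fs_hz
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("neural rate must be an integer multiple of the trajectory rate",
         call. = FALSE)
  structure(list(subject_id = subject_id, neural = neural,
                 trajectory = trajectory, emg = emg,
                 ground_truth_latency_ms = ground_truth_latency_ms),
            class = "subject_dataset")
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("<subject_dataset %s: %.1f s, neural %g Hz, trajectory %g Hz%s>\n",
              x$subject_id, duration_s(x$neural), x$neural$fs_hz,
              x$trajectory$fs_hz, if (is.null(x$emg)) "" else ", emg"))
  invisible(x)
}

#' Generate a multi-subject synthetic cohort
#'
#' Draws per-subject profiles around the cohort defaults, with multiplicative
#' (log-normal) spread scaled by `heterogeneity` applied to the modulation
#' gain, noise floor, latency, whisking frequency, bout statistics and
#' trajectory amplitude, then synthesizes the paired trajectory/neural (and
#' optionally EMG) channels. Deterministic given `base_seed`.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param duration_s per-subject recording length in seconds (>= 10).
#' @param base_seed integer cohort seed.
#' @param heterogeneity inter-subject spread on a 0--1 scale; 0 makes every
#'   profile identical except for its RNG seed.
#' @param base_profile cohort-mean [subject_profile].
#' @param emg also synthesize the EMG channel.
#' @return list of [subject_dataset]s with per-subject profiles attached as
#'   attribute `"profiles"`.
#' @export
make_cohort <- function(n_subjects, duration_s, base_seed = 1L,
                        heterogeneity = 0.3,
                        base_profile = subject_profile(),
                        emg = FALSE) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("`n_subjects` must be >= 1", call. = FALSE)
  if (!is.numeric(duration_s) || duration_s < 10)
    stop("`duration_s` must be >= 10 s", call. = FALSE)
  if (heterogeneity < 0 || heterogeneity > 1)
    stop("`heterogeneity` must lie in [0, 1]", call. = FALSE)
  n_subjects <- as.integer(n_subjects)
  profiles <- with_local_seed(as.integer(base_seed) * 101L, function() {
    lapply(seq_len(n_subjects), function(i) {
      # log-normal multiplicative spread: `heterogeneity` is the coefficient
      # of variation of the subject-specific physiology (gain, noise floor,
      # signal-to-motor latency, excursion amplitude, carrier band shape);
      # behavioural bout statistics vary at half that spread
      fac <- function(sd_scale = 1)
        exp(rnorm(1, 0, heterogeneity * sd_scale))
      p <- base_profile
      p$subject_id <- sprintf("S%02d", i)
      p$movement_rms_uv <- p$movement_rms_uv * fac()
      p$noise_rms_uv <- min(p$noise_rms_uv * fac(),
                            0.8 * p$movement_rms_uv)
      p$motor_latency_ms <- p$motor_latency_ms * fac()
      p$whisk_freq_hz <- p$whisk_freq_hz * fac(0.5)
      p$bout_rate_hz <- p$bout_rate_hz * fac(0.5)
      p$bout_duration_s <- p$bout_duration_s * fac(0.5)
      p$traj_amplitude_mm <- min(p$traj_amplitude_mm * fac(), 14)
      lo <- p$band_edges_hz[1] * fac()
      hi <- p$band_edges_hz[2] * fac(0.5)
      hi <- min(max(hi, lo + 400), 0.45 * p$fs_neural_hz)
      p$band_edges_hz <- c(lo, hi)
      # measurement-axis orientation: categorical, randomized across
      # subjects whenever the cohort is heterogeneous at all
      if (heterogeneity > 0) p$direction <- sample(c(-1, 1), 1)
      p$rng_seed <- as.integer((base_seed * 1000 + i) %% .Machine$integer.max)
      p
    })
  })
  cohort <- lapply(profiles, function(p) {
    traj <- synthesize_trajectory(p, duration_s)
    neu <- synthesize_neural(p, traj)
    em <- if (emg) synthesize_emg(p, traj) else NULL
    subject_dataset(p$subject_id, neu, traj, emg = em,
                    ground_truth_latency_ms = p$motor_latency_ms)
  })
  attr(cohort, "profiles") <- profiles
  cohort
}
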