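#' Sliding-window RMS
#'
#' Root-mean-square voltage per sliding window (default 200 ms width,
#' 100 ms overlap), the statistic used to quantify movement-period signal
#' amplitude and rest-period noise floors.
#'
#' @param rec a [recording].
#' @param w a [window_spec]; default 200 ms / 100 ms overlap.
#' @return a [sliding_series] of per-window RMS values.
#' @export
sliding_rms <- function(rec, w = window_spec(0.2, 0.1)) {
  r <- slide_apply(rec, w, function(x) sqrt(mean(x^2)))
  sliding_series(r$values, r$layout$t_centers_s, w, metric = "rms")
}

#' Sliding-window peak-to-peak voltage
#'
#' Vpp per window: maximum minus minimum voltage.
#'
#' @inheritParams sliding_rms
#' @return a [sliding_series] of per-window Vpp values.
#' @export
sliding_vpp <- function(rec, w = window_spec(0.2, 0.1)) {
  r <- slide_apply(rec, w, function(x) max(x) - min(x))
  sliding_series(r$values, r$layout$t_centers_s, w, metric = "vpp")
}

#' Signal-to-noise ratio in dB
#'
#' Computed as printed in the field convention used here:
#' `10 * log10(signal_rms / noise_rms)` on the RMS (amplitude) ratio. Set
#' `power = TRUE` for the `20 * log10` power-consistent variant.
#'
#' @param signal_rms RMS during movement (positive).
#' @param noise_rms RMS of the noise floor (positive).
#' @param power use the 20 log10 amplitude-to-power convention instead.
#' @return SNR in dB.
#' @export
snr_db <- function(signal_rms, noise_rms, power = FALSE) {
  if (any(signal_rms <= 0) || any(noise_rms <= 0))
    stop("RMS values must be positive", call. = FALSE)
  (if (power) 20 else 10) * log10(signal_rms / noise_rms)
}

#' Trial-by-trial SNR of movement-related activity
#'
#' Per-window SNR of the movement-period signal against a rest-derived noise
#' floor: the movement portions of `rec` are concatenated, windowed, and each
#' window's RMS is compared with the RMS of the concatenated rest signal.
#' At least 10 s of rest are required to establish the in vivo noise floor.
#'
#' @param rec a neural [recording].
#' @param move an [interval_set] of movement periods.
#' @param rest an [interval_set] of rest periods.
#' @param w a [window_spec]; default 200 ms / 100 ms overlap.
#' @param power passed to [snr_db()].
#' @return a [sliding_series] of per-window SNR values (dB), with the noise
#'   floor RMS in attribute `"noise_rms"`.
#' @export
trial_snr <- function(rec, move, rest, w = window_spec(0.2, 0.1),
                      power = FALSE) {
  stopifnot(inherits(rec, "recording"))
  if (interval_total_s(rest) < 10)
    stop("insufficient noise floor: need at least 10 s of rest", call. = FALSE)
  rest_sig <- gather_movement_signal(rec, rest)
  noise_rms <- sqrt(mean(rest_sig$samples^2))
  move_sig <- gather_movement_signal(rec, move)
  if (!inherits(move_sig, "recording"))
    stop("movement intervals contain no samples", call. = FALSE)
  rms <- sliding_rms(move_sig, w)
  out <- sliding_series(snr_db(rms$value, noise_rms, power = power),
                        rms$t_center_s, w, metric = "snr_db")
  attr(out, "noise_rms") <- noise_rms
  out
}

#' Persistence spectrum
#'
#' Occupancy histogram over (frequency, discretized power level): the signal
#' is divided into `n_segments` overlapping segments (50% overlap), each
#' Hamming-windowed and Fourier-transformed; per-segment power (dB) is
#' discretized into `n_levels` evenly spaced levels spanning the observed
#' dB range, and occupancy counts are aggregated per frequency bin.
#'
#' @param rec a [recording].
#' @param n_segments number of overlapping segments (default 256).
#' @param n_levels number of power levels (default 256).
#' @return a `persistence_spectrum` list with `freq_hz`, `level_db`
#'   (level centres), and `counts` (frequency x level matrix whose rows each
#'   sum to `n_segments`).
#' @export
persistence_spectrum <- function(rec, n_segments = 256L, n_levels = 256L) {
  stopifnot(inherits(rec, "recording"))
  n <- length(rec$samples)
  # 50% overlap: n = L + (S - 1) * L / 2  =>  L = 2n / (S + 1)
  L <- floor(2 * n / (n_segments + 1))
  L <- L - (L %% 2L)
  if (L < 8L)
    stop("signal too short for the requested number of segments", call. = FALSE)
  hop <- L %/% 2L
  ham <- 0.54 - 0.46 * cos(2 * pi * seq_len(L) / (L + 1))  # Hamming
  nf <- L %/% 2L + 1L
  pow_db <- matrix(NA_real_, nrow = n_segments, ncol = nf)
  for (s in seq_len(n_segments)) {
    i0 <- 1L + (s - 1L) * hop
    seg <- rec$samples[i0:(i0 + L - 1L)] * ham
    P <- Mod(fft(seg))^2 / L
    pow_db[s, ] <- 10 * log10(pmax(P[seq_len(nf)], 1e-300))
  }
  rng <- range(pow_db)
  if (diff(rng) < 1e-12) rng <- rng + c(-0.5, 0.5)
  brk <- seq(rng[1], rng[2], length.out = n_levels + 1L)
  lev <- matrix(pmin(pmax(findInterval(pow_db, brk, rightmost.closed = TRUE),
                          1L), n_levels),
                nrow = n_segments)
  counts <- matrix(0L, nrow = nf, ncol = n_levels)
  for (j in seq_len(nf)) counts[j, ] <- tabulate(lev[, j], nbins = n_levels)
  structure(list(freq_hz = (seq_len(nf) - 1L) * rec$fs_hz / L,
                 level_db = (brk[-1L] + brk[-length(brk)]) / 2,
                 counts = counts, n_segments = n_segments),
            class = "persistence_spectrum")
}

#' Sliding in-band power ratio
#'
#' Fraction of spectral energy in the 10--1500 Hz band relative to all
#' energy above 10 Hz, computed per sliding window (default 2 s width, 1 s
#' overlap) after a 50 Hz band-stop filter. Values lie in `[0, 1]`; high
#' values indicate energy concentrated in the neural band.
#'
#' @param rec a [recording] with `fs_hz > 3000`.
#' @param w a [window_spec]; default 2 s width / 1 s overlap.
#' @param band_hz in-band frequency range, Hz.
#' @param floor_hz lower bound of "total" energy, Hz.
#' @param notch apply the 50 Hz band-stop first (default TRUE).
#' @return a [sliding_series] of ratios in `[0, 1]`.
#' @export
in_band_power_ratio <- function(rec, w = window_spec(2, 1),
                                band_hz = c(10, 1500), floor_hz = 10,
                                notch = TRUE) {
  stopifnot(inherits(rec, "recording"))
  if (rec$fs_hz <= 3000)
    stop("`rec` must be sampled above 3 kHz", call. = FALSE)
  if (notch) rec <- bandstop_50(rec)
  fs <- rec$fs_hz
  r <- slide_apply(rec, w, function(x) {
    L <- length(x)
    P <- Mod(fft(x))^2
    nf <- L %/% 2L + 1L
    f <- (seq_len(nf) - 1L) * fs / L
    P <- P[seq_len(nf)]
    tot <- sum(P[f > floor_hz])
    if (tot <= 0) return(NA_real_)
    sum(P[f > band_hz[1] & f <= band_hz[2]]) / tot
  })
  sliding_series(r$values, r$layout$t_centers_s, w, metric = "in_band_ratio")
}

#' Sliding-window Pearson correlation between two envelopes
#'
#' Pearson's r between two envelope recordings per sliding window (200 ms /
#' 100 ms for trajectory comparisons, 4 s / 2 s for EMG comparisons). If the
#' sampling rates differ, the faster envelope is block-mean decimated to the
#' slower rate. Zero-variance windows yield `NA`.
#'
#' @param env_a,env_b envelope [recording]s (e.g. from [envelope()]).
#' @param w a [window_spec].
#' @return a [sliding_series] of per-window correlations.
#' @export
envelope_correlation <- function(env_a, env_b, w = window_spec(0.2, 0.1)) {
  stopifnot(inherits(env_a, "recording"), inherits(env_b, "recording"))
  fs <- min(env_a$fs_hz, env_b$fs_hz)
  a <- decimate_to(env_a, fs)
  b <- decimate_to(env_b, fs)
  n <- min(length(a$samples), length(b$samples))
  av <- a$samples[seq_len(n)]
  bv <- b$samples[seq_len(n)]
  lay <- window_layout(n, fs, w)
  vals <- vapply(lay$starts, function(s) {
    ai <- av[s:(s + lay$w_samp - 1L)]
    bi <- bv[s:(s + lay$w_samp - 1L)]
    if (sd(ai) < 1e-12 || sd(bi) < 1e-12) return(NA_real_)
    cor(ai, bi)
  }, numeric(1))
  sliding_series(vals, lay$t_centers_s, w, metric = "envelope_r")
}

#' Concordance correlation coefficient
#'
#' Lin's concordance correlation coefficient between a ground-truth sequence
#' and a prediction:
#' \deqn{\rho_c = \frac{2\rho\sigma_Y\sigma_{\hat Y}}
#'   {\sigma_Y^2 + \sigma_{\hat Y}^2 + (\mu_Y - \mu_{\hat Y})^2}}
#' with population (1/N) variances by default. It equals the Pearson
#' correlation penalized for mean and scale mismatch, and is the training
#' loss and evaluation metric of the decoder.
#'
#' @param y ground-truth numeric sequence.
#' @param yhat predicted sequence of the same length (>= 2).
#' @param population use population (1/N) variances (default TRUE); FALSE
#'   uses sample (1/(N-1)) variances.
#' @return a `ccc_result` list: `rho_c`, `rho`, `sigma_y`, `sigma_yhat`,
#'   `mu_y`, `mu_yhat`.
#' @export
concordance_cc <- function(y, yhat, population = TRUE) {
  if (length(y) != length(yhat))
    stop("`y` and `yhat` must have equal length", call. = FALSE)
  n <- length(y)
  if (n < 2L) stop("need at least two observations", call. = FALSE)
  denom <- if (population) n else n - 1L
  mu_y <- mean(y); mu_h <- mean(yhat)
  vy <- sum((y - mu_y)^2) / denom
  vh <- sum((yhat - mu_h)^2) / denom
  if (vy <= 0 || vh <= 0)
    stop("concordance undefined: zero variance", call. = FALSE)
  cv <- sum((y - mu_y) * (yhat - mu_h)) / denom
  rho <- cv / sqrt(vy * vh)
  rho_c <- 2 * cv / (vy + vh + (mu_y - mu_h)^2)
  structure(list(rho_c = rho_c, rho = rho,
                 sigma_y = sqrt(vy), sigma_yhat = sqrt(vh),
                 mu_y = mu_y, mu_yhat = mu_h),
            class = "ccc_result")
}

#' @export
print.ccc_result <- function(x, ...) {
  cat(sprintf("CCC rho_c = %.4f (Pearson rho = %.4f)\n", x$rho_c, x$rho))
  invisible(x)
}

#' Tidy a sliding series into long format
#'
#' @param x a [sliding_series].
#' @param subject optional subject label column.
#' @return a data.frame with columns `t_center_s`, `value`, `metric`,
#'   `subject`.
#' @export
tidy_sliding_series <- function(x, subject = NA_character_) {
  stopifnot(inherits(x, "sliding_series"))
  data.frame(t_center_s = x$t_center_s, value = x$value,
             metric = attr(x, "metric"), subject = subject)
}
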