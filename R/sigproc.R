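#' @importFrom stats fft approx median mad sd cor quantile runif rnorm
NULL

# 4th-order Butterworth applied forward-backward (zero phase).
butter_filtfilt <- function(x, fs, type, cutoff_hz, order = 4L) {
  ny <- fs / 2
  wn <- cutoff_hz / ny
  if (any(wn <= 0) || any(wn >= 1))
    stop("filter band must lie strictly inside (0, Nyquist)", call. = FALSE)
  bf <- signal::butter(order, wn, type = type)
  signal::filtfilt(bf, x)
}

#' Band-pass filter for extraneural recordings (1--1500 Hz)
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass, the
#' conditioning applied to every neural channel before analysis or decoding.
#'
#' @param rec a neural [recording]; `fs_hz` must exceed 3000 Hz so the upper
#'   band edge is below Nyquist.
#' @param band_hz numeric length-2 band edges in Hz; default `c(1, 1500)`.
#' @return filtered [recording], same length and sampling rate.
#' @export
bandpass_neural <- function(rec, band_hz = c(1, 1500)) {
  stopifnot(inherits(rec, "recording"))
  if (rec$fs_hz <= 2 * band_hz[2])
    stop("band edge at or above Nyquist frequency", call. = FALSE)
  y <- butter_filtfilt(rec$samples, rec$fs_hz, "pass", band_hz)
  out <- recording(y, rec$fs_hz, unit = rec$unit, kind = rec$kind)
  attr(out, "span_s") <- attr(rec, "span_s")
  out
}

#' High-pass filter for EMG recordings (10 Hz)
#'
#' @param rec an EMG [recording].
#' @param cutoff_hz high-pass cutoff in Hz; default 10.
#' @return filtered [recording], same length and sampling rate.
#' @export
highpass_emg <- function(rec, cutoff_hz = 10) {
  stopifnot(inherits(rec, "recording"))
  y <- butter_filtfilt(rec$samples, rec$fs_hz, "high", cutoff_hz)
  out <- recording(y, rec$fs_hz, unit = rec$unit, kind = rec$kind)
  attr(out, "span_s") <- attr(rec, "span_s")
  out
}

#' Band-stop (notch) filter at the 50 Hz mains frequency
#'
#' A biquad notch (zero on the unit circle at the centre frequency) applied
#' forward-backward; the narrow relative bandwidth at electrophysiology
#' sampling rates makes the biquad numerically robust where a high-order
#' band-stop design is not.
#'
#' @param rec a [recording].
#' @param band_hz stop band in Hz; default `c(45, 55)` (centre 50 Hz).
#' @return filtered [recording], same length and sampling rate.
#' @export
bandstop_50 <- function(rec, band_hz = c(45, 55)) {
  stopifnot(inherits(rec, "recording"))
  f0 <- mean(band_hz)
  bw <- diff(band_hz)
  if (f0 <= 0 || bw <= 0 || f0 >= rec$fs_hz / 2)
    stop("stop band must lie strictly inside (0, Nyquist)", call. = FALSE)
  w0 <- 2 * pi * f0 / rec$fs_hz
  alpha <- sin(w0) * sinh(log(2) / 2 * (bw / f0) * w0 / sin(w0))
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  y <- signal::filtfilt(signal::Arma(b = b, a = a), rec$samples)
  out <- recording(y, rec$fs_hz, unit = rec$unit, kind = rec$kind)
  attr(out, "span_s") <- attr(rec, "span_s")
  out
}

# Analytic signal magnitude via FFT (Hilbert transform).
analytic_magnitude <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

#' Signal envelope
#'
#' Slowly varying amplitude of an oscillatory signal. For neural and EMG
#' channels the envelope is the magnitude of the analytic (Hilbert) signal
#' low-pass smoothed at `smooth_hz`; for normalized trajectories the
#' deviation from the 0.5 rest baseline `|x - 0.5|` is used (optionally
#' smoothed the same way).
#'
#' @param rec a [recording].
#' @param smooth_hz low-pass cutoff for envelope smoothing in Hz; `NA`
#'   disables smoothing. Default 10 Hz for neural/EMG, none for trajectories.
#' @return non-negative envelope [recording] at the same sampling rate.
#' @export
envelope <- function(rec, smooth_hz = if (rec$kind == "trajectory") NA else 10) {
  stopifnot(inherits(rec, "recording"))
  raw <- if (rec$kind == "trajectory" && rec$unit == "normalized") {
    abs(rec$samples - 0.5)
  } else {
    analytic_magnitude(rec$samples)
  }
  if (!is.na(smooth_hz)) {
    if (length(raw) < 24L)
      stop("recording shorter than the envelope filter warm-up", call. = FALSE)
    raw <- butter_filtfilt(raw, rec$fs_hz, "low", smooth_hz)
  }
  out <- recording(pmax(raw, 0), rec$fs_hz, unit = rec$unit, kind = rec$kind)
  attr(out, "envelope") <- TRUE
  attr(out, "span_s") <- attr(rec, "span_s")
  out
}

# block-mean decimation of a recording to a target rate (integer factor)
decimate_to <- function(rec, fs_out) {
  fac <- rec$fs_hz / fs_out
  if (abs(fac - round(fac)) > 1e-9)
    stop("sampling-rate ratio must be an integer for decimation", call. = FALSE)
  fac <- as.integer(round(fac))
  if (fac == 1L) return(rec)
  n <- (length(rec$samples) %/% fac) * fac
  m <- colMeans(matrix(rec$samples[seq_len(n)], nrow = fac))
  recording(m, fs_out, unit = rec$unit, kind = rec$kind)
}

#' Temporal alignment by cross-correlation of envelopes
#'
#' Estimates the signal-to-motor lag between a neural (or EMG) recording and
#' a whisker trajectory by maximizing the normalized cross-correlation of
#' their envelopes. Both envelopes are decimated to the lower of the two
#' sampling rates before correlating. A positive lag means the neural signal
#' leads the movement.
#'
#' @param neural a neural/EMG [recording] (raw; its Hilbert envelope is used)
#'   or a precomputed envelope.
#' @param target a trajectory [recording] (its `|x - 0.5|` envelope is used)
#'   or a precomputed envelope.
#' @param max_lag_s maximum |lag| searched, seconds.
#' @return estimated lag in seconds (positive: `neural` leads `target`).
#' @export
align_by_envelope_xcorr <- function(neural, target, max_lag_s = 0.2) {
  stopifnot(inherits(neural, "recording"), inherits(target, "recording"))
  env_of <- function(r) if (isTRUE(attr(r, "envelope"))) r else envelope(r)
  ea <- env_of(neural)
  eb <- env_of(target)
  fs <- min(ea$fs_hz, eb$fs_hz)
  ea <- decimate_to(ea, fs)
  eb <- decimate_to(eb, fs)
  n <- min(length(ea$samples), length(eb$samples))
  a <- ea$samples[seq_len(n)]
  b <- eb$samples[seq_len(n)]
  if (sd(a) < 1e-12 || sd(b) < 1e-12)
    stop("alignment undefined: zero-variance envelope", call. = FALSE)
  maxk <- min(n - 2L, max(1L, floor(max_lag_s * fs)))
  lags <- (-maxk):maxk
  cc <- vapply(lags, function(k) {
    # positive k: `a` leads, i.e. a[t] matches b[t + k]
    if (k >= 0) {
      ai <- a[seq_len(n - k)]; bi <- b[(1 + k):n]
    } else {
      ai <- a[(1 - k):n]; bi <- b[seq_len(n + k)]
    }
    if (sd(ai) < 1e-12 || sd(bi) < 1e-12) return(-Inf)
    cor(ai, bi)
  }, numeric(1))
  lags[which.max(cc)] / fs
}

#' Movement-segment extraction from a whisker trajectory
#'
#' Finds motion periods (onset to cessation of whisker movement) as
#' excursions of the smoothed trajectory deviation `|x - 0.5|` above a
#' threshold. The default threshold is a robust rest-floor estimate
#' (median + 3 x MAD of the deviation). Gaps shorter than `min_gap_s` are
#' merged and bouts shorter than `min_bout_s` dropped.
#'
#' @param traj a normalized trajectory [recording] (values in 0--1, rest
#'   baseline 0.5).
#' @param threshold deviation threshold; `NULL` uses the robust default.
#' @param min_gap_s merge gaps shorter than this (seconds).
#' @param min_bout_s drop detected bouts shorter than this (seconds).
#' @return an [interval_set] of motion periods.
#' @export
extract_movement_segments <- function(traj, threshold = NULL,
                                      min_gap_s = 0.1, min_bout_s = 0.08) {
  stopifnot(inherits(traj, "recording"))
  if (traj$unit != "normalized" || min(traj$samples) < -1e-9 ||
      max(traj$samples) > 1 + 1e-9)
    stop("`traj` must be a normalized 0-1 trajectory", call. = FALSE)
  fs <- traj$fs_hz
  dev <- abs(traj$samples - 0.5)
  if (length(dev) >= 24L) dev <- pmax(butter_filtfilt(dev, fs, "low", 10), 0)
  if (is.null(threshold)) {
    threshold <- median(dev) + 3 * mad(dev)
    if (threshold < 1e-6) threshold <- 0.02  # flat trace guard
  }
  above <- dev > threshold
  if (!any(above)) return(interval_set())
  r <- rle(above)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  seg <- cbind(starts_i[r$values], ends_i[r$values])
  # merge gaps shorter than min_gap_s
  if (nrow(seg) > 1L) {
    merged <- seg[1L, , drop = FALSE]
    for (i in 2L:nrow(seg)) {
      gap <- (seg[i, 1] - merged[nrow(merged), 2] - 1) / fs
      if (gap < min_gap_s) {
        merged[nrow(merged), 2] <- seg[i, 2]
      } else {
        merged <- rbind(merged, seg[i, ])
      }
    }
    seg <- merged
  }
  keep <- (seg[, 2] - seg[, 1] + 1) / fs >= min_bout_s
  seg <- seg[keep, , drop = FALSE]
  if (!nrow(seg)) return(interval_set())
  interval_set((seg[, 1] - 1) / fs, seg[, 2] / fs)
}

# 1-based sample indices of a half-open [start_s, end_s) interval
interval_sample_idx <- function(iv_start, iv_end, fs, n) {
  i0 <- floor(iv_start * fs) + 1
  i1 <- min(floor(iv_end * fs), n)
  if (i1 < i0) integer() else seq.int(i0, i1)
}

#' Concatenate the in-interval portions of a recording
#'
#' Extracts and concatenates, in temporal order, the samples falling in each
#' interval, yielding e.g. a movement-only neural trace.
#'
#' @param rec a [recording].
#' @param intervals an [interval_set].
#' @return a [recording] containing the concatenated samples (possibly of
#'   length zero is not permitted; an empty interval set yields an error-free
#'   zero-length numeric, returned as a plain numeric vector).
#' @export
gather_movement_signal <- function(rec, intervals) {
  stopifnot(inherits(rec, "recording"), inherits(intervals, "interval_set"))
  n <- length(rec$samples)
  idx <- unlist(lapply(seq_len(nrow(intervals)), function(i) {
    interval_sample_idx(intervals$start_s[i], intervals$end_s[i], rec$fs_hz, n)
  }))
  if (!length(idx)) return(numeric())
  recording(rec$samples[idx], rec$fs_hz, unit = rec$unit, kind = rec$kind)
}
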