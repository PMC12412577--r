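#' Uniformly sampled recording
#'
#' Container for a single uniformly sampled channel: extraneural multi-unit
#' activity (microvolts), whisker-pad EMG (microvolts) or a whisker
#' trajectory (millimetres or normalized to 0--1 with rest baseline 0.5).
#'
#' @param samples numeric vector of samples, no missing values.
#' @param fs_hz sampling rate in Hz (positive scalar).
#' @param unit one of `"uV"`, `"mm"`, `"normalized"`.
#' @param kind one of `"neural"`, `"emg"`, `"trajectory"`.
#'
#' @return An object of class `recording`: a list with fields `samples`,
#'   `fs_hz`, `unit`, `kind`.
#' @export
#' @examples
#' r <- recording(sin(2 * pi * 5 * seq(0, 1, by = 1 / 1000)), 1000,
#'                unit = "uV", kind = "neural")
#' duration_s(r)
recording <- function(samples, fs_hz,
                      unit = c("uV", "mm", "normalized"),
                      kind = c("neural", "emg", "trajectory")) {
  unit <- match.arg(unit)
  kind <- match.arg(kind)
  if (!is.numeric(samples) || length(samples) < 1L)
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  if (anyNA(samples))
    stop("`samples` contains missing values", call. = FALSE)
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || !is.finite(fs_hz) || fs_hz <= 0)
    stop("`fs_hz` must be a positive finite scalar", call. = FALSE)
  structure(list(samples = as.numeric(samples), fs_hz = as.numeric(fs_hz),
                 unit = unit, kind = kind),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording: %s, %g Hz, %.3f s, unit %s>\n",
              x$kind, x$fs_hz, duration_s(x), x$unit))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a [recording].
#' @return length of the recording in seconds.
#' @export
duration_s <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  length(rec$samples) / rec$fs_hz
}

#' Crop a recording to a half-open time interval
#'
#' Extracts samples in `[from_s, to_s)` using the convention
#' `sample index = floor(t * fs)` (0-based time, 1-based storage). The crop
#' range is remembered in the `"span_s"` attribute so that downstream
#' normalization/testing code can check split provenance.
#'
#' @param rec a [recording].
#' @param from_s,to_s crop boundaries in seconds, relative to the start of
#'   `rec`.
#' @return a cropped [recording] carrying a `"span_s"` attribute.
#' @export
crop_recording <- function(rec, from_s, to_s) {
  stopifnot(inherits(rec, "recording"), to_s > from_s, from_s >= 0)
  i0 <- floor(from_s * rec$fs_hz) + 1L
  i1 <- min(floor(to_s * rec$fs_hz), length(rec$samples))
  if (i1 < i0) stop("crop interval contains no samples", call. = FALSE)
  out <- recording(rec$samples[i0:i1], rec$fs_hz, unit = rec$unit, kind = rec$kind)
  parent <- attr(rec, "span_s")
  off <- if (is.null(parent)) 0 else parent[1L]
  attr(out, "span_s") <- c(off + (i0 - 1L) / rec$fs_hz, off + i1 / rec$fs_hz)
  out
}

#' Set of disjoint half-open time intervals
#'
#' Intervals are half-open `[start_s, end_s)` in seconds, stored sorted and
#' non-overlapping; they describe movement bouts ("motion periods") of a
#' whisker trajectory.
#'
#' @param start_s,end_s numeric vectors of equal length.
#' @return an `interval_set`: a data.frame with columns `start_s`, `end_s`.
#' @export
interval_set <- function(start_s = numeric(), end_s = numeric()) {
  stopifnot(length(start_s) == length(end_s))
  df <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s))
  if (nrow(df)) {
    df <- df[order(df$start_s), , drop = FALSE]
    rownames(df) <- NULL
    if (any(df$end_s <= df$start_s))
      stop("interval ends must exceed starts", call. = FALSE)
    if (nrow(df) > 1L && any(df$start_s[-1L] < df$end_s[-nrow(df)]))
      stop("intervals must be non-overlapping", call. = FALSE)
  }
  class(df) <- c("interval_set", "data.frame")
  df
}

#' Total duration covered by an interval set
#' @param x an [interval_set].
#' @return summed interval length in seconds.
#' @export
interval_total_s <- function(x) {
  stopifnot(inherits(x, "interval_set"))
  if (!nrow(x)) return(0)
  sum(x$end_s - x$start_s)
}

#' Complement of an interval set within a span
#'
#' @param x an [interval_set].
#' @param span_s total span `[0, span_s)` in seconds.
#' @return an [interval_set] covering the gaps.
#' @export
interval_complement <- function(x, span_s) {
  stopifnot(inherits(x, "interval_set"), span_s > 0)
  if (!nrow(x)) return(interval_set(0, span_s))
  starts <- c(0, x$end_s)
  ends <- c(x$start_s, span_s)
  keep <- ends > starts + 1e-12
  interval_set(starts[keep], ends[keep])
}

#' Sliding-window specification
#'
#' @param width_s window width in seconds.
#' @param overlap_s overlap between consecutive windows in seconds;
#'   `0 <= overlap_s < width_s`.
#' @return a `window_spec` list with fields `width_s`, `overlap_s`.
#' @export
window_spec <- function(width_s, overlap_s = 0) {
  if (!is.numeric(width_s) || width_s <= 0)
    stop("`width_s` must be positive", call. = FALSE)
  if (!is.numeric(overlap_s) || overlap_s < 0 || overlap_s >= width_s)
    stop("`overlap_s` must satisfy 0 <= overlap_s < width_s", call. = FALSE)
  structure(list(width_s = width_s, overlap_s = overlap_s), class = "window_spec")
}

# Window bookkeeping: start indices (1-based) of each window over n samples.
# Returns NULL-count layout: list(starts, w_samp, stride_samp, t_centers_s).
window_layout <- function(n, fs_hz, w) {
  stopifnot(inherits(w, "window_spec"))
  w_samp <- round(w$width_s * fs_hz)
  stride <- round((w$width_s - w$overlap_s) * fs_hz)
  if (w_samp < 1L || stride < 1L)
    stop("window shorter than one sample at this sampling rate", call. = FALSE)
  if (n < w_samp)
    stop("signal shorter than one window", call. = FALSE)
  nw <- (n - w_samp) %/% stride + 1L
  starts <- 1L + (seq_len(nw) - 1L) * stride
  list(starts = starts, w_samp = w_samp, stride_samp = stride,
       t_centers_s = (starts - 1L) / fs_hz + w$width_s / 2)
}

#' Per-window statistic series
#'
#' @param values per-window statistic values.
#' @param t_centers_s window centre times in seconds.
#' @param window the [window_spec] used.
#' @param metric short metric label.
#' @return a `sliding_series` data.frame with columns `t_center_s`, `value`.
#' @export
sliding_series <- function(values, t_centers_s, window, metric = "stat") {
  stopifnot(length(values) == length(t_centers_s), inherits(window, "window_spec"))
  df <- data.frame(t_center_s = as.numeric(t_centers_s), value = as.numeric(values))
  attr(df, "window") <- window
  attr(df, "metric") <- metric
  class(df) <- c("sliding_series", "data.frame")
  df
}

# apply FUN over sliding windows of rec$samples
slide_apply <- function(rec, w, FUN) {
  stopifnot(inherits(rec, "recording"))
  lay <- window_layout(length(rec$samples), rec$fs_hz, w)
  vals <- vapply(lay$starts, function(s) {
    FUN(rec$samples[s:(s + lay$w_samp - 1L)])
  }, numeric(1))
  list(values = vals, layout = lay)
}
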