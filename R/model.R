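#' Streaming input/output specification
#'
#' Couples the neural sampling rate, the trajectory (output) rate and the
#' input window length. The decoder consumes sliding windows of `n_pad`
#' neural samples advancing by `fs_data / fs_laser` samples, emitting one
#' normalized position per stride.
#'
#' @param fs_data neural sampling rate, Hz (default 16000).
#' @param fs_laser trajectory output rate, Hz (default 125). Must divide
#'   `fs_data`.
#' @param n_pad input window length in samples (default 2000); must be at
#'   least one stride and a multiple of 16 (the handcrafted sub-window
#'   count).
#' @return a `stream_spec` list with fields `fs_data`, `fs_laser`, `n_pad`,
#'   `stride`.
#' @export
stream_spec <- function(fs_data = 16000, fs_laser = 125, n_pad = 2000) {
  stride <- fs_data / fs_laser
  if (abs(stride - round(stride)) > 1e-9)
    stop("`fs_data` must be an integer multiple of `fs_laser`", call. = FALSE)
  stride <- as.integer(round(stride))
  if (n_pad < stride)
    stop("`n_pad` must be at least one stride", call. = FALSE)
  if (n_pad %% 16L != 0L)
    stop("`n_pad` must be a multiple of 16", call. = FALSE)
  structure(list(fs_data = fs_data, fs_laser = fs_laser,
                 n_pad = as.integer(n_pad), stride = stride),
            class = "stream_spec")
}

#' Sliding input windows of the streaming contract
#'
#' Window `k` (k = 0, 1, ...) covers samples
#' `[1 + k * stride, n_pad + k * stride]`, so consecutive windows share
#' `n_pad - stride` samples and an input of exactly `n_pad` samples yields
#' one window. Each window is paired with the trajectory sample nearest its
#' end time.
#'
#' @param x a neural [recording] (or a numeric vector) sampled at
#'   `spec$fs_data`.
#' @param spec a [stream_spec].
#' @return a list with `starts` (1-based window start indices), `n_windows`,
#'   `traj_idx` (1-based trajectory sample aligned with each window) and
#'   `t_end_s` (window end times).
#' @export
stream_windows <- function(x, spec) {
  stopifnot(inherits(spec, "stream_spec"))
  n <- if (inherits(x, "recording")) length(x$samples) else length(x)
  if (n < spec$n_pad)
    stop(sprintf("input shorter than one window (%d < %d samples)",
                 n, spec$n_pad), call. = FALSE)
  K <- (n - spec$n_pad) %/% spec$stride + 1L
  k <- seq_len(K) - 1L
  ends <- spec$n_pad + k * spec$stride
  list(starts = 1L + k * spec$stride,
       n_windows = K,
       traj_idx = as.integer(round(ends / spec$stride)),
       t_end_s = ends / spec$fs_data)
}

#' Handcrafted features of one input window
#'
#' Splits an `n_pad`-sample window into 16 sub-windows (length = stride =
#' `n_pad / 16`) and computes ten classical surface-electromyography-style
#' amplitude/complexity features per sub-window: mean absolute value (MAV),
#' simple square integral (SSI), average amplitude change (AAC), standard
#' deviation (STD), RMS, waveform length (WL), zero crossings (ZC), slope
#' sign changes (SSC), Willison amplitude (WAMP) and variance (VAR).
#' Deviation-style features use population (1/N) variance.
#'
#' @param window numeric vector of raw (microvolt) samples, length a
#'   multiple of 16.
#' @param norm optional [compute_norm_params()] object; when supplied each
#'   feature is z-scored by its stored mean/sd.
#' @param wamp_thr Willison amplitude threshold in the window's units
#'   (default 10).
#' @return a 10 x 16 matrix (features x sub-windows) with feature rownames.
#' @export
extract_handcrafted <- function(window, norm = NULL, wamp_thr = 10) {
  stopifnot(is.numeric(window), length(window) %% 16L == 0L)
  if (!is.null(norm)) wamp_thr <- norm$wamp_thr
  m <- length(window) %/% 16L
  feats <- vapply(seq_len(16L), function(w) {
    x <- window[((w - 1L) * m + 1L):(w * m)]
    d <- diff(x)
    mu <- mean(x)
    v <- mean(x^2) - mu^2
    v <- max(v, 0)
    c(MAV = mean(abs(x)),
      SSI = sum(x^2),
      AAC = mean(abs(d)),
      STD = sqrt(v),
      RMS = sqrt(mean(x^2)),
      WL = sum(abs(d)),
      ZC = sum(x[-length(x)] * x[-1] < 0),
      SSC = sum((x[2:(m - 1)] - x[1:(m - 2)]) *
                  (x[2:(m - 1)] - x[3:m]) > 0),
      WAMP = sum(abs(d) > wamp_thr),
      VAR = v)
  }, numeric(10))
  if (!is.null(norm))
    feats <- (feats - norm$feature_means) / norm$feature_stds
  feats
}

# uniform init in +/- 1/sqrt(fan_in)
init_mat <- function(nr, nc, fan_in = nc) {
  matrix(runif(nr * nc, -1, 1) / sqrt(fan_in), nr, nc)
}

#' Initialize encoder parameters
#'
#' @param seed integer seed for the draw.
#' @param n_pad input window length (consistency check only).
#' @return named list of encoder weight matrices.
#' @export
init_encoder_params <- function(seed = 1L, n_pad = 2000L) {
  with_local_seed(as.integer(seed) * 7L + 3L, function() {
    H <- 30L
    lcb <- numeric(4L * H); lcb[(H + 1L):(2L * H)] <- 1  # forget bias
    lhb <- numeric(4L * H); lhb[(H + 1L):(2L * H)] <- 1
    # the 2-D kernels see nonnegative, nearly constant pooled maps: give
    # them a positive DC gain at init (centred weights + offset) so the
    # ReLU chain starts in the active regime -- an all-negative
    # pre-activation map would zero every conv gradient permanently
    dc <- function(W, gain) W - mean(W) + gain / length(W)
    list(c1w = init_mat(16L, 7L, 7L), c1b = rep(0.05, 16L),
         c2w = dc(init_mat(3L, 3L, 9L), 0.5), c2b = 0.1,
         c3w = dc(init_mat(3L, 3L, 9L), 0.5), c3b = 0.1,
         lcx = init_mat(4L * H, 1L, 31L), lch = init_mat(4L * H, H, 31L),
         lcb = lcb,
         lhx = init_mat(4L * H, 10L, 40L), lhh = init_mat(4L * H, H, 40L),
         lhb = lhb,
         hdw = init_mat(H, H, H), hdb = numeric(H))
  })
}

#' Initialize decoder parameters
#'
#' @param seed integer seed for the draw.
#' @return named list of decoder weight matrices (fusion dense producing the
#'   60-dim feature vector, 30-dim key/query/value transforms, scalar output
#'   head).
#' @export
init_decoder_params <- function(seed = 1L) {
  with_local_seed(as.integer(seed) * 7L + 4L, function() {
    H <- 30L
    list(fw = init_mat(2L * H, 2L * H, 2L * H), fb = numeric(2L * H),
         kw = init_mat(H, 2L * H, 2L * H), kb = numeric(H),
         qw = init_mat(H, 2L * H, 2L * H), qb = numeric(H),
         vw = init_mat(H, 2L * H, 2L * H), vb = numeric(H),
         ow = runif(H, -1, 1) / sqrt(H), ob = 0)
  })
}

#' Per-subject normalization parameters
#'
#' Computes the statistics used to give each individual's input a zero-mean,
#' unit-variance distribution: raw signal mean/sd plus per-feature mean/sd
#' of the handcrafted features over non-overlapping windows. Statistics must
#' come from the subject's own training or adaptation split, never the test
#' split; the source time span is recorded for hygiene checks.
#'
#' @param rec the subject's neural [recording] (training/adaptation split).
#' @param spec a [stream_spec].
#' @param max_duration_s cap on the amount of data used (default 1000 s for
#'   training subjects; use <= 500 s for adaptation data).
#' @param wamp_thr Willison amplitude threshold (microvolts).
#' @return a `norm_params` list with fields `raw_mean`, `raw_std`,
#'   `feature_means`, `feature_stds`, `wamp_thr`, `source_duration_s`,
#'   `source_span_s`.
#' @export
compute_norm_params <- function(rec, spec = stream_spec(),
                                max_duration_s = 1000, wamp_thr = 10) {
  stopifnot(inherits(rec, "recording"), inherits(spec, "stream_spec"))
  x <- rec$samples
  n_use <- min(length(x), round(max_duration_s * rec$fs_hz))
  x <- x[seq_len(n_use)]
  if (length(x) < spec$n_pad)
    stop("normalization source shorter than one input window", call. = FALSE)
  raw_sd <- sd(x)
  if (raw_sd < 1e-12)
    stop("zero-variance normalization source", call. = FALSE)
  starts <- seq.int(1L, length(x) - spec$n_pad + 1L, by = spec$n_pad)
  fs <- wn_feature_stats(x, as.integer(starts), spec$n_pad, wamp_thr)
  span <- attr(rec, "span_s")
  if (is.null(span)) span <- c(0, duration_s(rec))
  structure(list(raw_mean = mean(x), raw_std = raw_sd,
                 feature_means = as.numeric(fs$mean),
                 feature_stds = as.numeric(fs$sd),
                 wamp_thr = wamp_thr,
                 source_duration_s = n_use / rec$fs_hz,
                 source_span_s = c(span[1], span[1] + n_use / rec$fs_hz)),
            class = "norm_params")
}

#' One attention step over the feature buffer
#'
#' Reference (pure R) implementation of the temporal self-attention module:
#' each of the 16 buffered feature vectors is mapped through ReLU key,
#' query and value transforms; per-slot saliences `k' q / 4` are
#' softmax-normalized into 16 scores and the context is the score-weighted
#' sum of values.
#'
#' @param buffer 60 x 16 matrix; column 1 is the current feature vector
#'   `F_t`, columns 2..16 the preceding 15 steps (zero columns before the
#'   sequence starts).
#' @param dec decoder parameter list from [init_decoder_params()].
#' @return list with `scores` (16, summing to 1) and `context` (30-vector).
#' @export
attention_step <- function(buffer, dec) {
  stopifnot(is.matrix(buffer), nrow(buffer) == 60L, ncol(buffer) == 16L)
  relu <- function(z) pmax(z, 0)
  K <- relu(dec$kw %*% buffer + dec$kb)
  Q <- relu(dec$qw %*% buffer + dec$qb)
  V <- relu(dec$vw %*% buffer + dec$vb)
  logits <- colSums(K * Q) / 4
  logits <- logits - max(logits)
  s <- exp(logits) / sum(exp(logits))
  list(scores = as.numeric(s), context = as.numeric(V %*% s))
}

#' One decoding step
#'
#' Reference (pure R) implementation of a single output step: fuse the two
#' pathway latents into the 60-dim feature vector `F_t`, push it onto the
#' buffer, attend over the buffer and squash the context to a normalized
#' position in (0, 1).
#'
#' @param hand_latent,cnn_latent 30-vectors from the two encoder pathways.
#' @param buffer 60 x 16 buffer from the previous step (zeros initially).
#' @param dec decoder parameter list.
#' @return list with `y` (scalar in (0,1)), `buffer` (updated), `scores`.
#' @export
decode_step <- function(hand_latent, cnn_latent, buffer, dec) {
  stopifnot(length(hand_latent) == 30L, length(cnn_latent) == 30L)
  Ft <- as.numeric(dec$fw %*% c(hand_latent, cnn_latent) + dec$fb)
  buffer <- cbind(Ft, buffer[, 1:15, drop = FALSE], deparse.level = 0)
  at <- attention_step(buffer, dec)
  z <- sum(dec$ow * at$context) + dec$ob
  list(y = 1 / (1 + exp(-z)), buffer = buffer, scores = at$scores)
}

#' Full forward pass: neural recording to predicted trajectory
#'
#' Streams the recording through the encoder (handcrafted + CNN pathways)
#' and the attention decoder, emitting one normalized position per stride.
#' The attention buffer starts at zero; the first 15 outputs are warm-up
#' predictions (flagged in the `"warmup"` attribute).
#'
#' @param rec a neural [recording] sampled at `spec$fs_data`.
#' @param encoder,decoder parameter lists.
#' @param norm a [compute_norm_params()] object for this subject.
#' @param spec a [stream_spec].
#' @param mm return millimetres (times 28) instead of normalized 0--1.
#' @return a trajectory [recording] at `spec$fs_laser`, with attributes
#'   `"traj_idx"` (aligned trajectory sample per output) and `"warmup"`.
#' @export
whiskernet_forward <- function(rec, encoder, decoder, norm,
                               spec = stream_spec(), mm = FALSE) {
  stopifnot(inherits(rec, "recording"), inherits(norm, "norm_params"))
  sw <- stream_windows(rec, spec)
  lat <- wn_encoder_forward(rec$samples, as.integer(sw$starts), spec$n_pad,
                            unclass(norm), encoder)
  y <- as.numeric(wn_decoder_forward(lat, decoder))
  out <- recording(if (mm) 28 * y else y, spec$fs_laser,
                   unit = if (mm) "mm" else "normalized",
                   kind = "trajectory")
  attr(out, "traj_idx") <- sw$traj_idx
  attr(out, "warmup") <- seq_len(min(15L, length(y)))
  out
}

# encoder latents for cached (frozen-encoder) decoding
encoder_latents <- function(rec, encoder, norm, spec = stream_spec()) {
  sw <- stream_windows(rec, spec)
  list(lat = wn_encoder_forward(rec$samples, as.integer(sw$starts),
                                spec$n_pad, unclass(norm), encoder),
       traj_idx = sw$traj_idx, starts = sw$starts)
}
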