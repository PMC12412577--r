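# Independent brute-force reference implementations used as oracles.

# naive per-window statistic: explicit loop, no shared code with the package
ref_sliding <- function(x, fs, width_s, overlap_s, FUN) {
  wlen <- round(width_s * fs)
  stride <- round((width_s - overlap_s) * fs)
  out <- c()
  s <- 1
  while (s + wlen - 1 <= length(x)) {
    out <- c(out, FUN(x[s:(s + wlen - 1)]))
    s <- s + stride
  }
  out
}

ref_rms <- function(x) sqrt(sum(x^2) / length(x))
ref_vpp <- function(x) max(x) - min(x)

ref_inband <- function(x, fs, band = c(10, 1500), floor_hz = 10) {
  P <- Mod(fft(x))^2
  nf <- length(x) %/% 2 + 1
  f <- (seq_len(nf) - 1) * fs / length(x)
  P <- P[seq_len(nf)]
  sum(P[f > band[1] & f <= band[2]]) / sum(P[f > floor_hz])
}

# direct evaluation of the concordance formula with population moments
ref_ccc <- function(y, yh) {
  n <- length(y)
  my <- sum(y) / n; mh <- sum(yh) / n
  vy <- sum((y - my)^2) / n; vh <- sum((yh - mh)^2) / n
  cv <- sum((y - my) * (yh - mh)) / n
  2 * cv / (vy + vh + (my - mh)^2)
}

# reference recurrent forward pass (input d x T, last hidden state)
ref_lstm <- function(X, Wx, Wh, b) {
  H <- nrow(Wh) / 4
  sig <- function(z) 1 / (1 + exp(-z))
  h <- numeric(H); cst <- numeric(H)
  for (t in seq_len(ncol(X))) {
    z <- Wx %*% X[, t] + Wh %*% h + b
    gi <- sig(z[1:H]); gf <- sig(z[(H + 1):(2 * H)])
    gg <- tanh(z[(2 * H + 1):(3 * H)]); go <- sig(z[(3 * H + 1):(4 * H)])
    cst <- gf * cst + gi * gg
    h <- go * tanh(cst)
  }
  as.numeric(h)
}

# reference encoder forward for a single raw window (pure R)
ref_encoder_window <- function(xw, enc, norm) {
  relu <- function(z) pmax(z, 0)
  feats <- extract_handcrafted(xw, wamp_thr = norm$wamp_thr)
  feats <- (feats - norm$feature_means) / norm$feature_stds
  lat_h <- as.numeric(enc$hdw %*% ref_lstm(feats, enc$lhx, enc$lhh, enc$lhb) +
                        enc$hdb)
  xn <- (xw - norm$raw_mean) / norm$raw_std
  L1 <- length(xn) - ncol(enc$c1w) + 1
  a1 <- sapply(seq_len(L1), function(j)
    enc$c1w %*% xn[j:(j + ncol(enc$c1w) - 1)] + enc$c1b)  # 16 x L1
  r1 <- relu(a1)
  pool24 <- function(A) {
    Ro <- nrow(A) %/% 2; To <- ncol(A) %/% 4
    out <- matrix(0, Ro, To)
    for (r in seq_len(Ro)) for (cc in seq_len(To))
      out[r, cc] <- mean(A[(2 * r - 1):(2 * r), (4 * cc - 3):(4 * cc)])
    out
  }
  conv33 <- function(X, W, b) {
    R <- nrow(X) - 2; T <- ncol(X) - 2
    out <- matrix(0, R, T)
    for (r in seq_len(R)) for (cc in seq_len(T))
      out[r, cc] <- sum(W * X[r:(r + 2), cc:(cc + 2)]) + b
    out
  }
  p1 <- pool24(r1)
  p2 <- pool24(relu(conv33(p1, enc$c2w, enc$c2b)))
  xseq <- relu(conv33(p2, enc$c3w, enc$c3b))  # 1 x T4
  lat_c <- ref_lstm(xseq, enc$lcx, enc$lch, enc$lcb)
  c(lat_h, lat_c)
}

# reference decoder forward over latents using the exported step functions
ref_decoder_forward <- function(lat, dec) {
  buffer <- matrix(0, 60, 16)
  y <- numeric(ncol(lat))
  for (t in seq_len(ncol(lat))) {
    st <- decode_step(lat[1:30, t], lat[31:60, t], buffer, dec)
    y[t] <- st$y
    buffer <- st$buffer
  }
  y
}
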