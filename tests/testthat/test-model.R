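test_that("stream windows follow the index arithmetic", {
  spec <- stream_spec(16000, 125, 2000)
  expect_equal(spec$stride, 128)
  sw <- stream_windows(numeric(2000), spec)
  expect_equal(sw$n_windows, 1)           # boundary: exactly one window
  sw2 <- stream_windows(numeric(2000 + 128), spec)
  expect_equal(sw2$n_windows, 2)
  expect_equal(sw2$starts[2] - sw2$starts[1], 128)
  # consecutive windows share n_pad - stride samples
  overlap <- (sw2$starts[1] + spec$n_pad - 1) - sw2$starts[2] + 1
  expect_equal(overlap, 2000 - 128)
  expect_error(stream_windows(numeric(1999), spec), "shorter")
  set.seed(6)
  for (i in 1:20) {
    n <- sample(2000:100000, 1)
    expect_equal(stream_windows(numeric(n), spec)$n_windows,
                 (n - 2000) %/% 128 + 1)   # index-arithmetic oracle
  }
  expect_error(stream_spec(16000, 126), "integer multiple")
})

test_that("handcrafted features match their definitions", {
  z <- extract_handcrafted(numeric(2000))
  expect_equal(dim(z), c(10, 16))
  expect_true(all(z[c("MAV", "SSI", "AAC"), ] == 0))
  cst <- extract_handcrafted(rep(-2.5, 2000))
  expect_true(all(cst["MAV", ] == 2.5))
  expect_true(all(cst[c("AAC", "STD", "VAR"), ] == 0))
  expect_true(all(cst["RMS", ] == 2.5))
  # random window: per-definition brute force, sub-window by sub-window
  set.seed(7)
  xw <- rnorm(2000, sd = 15)
  f <- extract_handcrafted(xw, wamp_thr = 10)
  for (w in c(1, 7, 16)) {
    x <- xw[((w - 1) * 125 + 1):(w * 125)]
    d <- diff(x)
    expect_equal(unname(f["MAV", w]), mean(abs(x)))
    expect_equal(unname(f["SSI", w]), sum(x^2))
    expect_equal(unname(f["AAC", w]), mean(abs(d)))
    expect_equal(unname(f["WL", w]), sum(abs(d)))
    expect_equal(unname(f["ZC", w]), sum(head(x, -1) * x[-1] < 0))
    expect_equal(unname(f["WAMP", w]), sum(abs(d) > 10))
    expect_equal(unname(f["VAR", w]), mean(x^2) - mean(x)^2)
  }
  # compiled implementation agrees exactly with the R implementation
  fc <- whiskdecode:::wn_window_features(xw, 10)
  expect_equal(unname(f), fc, tolerance = 1e-14)
})

test_that("attention scores are a proper convex weighting", {
  dec <- init_decoder_params(11)
  # identical feature vectors in every slot: uniform scores, O = Value(F)
  Fv <- rnorm(60)
  buf <- matrix(Fv, 60, 16)
  at <- attention_step(buf, dec)
  expect_equal(sum(at$scores), 1, tolerance = 1e-12)
  expect_true(all(abs(at$scores - 1 / 16) < 1e-12))
  v <- pmax(dec$vw %*% Fv + dec$vb, 0)
  expect_equal(at$context, as.numeric(v), tolerance = 1e-12)
  # random buffers still normalize
  set.seed(8)
  for (i in 1:10) {
    at2 <- attention_step(matrix(rnorm(60 * 16), 60, 16), dec)
    expect_equal(sum(at2$scores), 1, tolerance = 1e-12)
    expect_true(all(at2$scores >= 0))
  }
  # one dominating salience draws all the weight
  dec2 <- dec
  big <- matrix(rnorm(60 * 16, sd = 0.01), 60, 16)
  big[, 5] <- 40  # huge salience k'q/4 at slot 5
  at3 <- attention_step(big, dec2)
  expect_gt(at3$scores[5], 0.99)
})

test_that("decode_step is bounded and hits the zero-weight fixed point", {
  dec <- init_decoder_params(12)
  buf <- matrix(0, 60, 16)
  st <- decode_step(rnorm(30), rnorm(30), buf, dec)
  expect_true(st$y > 0 && st$y < 1)
  zero <- lapply(dec, function(p) p * 0)
  st0 <- decode_step(rnorm(30), rnorm(30), buf, zero)
  expect_equal(st0$y, 0.5)  # sigmoid(0)
  # buffer aging: current F becomes slot 2 at the next step
  st1 <- decode_step(rnorm(30), rnorm(30), st$buffer, dec)
  expect_equal(st1$buffer[, 2], st$buffer[, 1])
})

test_that("compiled decoder equals the pure-R reference forward", {
  set.seed(9)
  dec <- init_decoder_params(13)
  lat <- matrix(rnorm(60 * 40), 60, 40)
  y_cpp <- as.numeric(whiskdecode:::wn_decoder_forward(lat, dec))
  y_ref <- ref_decoder_forward(lat, dec)
  expect_equal(y_cpp, y_ref, tolerance = 1e-12)
  expect_true(all(y_cpp > 0 & y_cpp < 1))
})

test_that("compiled encoder equals the pure-R reference forward", {
  set.seed(10)
  enc <- init_encoder_params(14)
  xw <- rnorm(2000, sd = 8)
  norm <- list(raw_mean = 0.2, raw_std = 7.5, wamp_thr = 10,
               feature_means = rnorm(10), feature_stds = runif(10, 0.5, 2))
  lat_cpp <- whiskdecode:::wn_encoder_forward(xw, 1L, 2000L, norm, enc)
  lat_ref <- ref_encoder_window(xw, enc, norm)
  expect_equal(as.numeric(lat_cpp), lat_ref, tolerance = 1e-10)
})

test_that("full forward is deterministic, bounded and unit-aware", {
  fx <- fx_subject()
  spec <- stream_spec()
  norm <- compute_norm_params(fx$neural, spec)
  enc <- init_encoder_params(1)
  dec <- init_decoder_params(2)
  short <- crop_recording(fx$neural, 0, 5)
  p1 <- whiskernet_forward(short, enc, dec, norm, spec)
  p2 <- whiskernet_forward(short, enc, dec, norm, spec)
  expect_identical(p1$samples, p2$samples)
  expect_equal(p1$fs_hz, 125)
  expect_equal(length(p1$samples), (5 * 16000 - 2000) %/% 128 + 1)
  expect_true(all(p1$samples > 0 & p1$samples < 1))
  expect_length(attr(p1, "warmup"), 15)
  # normalized 0.5 corresponds to 14 mm of the 0-28 mm physical range
  pmm <- whiskernet_forward(short, enc, dec, norm, spec, mm = TRUE)
  expect_equal(pmm$samples, 28 * p1$samples)
  expect_equal(pmm$unit, "mm")
})
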