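test_that("concordance loss matches its closed forms and the metric", {
  y <- c(0, 1, 2, 3, 4)
  expect_equal(ccc_loss(y, y), 0, tolerance = 1e-12)
  expect_equal(ccc_loss(y, y + 1), 0.2, tolerance = 1e-9)
  set.seed(13)
  for (i in 1:20) {
    a <- rnorm(60); b <- rnorm(60)
    l <- ccc_loss(a, b)
    expect_gte(l, 0); expect_lte(l, 2)
    expect_equal(1 - l, concordance_cc(a, b)$rho_c, tolerance = 1e-9)
  }
})

test_that("normalization statistics are recovered and guarded", {
  set.seed(14)
  spec <- stream_spec()
  r <- recording(rnorm(16000 * 20, mean = 5, sd = 2), 16000,
                 unit = "uV", kind = "neural")
  np <- compute_norm_params(r, spec)
  expect_equal(np$raw_mean, 5, tolerance = 0.05)
  expect_equal(np$raw_std, 2, tolerance = 0.05)
  expect_length(np$feature_means, 10)
  expect_true(all(np$feature_stds > 0))
  # renormalizing already-normalized data gives ~0 mean, ~1 sd
  z <- recording((r$samples - np$raw_mean) / np$raw_std, 16000,
                 unit = "uV", kind = "neural")
  np2 <- compute_norm_params(z, spec)
  expect_lt(abs(np2$raw_mean), 1e-9 + 0.02)
  expect_lt(abs(np2$raw_std - 1), 0.02)
  flat <- recording(rep(3, 16000 * 2), 16000, unit = "uV", kind = "neural")
  expect_error(compute_norm_params(flat, spec), "zero-variance")
})

test_that("shared fit produces one decoder per subject, deterministically", {
  m <- micro()
  model <- m$model
  expect_s3_class(model, "shared_model")
  expect_named(model$decoders, c("S01", "S02"))
  expect_named(model$norms, c("S01", "S02"))
  model2 <- fit_shared(m$cohort, m$cfg)
  expect_identical(params_hash(model$encoder), params_hash(model2$encoder))
  expect_identical(params_hash(model$decoders), params_hash(model2$decoders))
  expect_equal(model$history, model2$history)
  single <- NULL
  expect_warning(
    single <- fit_shared(m$cohort[1], train_config(epochs = 1,
                                                   seqs_per_epoch = 1,
                                                   seed = 3)),
    "degenerate")
  expect_length(single$decoders, 1)
})

test_that("adaptation freezes the encoder and reinitializes the decoder", {
  m <- micro()
  newsub <- make_cohort(1, 12, base_seed = 77, heterogeneity = 0)[[1]]
  h_before <- params_hash(m$model$encoder)
  ad <- adapt(m$model, newsub, m$cfg, seconds = 8)
  expect_identical(params_hash(m$model$encoder), h_before)
  expect_s3_class(ad, "adapted_decoder")
  # adapted decoder is independent of every training decoder
  for (d in m$model$decoders)
    expect_false(identical(params_hash(ad$decoder), params_hash(d)))
  # different reinitialization seed, different parameters
  ad2 <- adapt(m$model, newsub, m$cfg, seconds = 8, init_seed = 999)
  expect_false(identical(params_hash(ad$decoder), params_hash(ad2$decoder)))
  expect_error(adapt(m$model, newsub, m$cfg, seconds = 0.5),
               "shorter than one training sequence")
})

test_that("prediction mutates nothing and enforces split hygiene", {
  m <- micro()
  newsub <- make_cohort(1, 12, base_seed = 78, heterogeneity = 0)[[1]]
  ad <- adapt(m$model, newsub, m$cfg, seconds = 8)
  h_enc <- params_hash(m$model$encoder)
  h_dec <- params_hash(ad$decoder)
  xt <- crop_recording(newsub$neural, 8, 12)
  pred <- predict_test(m$model$encoder, ad$decoder, xt, ad$norm, m$cfg$spec)
  expect_identical(params_hash(m$model$encoder), h_enc)
  expect_identical(params_hash(ad$decoder), h_dec)
  expect_equal(length(pred$samples), (4 * 16000 - 2000) %/% 128 + 1)
  expect_equal(pred$fs_hz, 125)
  # normalization computed on a span overlapping the test split is refused
  overlap <- crop_recording(newsub$neural, 6, 12)
  expect_error(predict_test(m$model$encoder, ad$decoder, overlap, ad$norm,
                            m$cfg$spec),
               "hygiene")
})

test_that("training improves concordance on an easy cohort", {
  res <- fixture("easy_fit", {
    cohort <- make_cohort(2, 30, base_seed = 3, heterogeneity = 0.2)
    cfg <- train_config(epochs = 5, seqs_per_epoch = 8, seed = 1)
    fit_shared(cohort, cfg)
  })
  expect_gt(max(res$history$val_ccc), res$history$val_ccc[1])
  expect_gt(max(res$history$val_ccc), 0.3)
  expect_lt(min(res$history$train_loss), res$history$train_loss[1])
})
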