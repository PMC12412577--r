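#' Training configuration
#'
#' Settings for the concordance-loss sequence-to-sequence trainer and the
#' decoder adaptation phase. Loss sequences are contiguous runs of
#' `sequence_length_steps` outputs (default 125 steps = 1 s at 125 Hz).
#'
#' @param epochs training epochs for the shared (encoder + decoders) phase.
#' @param learning_rate Adam learning rate.
#' @param sequence_length_steps outputs per training sequence.
#' @param seqs_per_epoch sequences drawn per subject per epoch.
#' @param adapt_epochs,adapt_seqs_per_epoch the cheaper frozen-encoder
#'   decoder-adaptation phase (encoder latents are cached, so many more
#'   updates are affordable).
#' @param seed integer seed governing initialization and sequence sampling.
#' @param adaptation_data_s cap on adaptation data per new subject
#'   (<= 500 s).
#' @param normalization_source_s cap on per-subject normalization data for
#'   training subjects (default 1000 s).
#' @param clip_norm global gradient-norm clip.
#' @param patience early-stopping patience (epochs without validation
#'   improvement); validation uses a held-out tail of each subject's
#'   training split.
#' @param validation_fraction fraction of each subject's windows held out
#'   for validation.
#' @param wamp_thr Willison amplitude threshold (microvolts).
#' @param spec a [stream_spec].
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 10, learning_rate = 1e-3,
                         sequence_length_steps = 125,
                         seqs_per_epoch = 12,
                         adapt_epochs = 30, adapt_seqs_per_epoch = 16,
                         seed = 1L,
                         adaptation_data_s = 500,
                         normalization_source_s = 1000,
                         clip_norm = 5, patience = 3,
                         validation_fraction = 0.15,
                         wamp_thr = 10,
                         spec = stream_spec()) {
  if (adaptation_data_s > 500)
    stop("`adaptation_data_s` must not exceed 500 s", call. = FALSE)
  if (epochs < 1 || sequence_length_steps < 2)
    stop("invalid epochs or sequence length", call. = FALSE)
  structure(list(epochs = epochs, learning_rate = learning_rate,
                 sequence_length_steps = as.integer(sequence_length_steps),
                 seqs_per_epoch = as.integer(seqs_per_epoch),
                 adapt_epochs = as.integer(adapt_epochs),
                 adapt_seqs_per_epoch = as.integer(adapt_seqs_per_epoch),
                 seed = as.integer(seed),
                 adaptation_data_s = adaptation_data_s,
                 normalization_source_s = normalization_source_s,
                 clip_norm = clip_norm, patience = patience,
                 validation_fraction = validation_fraction,
                 wamp_thr = wamp_thr, spec = spec),
            class = "train_config")
}

#' Concordance loss
#'
#' `1 - rho_c` in minimization form, with an epsilon-guarded denominator so
#' the loss stays defined for (near-)constant model output early in
#' training.
#'
#' @param y ground truth sequence.
#' @param yhat predicted sequence.
#' @return scalar loss in `[0, 2]`.
#' @export
ccc_loss <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  wn_ccc_loss_grad(as.numeric(y), as.numeric(yhat))$loss
}

#' Stable hash of a parameter list
#'
#' Serialization-based fingerprint used to assert the freeze contract (the
#' shared encoder must be bit-identical before and after adaptation and
#' testing).
#'
#' @param params any serializable R object.
#' @return md5 hex string.
#' @export
params_hash <- function(params) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(params, f, version = 2)
  unname(tools::md5sum(f))
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

grad_global_norm <- function(...) {
  sqrt(sum(vapply(list(...), function(g)
    sum(vapply(g, function(x) sum(x^2), numeric(1))), numeric(1))))
}

scale_grads <- function(g, fac) lapply(g, function(x) x * fac)

adam_step <- function(params, grads, state, lr,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- subject training tables ----------------------------------------------

# windows, targets and train/validation split for one subject
subject_table <- function(ds, cfg) {
  spec <- cfg$spec
  sw <- stream_windows(ds$neural, spec)
  keep <- sw$traj_idx <= length(ds$trajectory$samples)
  starts <- sw$starts[keep]
  y <- ds$trajectory$samples[sw$traj_idx[keep]]
  K <- length(starts)
  S <- cfg$sequence_length_steps
  if (K < S)
    stop(sprintf("subject %s: fewer windows (%d) than one training sequence (%d)",
                 ds$subject_id, K, S), call. = FALSE)
  n_val <- max(0L, min(K - S, as.integer(floor(K * cfg$validation_fraction))))
  K_train <- K - n_val
  list(x = ds$neural$samples, starts = starts, y = y, K = K,
       train_max_start = K_train - S + 1L,
       val_start = if (n_val >= S) K_train + 1L else NA_integer_)
}

seq_slice <- function(tab, j, S) {
  idx <- j:(j + S - 1L)
  list(starts = as.integer(tab$starts[idx]), y = tab$y[idx])
}

# validation CCC on the held-out tail (forward only); NA when no tail
validation_ccc <- function(tab, enc, dec, norm, cfg) {
  if (is.na(tab$val_start)) return(NA_real_)
  idx <- tab$val_start:tab$K
  lat <- wn_encoder_forward(tab$x, as.integer(tab$starts[idx]),
                            cfg$spec$n_pad, unclass(norm), enc)
  yh <- as.numeric(wn_decoder_forward(lat, dec))
  tryCatch(concordance_cc(tab$y[idx], yh)$rho_c, error = function(e) NA_real_)
}

# ---- shared training -------------------------------------------------------

#' Fit the shared-encoder model on a training cohort
#'
#' Trains one shared encoder jointly across all subjects and one private
#' decoder per subject: encoder gradients accumulate from every subject's
#' sequences (round-robin within each epoch, so no subject-order bias),
#' decoder `i` only from subject `i`. The loss is the concordance loss over
#' contiguous output sequences. Per-subject normalization statistics are
#' computed from that subject's own data. Deterministic given `cfg$seed`.
#'
#' @param cohort list of [subject_dataset]s (>= 2 subjects for genuine
#'   sharing; a single subject trains but warns).
#' @param cfg a [train_config].
#' @param shared_decoder train a single decoder shared by every subject (the
#'   no-adaptation control variant) instead of per-subject decoders.
#' @param quiet suppress progress messages.
#' @return a `shared_model`: list with `encoder`, `decoders` (named by
#'   subject, or `"shared"`), `norms`, `cfg`, `history`.
#' @export
fit_shared <- function(cohort, cfg = train_config(), shared_decoder = FALSE,
                       quiet = TRUE) {
  stopifnot(length(cohort) >= 1)
  if (length(cohort) < 2)
    warning("single-subject cohort: parameter sharing is degenerate")
  ids <- vapply(cohort, function(d) d$subject_id, character(1))
  spec <- cfg$spec
  norms <- lapply(cohort, function(d)
    compute_norm_params(d$neural, spec, cfg$normalization_source_s,
                        cfg$wamp_thr))
  names(norms) <- ids
  tabs <- lapply(cohort, subject_table, cfg = cfg)
  names(tabs) <- ids
  enc <- init_encoder_params(cfg$seed, spec$n_pad)
  dec_ids <- if (shared_decoder) "shared" else ids
  decs <- lapply(seq_along(dec_ids), function(i)
    init_decoder_params(cfg$seed + i))
  names(decs) <- dec_ids
  enc_st <- adam_init(enc)
  dec_st <- lapply(decs, adam_init)
  S <- cfg$sequence_length_steps
  hist <- data.frame()
  best <- list(val = -Inf, enc = enc, decs = decs, epoch = 0L)
  wait <- 0L
  with_local_seed(cfg$seed * 17L + 5L, function() {
    for (ep in seq_len(cfg$epochs)) {
      ep_loss <- 0; n_seq <- 0L
      for (s in seq_len(cfg$seqs_per_epoch)) {
        for (i in seq_along(ids)) {
          tab <- tabs[[i]]
          di <- if (shared_decoder) "shared" else ids[i]
          j <- sample.int(tab$train_max_start, 1L)
          sl <- seq_slice(tab, j, S)
          r <- wn_seq_grad(tab$x, sl$starts, spec$n_pad,
                           unclass(norms[[i]]), enc, decs[[di]], sl$y, TRUE)
          gn <- grad_global_norm(r$genc, r$gdec)
          fac <- if (gn > cfg$clip_norm) cfg$clip_norm / gn else 1
          up <- adam_step(enc, scale_grads(r$genc, fac), enc_st,
                          cfg$learning_rate)
          enc <<- up$params; enc_st <<- up$state
          up <- adam_step(decs[[di]], scale_grads(r$gdec, fac),
                          dec_st[[di]], cfg$learning_rate)
          decs[[di]] <<- up$params; dec_st[[di]] <<- up$state
          ep_loss <- ep_loss + r$loss; n_seq <- n_seq + 1L
        }
      }
      vals <- vapply(seq_along(ids), function(i)
        validation_ccc(tabs[[i]], enc,
                       decs[[if (shared_decoder) "shared" else ids[i]]],
                       norms[[i]], cfg), numeric(1))
      vmean <- mean(vals, na.rm = TRUE)
      hist <<- rbind(hist, data.frame(epoch = ep,
                                      train_loss = ep_loss / n_seq,
                                      val_ccc = vmean))
      if (!quiet)
        message(sprintf("epoch %d: loss %.4f, val CCC %.4f", ep,
                        ep_loss / n_seq, vmean))
      if (is.finite(vmean) && vmean > best$val) {
        best <<- list(val = vmean, enc = enc, decs = decs, epoch = ep)
        wait <<- 0L
      } else {
        wait <<- wait + 1L
        if (wait >= cfg$patience && ep >= 3L) break
      }
    }
  })
  if (is.finite(best$val)) { enc <- best$enc; decs <- best$decs }
  structure(list(encoder = enc, decoders = decs, norms = norms,
                 cfg = cfg, history = hist, subject_ids = ids,
                 shared_decoder = shared_decoder),
            class = "shared_model")
}

#' @export
print.shared_model <- function(x, ...) {
  cat(sprintf("<shared_model: %d subject(s), %s decoder(s), %d epoch(s) trained>\n",
              length(x$subject_ids), length(x$decoders), nrow(x$history)))
  invisible(x)
}

# ---- adaptation ------------------------------------------------------------

#' Adapt a reinitialized decoder to a new subject
#'
#' Frozen-encoder adaptation: encoder latents for the adaptation split are
#' computed once with the shared encoder (whose parameters are not touched),
#' then a freshly initialized decoder is trained on those cached latents
#' with the concordance loss. Normalization statistics come from the
#' adaptation split only.
#'
#' @param model a `shared_model` from [fit_shared()].
#' @param new_subject a [subject_dataset] not in the training cohort.
#' @param cfg a [train_config]; `cfg$adaptation_data_s` caps the data used.
#' @param seconds adaptation data length (defaults to the config cap).
#' @param offset_s where the adaptation split starts within the subject's
#'   recording.
#' @param init_seed seed for the fresh decoder initialization.
#' @return an `adapted_decoder`: list with `decoder`, `norm`, `history`,
#'   `adapt_span_s`.
#' @export
adapt <- function(model, new_subject, cfg = model$cfg,
                  seconds = cfg$adaptation_data_s, offset_s = 0,
                  init_seed = cfg$seed * 31L + 17L) {
  stopifnot(inherits(model, "shared_model"),
            inherits(new_subject, "subject_dataset"))
  seconds <- min(seconds, cfg$adaptation_data_s,
                 duration_s(new_subject$neural) - offset_s)
  spec <- cfg$spec
  S <- cfg$sequence_length_steps
  min_s <- (spec$n_pad + (S - 1) * spec$stride) / spec$fs_data
  if (seconds < min_s)
    stop(sprintf("adaptation data (%.1f s) shorter than one training sequence (%.1f s)",
                 seconds, min_s), call. = FALSE)
  arec <- crop_recording(new_subject$neural, offset_s, offset_s + seconds)
  norm <- compute_norm_params(arec, spec, min(seconds, 500), cfg$wamp_thr)
  el <- encoder_latents(arec, model$encoder, norm, spec)
  traj0 <- as.integer(round(offset_s * spec$fs_laser))
  tidx <- traj0 + el$traj_idx
  keep <- tidx <= length(new_subject$trajectory$samples)
  lat <- el$lat[, keep, drop = FALSE]
  y <- new_subject$trajectory$samples[tidx[keep]]
  K <- ncol(lat)
  if (K < S) stop("adaptation data shorter than one training sequence",
                  call. = FALSE)
  dec <- init_decoder_params(init_seed)
  st <- adam_init(dec)
  hist <- numeric(0)
  with_local_seed(init_seed * 3L + 1L, function() {
    for (ep in seq_len(cfg$adapt_epochs)) {
      ep_loss <- 0
      for (s in seq_len(cfg$adapt_seqs_per_epoch)) {
        j <- sample.int(K - S + 1L, 1L)
        idx <- j:(j + S - 1L)
        r <- wn_decoder_seq_grad(lat[, idx, drop = FALSE], dec, y[idx])
        gn <- grad_global_norm(r$gdec)
        fac <- if (gn > cfg$clip_norm) cfg$clip_norm / gn else 1
        up <- adam_step(dec, scale_grads(r$gdec, fac), st, cfg$learning_rate)
        dec <<- up$params; st <<- up$state
        ep_loss <- ep_loss + r$loss
      }
      hist <<- c(hist, ep_loss / cfg$adapt_seqs_per_epoch)
    }
  })
  structure(list(decoder = dec, norm = norm, history = hist,
                 adapt_span_s = c(offset_s, offset_s + seconds),
                 subject_id = new_subject$subject_id),
            class = "adapted_decoder")
}

#' Pure forward prediction on a test split
#'
#' Applies the frozen shared encoder and a (subject-specific) decoder to a
#' test recording. No parameters are mutated. The normalization parameters
#' must not have been computed from the test span (split provenance is
#' checked when both spans are known).
#'
#' @param encoder encoder parameter list.
#' @param decoder decoder parameter list (e.g. from [adapt()]).
#' @param x_test neural [recording] of the test split (use
#'   [crop_recording()] so its span is known).
#' @param norm [compute_norm_params()] object from the training/adaptation
#'   split.
#' @param spec a [stream_spec].
#' @param mm return millimetres.
#' @return predicted trajectory [recording]; see [whiskernet_forward()].
#' @export
predict_test <- function(encoder, decoder, x_test, norm,
                         spec = stream_spec(), mm = FALSE) {
  span <- attr(x_test, "span_s")
  src <- norm$source_span_s
  if (!is.null(span) && !is.null(src) &&
      max(span[1], src[1]) < min(span[2], src[2]) - 1e-9)
    stop("data hygiene: normalization statistics overlap the test split",
         call. = FALSE)
  whiskernet_forward(x_test, encoder, decoder, norm, spec, mm = mm)
}

# CCC of a prediction against the subject's true trajectory
prediction_ccc <- function(pred, trajectory, offset_s = 0, drop_warmup = TRUE) {
  tidx <- as.integer(round(offset_s * pred$fs_hz)) + attr(pred, "traj_idx")
  keep <- tidx <= length(trajectory$samples)
  yh <- pred$samples[keep]
  y <- trajectory$samples[tidx[keep]]
  if (drop_warmup && length(yh) > 20) {
    yh <- yh[-seq_len(15L)]
    y <- y[-seq_len(15L)]
  }
  concordance_cc(y, yh)$rho_c
}
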