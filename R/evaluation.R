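#' Control model 1: fully shared, no adaptation
#'
#' Both encoder and decoder are shared across all training subjects and the
#' model is applied to new subjects without any adaptation phase (the
#' subject still gets their own normalization statistics, which are
#' preprocessing rather than model parameters).
#'
#' @param cohort training cohort (list of [subject_dataset]s).
#' @param cfg a [train_config].
#' @return a `shared_model` whose `decoders` holds the single `"shared"`
#'   decoder.
#' @export
build_control1 <- function(cohort, cfg = train_config()) {
  fit_shared(cohort, cfg, shared_decoder = TRUE)
}

#' Control model 2: fully individualized, no prior parameters
#'
#' Encoder and decoder are trained from scratch on the test subject's
#' adaptation data only, sharing nothing with any training cohort.
#'
#' @param new_subject a [subject_dataset].
#' @param cfg a [train_config].
#' @param seconds adaptation data length in seconds.
#' @param offset_s start of the adaptation split.
#' @return a `shared_model` with one decoder, trained on the one subject.
#' @export
build_control2 <- function(new_subject, cfg = train_config(),
                           seconds = cfg$adaptation_data_s, offset_s = 0) {
  seconds <- min(seconds, duration_s(new_subject$neural) - offset_s)
  sub <- subject_dataset(
    new_subject$subject_id,
    crop_recording(new_subject$neural, offset_s, offset_s + seconds),
    crop_recording(new_subject$trajectory, offset_s, offset_s + seconds),
    ground_truth_latency_ms = new_subject$ground_truth_latency_ms)
  suppressWarnings(fit_shared(list(sub), cfg))
}

# CCC of a model variant on a test span of a new subject
evaluate_on_span <- function(encoder, decoder, norm, new_subject,
                             test_from_s, test_to_s, spec) {
  xt <- crop_recording(new_subject$neural, test_from_s, test_to_s)
  pred <- predict_test(encoder, decoder, xt, norm, spec)
  prediction_ccc(pred, new_subject$trajectory, offset_s = test_from_s)
}

#' Evaluate the adapted model on a held-out test span
#'
#' Convenience wrapper: adapt a fresh decoder on `[0, adapt_s)` of the new
#' subject and score the concordance of the prediction on the disjoint
#' `[adapt_s, test_to_s)` span.
#'
#' @param model a `shared_model`.
#' @param new_subject a [subject_dataset] outside the training cohort.
#' @param cfg a [train_config].
#' @param adapt_s adaptation length, seconds.
#' @param test_to_s end of the test span (default: end of recording).
#' @param init_seed decoder reinitialization seed.
#' @return list with `ccc`, `adapted` (the [adapt()] result) and the spans.
#' @export
evaluate_adapted <- function(model, new_subject, cfg = model$cfg,
                             adapt_s = 60,
                             test_to_s = duration_s(new_subject$neural),
                             init_seed = cfg$seed * 31L + 17L) {
  ad <- adapt(model, new_subject, cfg, seconds = adapt_s, offset_s = 0,
              init_seed = init_seed)
  ccc <- evaluate_on_span(model$encoder, ad$decoder, ad$norm, new_subject,
                          adapt_s, test_to_s, cfg$spec)
  list(ccc = ccc, adapted = ad,
       adapt_span_s = c(0, adapt_s), test_span_s = c(adapt_s, test_to_s))
}

#' Leave-one-subject-out cross-validation
#'
#' The cross-subject evaluation protocol: in each fold one subject is held
#' out, the shared model is trained on the remaining subjects, a decoder is
#' adapted on the held-out subject's adaptation split, and the concordance
#' is measured on their disjoint test split. Each train-test run is repeated
#' under `n_seeds` random seeds (1..n_seeds).
#'
#' @param cohort list of [subject_dataset]s.
#' @param cfg a [train_config].
#' @param n_seeds seeds 1..n_seeds per fold (default 10).
#' @param adapt_s adaptation length per held-out subject, seconds.
#' @param variant `"whiskernet"` (adapted) or `"control1"` (fully shared,
#'   no adaptation).
#' @return an `evaluation_report`: list with `per_fold` (data.frame
#'   subject/seed/ccc), `summary` (mean, sd, median, IQR) and `variant`.
#' @export
loso_crossval <- function(cohort, cfg = train_config(), n_seeds = 10,
                          adapt_s = 60, variant = c("whiskernet", "control1")) {
  variant <- match.arg(variant)
  ids <- vapply(cohort, function(d) d$subject_id, character(1))
  rows <- list()
  for (f in seq_along(cohort)) {
    test_ds <- cohort[[f]]
    train_cohort <- cohort[-f]
    for (sd_i in seq_len(n_seeds)) {
      cfg_s <- cfg
      cfg_s$seed <- as.integer(sd_i)
      if (variant == "whiskernet") {
        m <- fit_shared(train_cohort, cfg_s)
        ev <- evaluate_adapted(m, test_ds, cfg_s, adapt_s = adapt_s)
        ccc <- ev$ccc
      } else {
        m <- build_control1(train_cohort, cfg_s)
        norm <- compute_norm_params(
          crop_recording(test_ds$neural, 0, adapt_s), cfg$spec,
          min(adapt_s, 500), cfg$wamp_thr)
        ccc <- evaluate_on_span(m$encoder, m$decoders$shared, norm, test_ds,
                                adapt_s, duration_s(test_ds$neural),
                                cfg$spec)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(subject = ids[f], seed = sd_i, ccc = ccc)
    }
  }
  per_fold <- do.call(rbind, rows)
  structure(list(
    per_fold = per_fold,
    summary = c(mean = mean(per_fold$ccc), sd = sd(per_fold$ccc),
                median = median(per_fold$ccc),
                iqr = unname(diff(quantile(per_fold$ccc, c(0.25, 0.75))))),
    variant = variant, n_seeds = n_seeds),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report %s: %d runs, CCC %.3f +/- %.3f>\n",
              x$variant, nrow(x$per_fold), x$summary["mean"], x$summary["sd"]))
  invisible(x)
}

# smallest grid length reaching 90% of the curve's maximum
data_to_90pct <- function(ccc, lengths_s) {
  stopifnot(length(ccc) == length(lengths_s))
  if (all(!is.finite(ccc))) return(NA_real_)
  # epsilon guards the boundary case ccc == 0.9 * max against rounding
  lengths_s[min(which(ccc >= 0.9 * max(ccc, na.rm = TRUE) - 1e-9))]
}

#' Adaptation-data learning curve
#'
#' Convergence-speed protocol: for each of `n_folds` contiguous test blocks
#' of the subject's recording and each adaptation-data length, adapt (or,
#' for the from-scratch control, fully train) on that much data drawn from
#' the remaining recording and score concordance on the test block. The
#' data-efficiency benchmark is the smallest length reaching 90% of the
#' curve's maximum.
#'
#' @param model a `shared_model` (ignored for `variant = "control2"`).
#' @param new_subject a [subject_dataset].
#' @param lengths_s increasing grid of adaptation lengths (seconds);
#'   `NULL` scales a default grid to the recording length.
#' @param cfg a [train_config].
#' @param n_folds number of cross-validation folds (default 5).
#' @param variant `"whiskernet"` (frozen shared encoder + adapted decoder)
#'   or `"control2"` (encoder and decoder trained from scratch per fold).
#' @return a `learning_curve`: list with `lengths_s`, `ccc` (folds x
#'   lengths matrix), `mean_ccc`, `d90_per_fold_s`, `data_to_90pct_s`
#'   (from the mean curve) and `variant`.
#' @export
learning_curve <- function(model, new_subject, lengths_s = NULL,
                           cfg = train_config(), n_folds = 5,
                           variant = c("whiskernet", "control2")) {
  variant <- match.arg(variant)
  dur <- duration_s(new_subject$neural)
  if (is.null(lengths_s)) {
    pool_min <- dur * (1 - 1 / n_folds) / 2  # worst-case contiguous pool
    lengths_s <- round(pool_min * c(0.25, 0.5, 1))
  }
  stopifnot(all(diff(lengths_s) > 0))
  ccc <- matrix(NA_real_, n_folds, length(lengths_s))
  for (f in seq_len(n_folds)) {
    t0 <- (f - 1) * dur / n_folds
    t1 <- f * dur / n_folds
    # largest contiguous non-test piece
    before <- t0; after <- dur - t1
    pool <- if (before >= after) c(0, t0) else c(t1, dur)
    for (li in seq_along(lengths_s)) {
      len <- min(lengths_s[li], pool[2] - pool[1])
      res <- tryCatch({
        if (variant == "whiskernet") {
          ad <- adapt(model, new_subject, cfg, seconds = len,
                      offset_s = pool[1])
          evaluate_on_span(model$encoder, ad$decoder, ad$norm,
                           new_subject, t0, t1, cfg$spec)
        } else {
          m2 <- build_control2(new_subject, cfg, seconds = len,
                               offset_s = pool[1])
          norm <- m2$norms[[1]]
          evaluate_on_span(m2$encoder, m2$decoders[[1]], norm,
                           new_subject, t0, t1, cfg$spec)
        }
      }, error = function(e) NA_real_)
      ccc[f, li] <- res
    }
  }
  mean_ccc <- colMeans(ccc, na.rm = TRUE)
  structure(list(
    lengths_s = lengths_s, ccc = ccc, mean_ccc = mean_ccc,
    d90_per_fold_s = apply(ccc, 1, data_to_90pct, lengths_s = lengths_s),
    data_to_90pct_s = data_to_90pct(mean_ccc, lengths_s),
    variant = variant),
    class = "learning_curve")
}

#' @export
print.learning_curve <- function(x, ...) {
  cat(sprintf("<learning_curve %s: lengths %s s, mean CCC %s, d90 = %s s>\n",
              x$variant, paste(x$lengths_s, collapse = "/"),
              paste(sprintf("%.2f", x$mean_ccc), collapse = "/"),
              format(x$data_to_90pct_s)))
  invisible(x)
}

#' Signed difference in data-to-90%-benchmark
#'
#' @param curve_a,curve_b [learning_curve] objects over the same grid.
#' @return list with `diff_s` (`a - b`, negative when `a` needs less data)
#'   and `per_fold_s` (per-fold signed differences).
#' @export
compare_data_efficiency <- function(curve_a, curve_b) {
  stopifnot(inherits(curve_a, "learning_curve"),
            inherits(curve_b, "learning_curve"),
            identical(curve_a$lengths_s, curve_b$lengths_s))
  list(diff_s = curve_a$data_to_90pct_s - curve_b$data_to_90pct_s,
       per_fold_s = curve_a$d90_per_fold_s - curve_b$d90_per_fold_s)
}
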