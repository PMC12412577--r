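#' Write a cohort to a directory container
#'
#' One subdirectory per subject holding per-channel CSV files
#' (`time_s,value` header) and an `attrs.json` with the channel sampling
#' rates, units and the generator-injected latency. Everything is plain
#' text, so a cohort round-trips bit-identically through `fwrite`/`fread`
#' at full double precision.
#'
#' @param cohort list of [subject_dataset]s.
#' @param path container directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (ds in cohort) {
    sdir <- file.path(path, ds$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    chans <- list(neural = ds$neural, trajectory = ds$trajectory)
    if (!is.null(ds$emg)) chans$emg <- ds$emg
    attrs <- list(subject_id = ds$subject_id,
                  latency_ms = ds$ground_truth_latency_ms,
                  channels = list())
    for (nm in names(chans)) {
      r <- chans[[nm]]
      data.table::fwrite(
        # %.17g guarantees the doubles round-trip bit-exactly through text
        data.table::data.table(time_s = (seq_along(r$samples) - 1) / r$fs_hz,
                               value = sprintf("%.17g", r$samples)),
        file.path(sdir, paste0(nm, ".csv")))
      attrs$channels[[nm]] <- list(fs_hz = r$fs_hz, unit = r$unit,
                                   kind = r$kind)
    }
    jsonlite::write_json(attrs, file.path(sdir, "attrs.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

read_subject_dir <- function(sdir) {
  af <- file.path(sdir, "attrs.json")
  if (!file.exists(af))
    stop("missing attrs.json in ", sdir, call. = FALSE)
  attrs <- jsonlite::read_json(af, simplifyVector = TRUE)
  read_chan <- function(nm) {
    f <- file.path(sdir, paste0(nm, ".csv"))
    if (!file.exists(f)) return(NULL)
    ch <- attrs$channels[[nm]]
    if (is.null(ch$fs_hz))
      stop("missing fs_hz attribute for channel ", nm, call. = FALSE)
    d <- data.table::fread(f)
    if (anyNA(d$value))
      stop("NaN/missing samples in channel ", nm, call. = FALSE)
    recording(d$value, ch$fs_hz, unit = ch$unit, kind = ch$kind)
  }
  neural <- read_chan("neural")
  traj <- read_chan("trajectory")
  if (is.null(neural) || is.null(traj))
    stop("subject directory must contain neural and trajectory channels",
         call. = FALSE)
  subject_dataset(attrs$subject_id, neural, traj, emg = read_chan("emg"),
                  ground_truth_latency_ms =
                    if (is.null(attrs$latency_ms)) NA_real_ else attrs$latency_ms)
}

#' Load a cohort (or single subject) from a directory container
#'
#' @param path a container directory written by [write_cohort()], or a
#'   single subject subdirectory.
#' @return a list of [subject_dataset]s (container) or one
#'   [subject_dataset] (subject directory).
#' @export
load_cohort <- function(path) {
  if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
  if (file.exists(file.path(path, "attrs.json")))
    return(read_subject_dir(path))
  subs <- list.dirs(path, recursive = FALSE)
  subs <- subs[file.exists(file.path(subs, "attrs.json"))]
  if (!length(subs))
    stop("no subject directories found under ", path, call. = FALSE)
  lapply(sort(subs), read_subject_dir)
}

#' Save a trained model
#'
#' Writes the parameter lists to an RDS payload next to a JSON manifest
#' (layer names and shapes, subjects, training history, package version).
#'
#' @param model a `shared_model`.
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "shared_model"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(path, "model.rds"), version = 2)
  shapes <- function(p) lapply(p, function(x)
    if (is.matrix(x)) dim(x) else length(x))
  jsonlite::write_json(list(
    package = "whiskdecode",
    version = as.character(utils::packageVersion("whiskdecode")),
    subjects = model$subject_ids,
    shared_decoder = model$shared_decoder,
    encoder_shapes = shapes(model$encoder),
    decoder_names = names(model$decoders),
    encoder_hash = params_hash(model$encoder),
    epochs_trained = nrow(model$history)),
    file.path(path, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a model saved by [save_model()]
#' @param path model directory.
#' @return the `shared_model`.
#' @export
load_model <- function(path) {
  m <- readRDS(file.path(path, "model.rds"))
  stopifnot(inherits(m, "shared_model"))
  m
}

#' Run the full pipeline on a configuration
#'
#' Chains simulate, signal-quality metrics, shared training, adaptation and
#' evaluation, writing artifacts and a run manifest under `out_dir`. Stages
#' whose outputs already exist are skipped unless `overwrite = TRUE`.
#'
#' @param config list with elements `n_subjects`, `duration_s`, `seed`,
#'   `heterogeneity`, `adapt_s` and optionally any [train_config()] field
#'   under `train`.
#' @param out_dir output directory.
#' @param overwrite regenerate existing stage outputs.
#' @param quiet suppress progress messages.
#' @return list with the evaluation results and artifact paths.
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE, quiet = TRUE) {
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  tr <- config$train %||% list()
  cfg <- do.call(train_config, c(list(seed = seed), tr))
  cohort_dir <- file.path(out_dir, "cohort")
  if (overwrite || !dir.exists(cohort_dir)) {
    cohort <- make_cohort(config$n_subjects %||% 4L,
                          config$duration_s %||% 60,
                          base_seed = seed,
                          heterogeneity = config$heterogeneity %||% 0.3)
    write_cohort(cohort, cohort_dir)
  } else {
    cohort <- load_cohort(cohort_dir)
  }
  n <- length(cohort)
  test_ds <- cohort[[n]]
  train_cohort <- cohort[-n]
  metrics_file <- file.path(out_dir, "quality_metrics.csv")
  if (overwrite || !file.exists(metrics_file)) {
    met <- do.call(rbind, lapply(cohort, function(ds) {
      env_n <- envelope(bandpass_neural(ds$neural))
      env_t <- envelope(ds$trajectory)
      rbind(tidy_sliding_series(sliding_rms(ds$neural), ds$subject_id),
            tidy_sliding_series(
              envelope_correlation(env_n, env_t, window_spec(1, 0.5)),
              ds$subject_id))
    }))
    data.table::fwrite(met, metrics_file)
  }
  model_dir <- file.path(out_dir, "model")
  if (overwrite || !dir.exists(model_dir)) {
    model <- fit_shared(train_cohort, cfg, quiet = quiet)
    save_model(model, model_dir)
  } else {
    model <- load_model(model_dir)
  }
  adapt_s <- config$adapt_s %||% min(60, duration_s(test_ds$neural) / 2)
  ev <- evaluate_adapted(model, test_ds, cfg, adapt_s = adapt_s)
  report <- list(test_subject = test_ds$subject_id,
                 adapt_s = adapt_s, ccc = ev$ccc)
  jsonlite::write_json(report, file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(command = "run_pipeline", config = config, seed = seed,
                   out_dir = out_dir,
                   package_version =
                     as.character(utils::packageVersion("whiskdecode")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(report = report, cohort_dir = cohort_dir,
                 model_dir = model_dir, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
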