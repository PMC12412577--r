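# Memoized fixtures shared across test files (built once per test run).
.wd_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .wd_cache)) {
    assign(name, force(expr), envir = .wd_cache)
  }
  get(name, envir = .wd_cache)
}

# small paired trajectory/neural recording used by many tests
fx_subject <- function() fixture("subject30", {
  p <- subject_profile(rng_seed = 5)
  tr <- synthesize_trajectory(p, 30)
  list(profile = p, traj = tr, neural = synthesize_neural(p, tr))
})

# the scaled-down cross-subject study: 4 training + 1 test subject, 120 s
# each, heterogeneity 0.3, fixed seeds, reduced epochs
fx_study <- function() fixture("study", {
  cohort <- make_cohort(5, 120, base_seed = 1, heterogeneity = 0.3)
  list(train = cohort[1:4], test = cohort[[5]],
       cfg = train_config(epochs = 10, seqs_per_epoch = 10, seed = 1))
})

fx_model <- function() fixture("model", {
  st <- fx_study()
  fit_shared(st$train, st$cfg)
})

fx_adapted <- function() fixture("adapted", {
  st <- fx_study()
  evaluate_adapted(fx_model(), st$test, st$cfg, adapt_s = 60)
})

# a tiny 2-subject cohort + fitted model for fast structural checks
micro <- function() fixture("micro", {
  cohort <- make_cohort(2, 12, base_seed = 4, heterogeneity = 0.3)
  cfg <- train_config(epochs = 2, seqs_per_epoch = 2, adapt_epochs = 3,
                      adapt_seqs_per_epoch = 4, seed = 2)
  list(cohort = cohort, cfg = cfg, model = fit_shared(cohort, cfg))
})

fx_control1 <- function() fixture("control1", {
  st <- fx_study()
  build_control1(st$train, st$cfg)
})
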