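# Shared fixtures, built in code and memoised for the test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, builder(), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# tiny noiseless study: 3 patients, 5 days, shared start date
tiny_noiseless <- function() memo("tiny_noiseless", function() {
  cfg <- sim_config(n_patients = 3, days = 5, seed = 7, noise_sd = 0,
                    enrollment_span_days = 0)
  ds <- simulate_study(generate_cohort(cfg), cfg)
  list(cfg = cfg, ds = ds, features = build_feature_table(ds))
})

# small noisy study spanning ten weeks of calendar time (rolling enrollment)
small_noisy <- function() memo("small_noisy", function() {
  cfg <- sim_config(n_patients = 10, days = 20, seed = 21, noise_sd = 12,
                    enrollment_span_days = 70)
  ds <- clean_cgm(simulate_study(generate_cohort(cfg), cfg))
  ft <- build_feature_table(ds)
  list(cfg = cfg, ds = ds, features = ft, keep = ft[excluded == FALSE])
})

# model trained on the small noisy study (used by predict/recommend tests)
small_model <- function() memo("small_model", function() {
  sn <- small_noisy()
  folds <- make_folds(sn$keep$timestamp)
  train_ppgr(sn$keep, sn$keep$observed_delta, model_config(seed = 21), folds)
})

# function-recovery fit: noiseless study, target 2 * carbs * GI/100 (inside
# the model class); 600 meals over ten calendar weeks
recovery_fit <- function() memo("recovery_fit", function() {
  cfg <- sim_config(n_patients = 10, days = 20, seed = 31, noise_sd = 0,
                    enrollment_span_days = 70)
  ds <- simulate_study(generate_cohort(cfg), cfg)
  ft <- build_feature_table(ds)
  keep <- ft[excluded == FALSE]
  targets <- 2 * keep$glycemic_load
  folds <- make_folds(keep$timestamp)
  model <- train_ppgr(keep, targets, model_config(seed = 31), folds)
  list(features = keep, targets = targets, model = model, folds = folds)
})

# MCAR coverage simulation shared by the imputation and acceptance tests:
# y ~ Normal(50, 10) with a correlated observed covariate, n = 500, 20%
# missing completely at random, 50 seeded replicates
mice_coverage <- function() memo("mice_coverage", function() {
  vapply(1:50, function(rep) {
    set.seed(1000 + rep)
    x <- rnorm(500)
    y <- 50 + 4 * x + rnorm(500, 0, sqrt(100 - 16))
    d <- data.frame(x = x, y = y)
    d$y[sample(500, 100)] <- NA
    imp <- mice_impute(d, m = 5, seed = rep)
    est <- vapply(imp$datasets, function(dd) mean(dd$y), numeric(1))
    vr <- vapply(imp$datasets, function(dd) var(dd$y) / 500, numeric(1))
    ci <- rubin_pool(est, vr)$ci
    ci[1] <= 50 && 50 <= ci[2]
  }, logical(1))
})

# one synthetic patient as a plain list for kernel-level tests
flat_patient <- function(...) {
  p <- list(patient_id = "T01", basal_glucose = 100, circadian_amplitude = 0,
            carb_sensitivity = 0, fiber_damping = 0, protein_fat_damping = 0,
            activity_damping = 0, sleep_penalty = 0, med_effect = 0,
            med_count = 0, noise_sd = 0)
  mods <- list(...)
  p[names(mods)] <- mods
  p
}

make_trace <- function(glucose, start = "2023-03-01 07:00:00", by_min = 5,
                       patient_id = "T01") {
  data.table::data.table(
    patient_id = patient_id,
    timestamp = as.POSIXct(start, tz = "UTC") +
      (seq_along(glucose) - 1) * by_min * 60,
    glucose_mgdl = glucose)
}
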