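# End-to-end orchestration: simulate -> clean -> featurize -> train ->
# evaluate -> recommend, with every artifact stamped with the config hash.

#' Run configuration for the end-to-end pipeline
#'
#' @param seed Integer seed; required (fail-fast before any stage runs).
#' @param sim A [sim_config()]; its seed is overridden by `seed`.
#' @param model A [model_config()]; its seed is overridden by `seed`.
#' @param rec A [recommendation_config()].
#' @param spike A [spike_definition()].
#' @param log_level "info" or "quiet".
#' @export
run_config <- function(seed = NULL, sim = sim_config(), model = model_config(),
                       rec = recommendation_config(),
                       spike = spike_definition(), log_level = "info") {
  cfg <- list(seed = seed, sim = sim, model = model, rec = rec,
              spike = spike, log_level = log_level)
  class(cfg) <- "run_config"
  cfg
}

log_msg <- function(cfg, ...) {
  if (identical(cfg$log_level, "info")) {
    message(sprintf("[glycotwin %s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...)))
  }
}

#' Run the full pipeline
#'
#' Simulates the cohort, cleans the CGM streams, engineers features, trains
#' the PPGR model under temporal-gap CV, writes the validation report, and
#' emits ranked recommendations for the first patient. Every artifact embeds
#' the hash of the configuration that produced it. Stages up to feature
#' extraction are resumable from their on-disk artifacts with `resume =
#' TRUE`; model training always re-runs (the model artifact stores its
#' report, not a reloadable fit).
#'
#' @param config A [run_config()] with a non-NULL seed.
#' @param out_dir Artifact directory.
#' @param resume Reuse existing simulate/clean/featurize artifacts?
#' @return Invisibly, a list with the trained model, the validation report
#'   and the recommendation set.
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE) {
  if (!inherits(config, "run_config")) {
    stop_invalid_config("config must be a run_config")
  }
  if (is.null(config$seed)) {
    stop_invalid_config("run_config seed must be set before any stage runs")
  }
  config$sim$seed <- as.integer(config$seed)
  config$model$seed <- as.integer(config$seed)
  chash <- rlang::hash(config[c("seed", "sim", "model", "rec", "spike")])
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data_dir <- file.path(out_dir, "data")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      glyco_abort(sprintf("stage '%s' failed: %s", name,
                          conditionMessage(e)), "glycotwin_stage_error")
    })
  }

  ds <- stage("simulate", {
    if (resume && file.exists(file.path(data_dir, "cgm.csv"))) {
      log_msg(config, "simulate: reusing %s", data_dir)
      raw <- load_dataset(data_dir)
      raw$config <- config$sim
      raw
    } else {
      cohort <- generate_cohort(config$sim)
      d <- simulate_study(cohort, config$sim)
      d <- corrupt_dataset(d, config$sim)
      write_dataset(d, data_dir)
      log_msg(config, "simulate: %d patients, %d CGM samples",
              nrow(d$profiles), nrow(d$cgm))
      d
    }
  })

  ds <- stage("clean", {
    d <- clean_cgm(ds, report_path = file.path(out_dir, "cleaning_report.json"))
    rep <- attr(d, "cleaning_report")
    log_msg(config, "clean: %d outliers flagged, %d samples imputed",
            rep$n_flagged_outlier, rep$n_imputed)
    d
  })

  ft <- stage("featurize", {
    f <- build_feature_table(ds)
    fcsv <- data.table::copy(f)[, timestamp := format(
      timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")]
    data.table::fwrite(fcsv, file.path(out_dir, "features.csv"))
    write_registry(path = file.path(out_dir, "registry.yaml"))
    log_msg(config, "featurize: %d rows (%d excluded)", nrow(f),
            sum(f$excluded))
    f
  })

  keep <- ft[excluded == FALSE]
  model <- stage("train", {
    folds <- make_folds(keep$timestamp)
    m <- train_ppgr(keep, keep$observed_delta, config$model, folds)
    rep <- c(m$report[c("pooled", "chosen_combo", "residual_normality_p",
                        "residual_lag1_autocorrelation", "seed")],
             list(config_hash = chash, algorithm = m$algorithm))
    jsonlite::write_json(rep, file.path(out_dir, "training_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_msg(config, "train: outer-fold RMSE %.2f mg/dL", m$report$pooled$rmse)
    m
  })

  vr <- stage("evaluate", {
    validation_report(model, keep, config$spike,
                      out = file.path(out_dir, "validation_report.json"),
                      seed = config$seed)
  })

  rec <- stage("recommend", {
    pid <- ds$profiles$patient_id[1]
    trace <- ds$cgm[patient_id == pid]
    now <- keep[patient_id == pid][.N]
    ctx <- temporal_context(trace, ds$activity[patient_id == pid],
                            ds$sleep[patient_id == pid], now$timestamp)
    st <- patient_state(ds$profiles[patient_id == pid], ctx,
                        now$baseline_adjusted, now$timestamp)
    nrt <- nrt_from_impacts(model$report$outer_predictions$predicted)
    rs <- recommend_foods(default_food_table(), st, model, config$rec,
                          nrt = nrt)
    jsonlite::write_json(
      list(patient_id = pid, config_hash = chash,
           model_version = model$version, nrt_version = nrt$version,
           nrt = unclass(nrt)[c("t_green", "t_orange")],
           recommendations = rs),
      file.path(out_dir, "recommendations.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
    rs
  })

  manifest <- list(
    config_hash = chash, seed = config$seed,
    artifacts = list.files(out_dir, recursive = TRUE),
    metrics = vr$metrics
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(model = model, report = vr, recommendations = rec,
                 config_hash = chash))
}
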