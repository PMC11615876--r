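#' Simulation configuration
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults define the
#' desk benchmark used throughout the package: 60 patients wearing a 5-minute
#' CGM for 30 days, three logged meals per day, sensor noise 12 mg/dL, and
#' rolling enrollment over 70 calendar days so temporal-gap cross-validation
#' with a two-week gap is feasible.
#'
#' @param n_patients Number of virtual patients (>= 1).
#' @param days CGM wear days per patient.
#' @param cgm_interval CGM sampling interval, minutes.
#' @param meals_per_day Logged meals per day (3 = breakfast/lunch/dinner,
#'   4 adds an afternoon snack; at most 4).
#' @param seed Integer seed; fully determines every generated stream.
#' @param missing_rate Fraction of CGM samples removed by [corrupt_dataset()].
#' @param outlier_rate Fraction of CGM samples turned into spikes by
#'   [corrupt_dataset()].
#' @param noise_sd CGM sensor noise standard deviation, mg/dL.
#' @param enrollment_span_days Calendar span over which patients start wearing
#'   the sensor (rolling enrollment); 0 starts everyone on the same day.
#' @param meal_window Post-meal window for peak search, minutes.
#' @param baseline_window Pre-meal window for the baseline median, minutes.
#' @param start_date First enrollment date (UTC midnight).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 60, days = 30, cgm_interval = 5,
                       meals_per_day = 3, seed = 1, missing_rate = 0,
                       outlier_rate = 0, noise_sd = 12,
                       enrollment_span_days = 70, meal_window = 120,
                       baseline_window = 60, start_date = "2023-03-01") {
  cfg <- list(
    n_patients = n_patients, days = days, cgm_interval = cgm_interval,
    meals_per_day = meals_per_day, seed = as.integer(seed),
    missing_rate = missing_rate, outlier_rate = outlier_rate,
    noise_sd = noise_sd, enrollment_span_days = enrollment_span_days,
    meal_window = meal_window, baseline_window = baseline_window,
    start_date = start_date
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || cfg$n_patients < 1) {
    stop_invalid_config("n_patients must be >= 1")
  }
  if (cfg$cgm_interval <= 0) stop_invalid_config("cgm_interval must be > 0")
  if (cfg$days < 1) stop_invalid_config("days must be >= 1")
  if (cfg$meals_per_day < 1 || cfg$meals_per_day > 4) {
    stop_invalid_config("meals_per_day must be between 1 and 4")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop_invalid_config("missing_rate must be in [0, 1)")
  }
  if (cfg$outlier_rate < 0 || cfg$outlier_rate >= 1) {
    stop_invalid_config("outlier_rate must be in [0, 1)")
  }
  if (cfg$noise_sd < 0) stop_invalid_config("noise_sd must be >= 0")
  invisible(cfg)
}

#' Bundled food table
#'
#' A small food table (one row per food, per typical portion) with
#' macronutrients, fiber, glycemic index and dietary tags. Stands in for the
#' large food-composition databases a production system would use.
#'
#' @return A data.table with columns food_id, name, calories, carbs_g,
#'   protein_g, fat_g, fiber_g, glycemic_index, tags.
#' @export
default_food_table <- function() {
  path <- system.file("extdata", "foods.csv", package = "glycotwin")
  ft <- data.table::fread(path)
  ft[, tags := as.character(tags)]
  ft[]
}
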