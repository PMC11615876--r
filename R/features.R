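# Feature engineering: from cleaned streams to the model's predictor rows.

#' The 37-feature registry
#'
#' Fixed name/order/type registry of the predictor row consumed by the PPGR
#' model: demographics, labs, medications, meal composition (including
#' carbohydrate-to-protein ratio and time since last meal), meal-type
#' encoding, time of day, recent-glucose context, activity and sleep.
#'
#' @return A data.table with columns name, group, type (numeric | binary).
#' @export
feature_registry <- function() {
  reg <- data.table::rbindlist(list(
    data.table(name = c("age", "sex_male", "bmi", "waist_cm"),
               group = "demographics",
               type = c("numeric", "binary", "numeric", "numeric")),
    data.table(name = c("hba1c", "homa"), group = "labs", type = "numeric"),
    data.table(name = c("med_metformin", "med_sulfonylurea", "med_dpp4",
                        "med_count", "med_penalty_total"),
               group = "medications",
               type = c("binary", "binary", "binary", "numeric", "numeric")),
    data.table(name = c("calories", "carbs_g", "protein_g", "fat_g",
                        "fiber_g", "glycemic_index", "glycemic_load",
                        "carb_to_protein_ratio", "time_since_last_meal"),
               group = "meal", type = "numeric"),
    data.table(name = c("meal_breakfast", "meal_lunch", "meal_dinner",
                        "meal_snack"),
               group = "meal_type", type = "binary"),
    data.table(name = c("hour_sin", "hour_cos"), group = "time_of_day",
               type = "numeric"),
    data.table(name = c("baseline_adjusted", "premeal_median",
                        "trailing_slope", "trailing_mean", "trailing_sd"),
               group = "recent_glucose", type = "numeric"),
    data.table(name = c("steps_2h", "steps_day", "active_minutes_day",
                        "sedentary_minutes_day"),
               group = "activity", type = "numeric"),
    data.table(name = c("sleep_minutes", "sleep_efficiency"),
               group = "sleep", type = "numeric")
  ))
  stopifnot(nrow(reg) == 37L)
  reg[]
}

#' @rdname feature_registry
#' @param registry A feature registry table.
#' @export
registry_hash <- function(registry = feature_registry()) {
  rlang::hash(list(registry$name, registry$type))
}

#' Write the registry as YAML
#' @param registry A feature registry table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry = feature_registry(),
                           path = "registry.yaml") {
  yaml::write_yaml(
    list(features = lapply(seq_len(nrow(registry)), function(i)
      as.list(registry[i])), hash = registry_hash(registry)), path)
  invisible(path)
}

#' Default per-medication baseline penalty table (mg/dL)
#'
#' Additive compensation for pharmacologically lowered baselines. Magnitudes
#' are package defaults chosen per drug class; they are configuration, not
#' estimates from data.
#' @export
default_penalty_table <- function() {
  c(metformin = 6, sulfonylurea = 8, dpp4 = 4, insulin = 12,
    glp1 = 5, sglt2 = 7)
}

#' Medication-penalized pre-meal baseline
#'
#' Median glucose over the pre-meal window plus the summed penalty of the
#' patient's active glucose-lowering medications. The penalty is additive and
#' order-independent over the medication list.
#'
#' @param trace One patient's CGM data.table (timestamp, glucose_mgdl,
#'   optional quality_flag; "outlier" samples are ignored).
#' @param meal_time POSIXct meal time.
#' @param medications Character vector of active medication names.
#' @param penalty_table Named penalties, mg/dL; see [default_penalty_table()].
#' @param window Pre-meal window, minutes.
#' @return Adjusted baseline, mg/dL.
#' @export
baseline_glucose <- function(trace, meal_time,
                             medications = character(),
                             penalty_table = default_penalty_table(),
                             window = 60) {
  if (any(penalty_table < 0)) stop_invalid_config("penalties must be >= 0")
  g <- premeal_samples(trace, meal_time, window)
  if (length(g) < 3) {
    stop_insufficient_data("fewer than 3 samples in the pre-meal window")
  }
  pen <- penalty_table[medications]
  if (anyNA(pen)) {
    stop_invalid_config(sprintf("no penalty configured for: %s",
      paste(medications[is.na(pen)], collapse = ", ")))
  }
  median(g) + sum(pen)
}

premeal_samples <- function(trace, meal_time, window) {
  sel <- trace$timestamp > meal_time - window * 60 &
    trace$timestamp <= meal_time
  if ("quality_flag" %in% names(trace)) {
    sel <- sel & trace$quality_flag != "outlier"
  }
  trace$glucose_mgdl[sel]
}

#' Observed glucose peak in the post-meal window
#'
#' Maximum observed glucose inside (meal_time, meal_time + window\] and its
#' offset in minutes; ties are broken by the earliest sample.
#'
#' @inheritParams baseline_glucose
#' @param window_minutes Post-meal window, minutes.
#' @return A list: peak (mg/dL), minutes_to_peak.
#' @export
glucose_max <- function(trace, meal_time, window_minutes = 120) {
  sel <- trace$timestamp > meal_time &
    trace$timestamp <= meal_time + window_minutes * 60
  if ("quality_flag" %in% names(trace)) {
    sel <- sel & trace$quality_flag != "outlier"
  }
  tt <- trace$timestamp[sel]
  g <- trace$glucose_mgdl[sel]
  if (!length(g)) {
    stop_insufficient_data("no samples in the post-meal window")
  }
  o <- order(tt)
  g <- g[o]; tt <- tt[o]
  i <- which.max(g)  # which.max returns the earliest maximum
  list(peak = g[i], minutes_to_peak = as.numeric(tt[i] - meal_time,
                                                 units = "mins"))
}

#' Normalized glycemic impact of a meal
#'
#' @param peak Observed or predicted peak, mg/dL.
#' @param adjusted_baseline Medication-penalized baseline, mg/dL (> 0).
#' @return A list: delta (peak - baseline, mg/dL, may be negative) and
#'   relative (delta / baseline).
#' @export
normalized_impact <- function(peak, adjusted_baseline) {
  if (any(adjusted_baseline <= 0)) {
    stop_invalid_input("adjusted baseline must be > 0")
  }
  delta <- peak - adjusted_baseline
  list(delta = delta, relative = delta / adjusted_baseline)
}

#' Meal-level engineered features
#'
#' @param meal List/row with calories, carbs_g, protein_g, fat_g, fiber_g,
#'   glycemic_index, glycemic_load, timestamp.
#' @param meal_history POSIXct vector of the patient's earlier meal times.
#' @param protein_eps Grams guarding the ratio denominator.
#' @param tsl_cap Cap (and first-meal value) for time_since_last_meal, min.
#' @return A list: carb_to_protein_ratio, time_since_last_meal, first_meal,
#'   glycemic_load (recomputed as GI/100 x carbs and reconciled with the
#'   logged value).
#' @export
meal_features <- function(meal, meal_history = NULL, protein_eps = 1,
                          tsl_cap = 960) {
  meal <- as.list(meal)
  macros <- unlist(meal[c("carbs_g", "protein_g", "fat_g", "fiber_g")])
  if (any(macros < 0)) stop_invalid_meal("meal totals must be >= 0")
  gl <- meal$glycemic_index / 100 * meal$carbs_g
  prior <- meal_history[meal_history < meal$timestamp]
  first_meal <- length(prior) == 0
  tsl <- if (first_meal) tsl_cap else
    min(tsl_cap, as.numeric(meal$timestamp - max(prior), units = "mins"))
  list(
    carb_to_protein_ratio = meal$carbs_g / max(meal$protein_g, protein_eps),
    time_since_last_meal = tsl,
    first_meal = first_meal,
    glycemic_load = gl
  )
}

#' Temporal context ahead of a meal
#'
#' Trailing-glucose trend (least-squares slope in mg/dL per minute), mean and
#' SD over the trailing window, trailing step count, and the prior night's
#' sleep summary.
#'
#' @inheritParams baseline_glucose
#' @param activity Hourly activity data.table (timestamp, steps).
#' @param sleep Nightly sleep data.table (date, sleep_minutes, efficiency).
#' @param windows List: glucose (minutes), steps (minutes).
#' @return A `temporal_context` list.
#' @export
temporal_context <- function(trace, activity, sleep, meal_time,
                             windows = list(glucose = 60, steps = 120)) {
  sel <- trace$timestamp > meal_time - windows$glucose * 60 &
    trace$timestamp <= meal_time
  if ("quality_flag" %in% names(trace)) {
    sel <- sel & trace$quality_flag != "outlier"
  }
  g <- trace$glucose_mgdl[sel]
  tt <- as.numeric(trace$timestamp[sel] - meal_time, units = "mins")
  if (length(g) < 2) {
    stop_insufficient_data("fewer than 2 trailing glucose samples")
  }
  slope <- if (var(tt) == 0) 0 else cov(tt, g) / var(tt)
  st <- activity[activity$timestamp >= meal_time - windows$steps * 60 &
                   activity$timestamp < meal_time, ]
  day <- as.Date(meal_time)
  night <- sleep[sleep$date == day, ]
  ctx <- list(
    trailing_slope = slope,
    trailing_mean = mean(g),
    trailing_sd = sd(g),
    steps_trailing = sum(st$steps),
    sleep_minutes = if (nrow(night)) night$sleep_minutes[1] else NA_real_,
    sleep_efficiency = if (nrow(night)) night$efficiency[1] else NA_real_
  )
  class(ctx) <- "temporal_context"
  ctx
}

#' Assemble one predictor row
#'
#' Binds the profile, meal, temporal-context and baseline components into a
#' named numeric vector matching the registry exactly (order and length). A
#' pure function of its inputs.
#'
#' @param profile One-row profile (age, sex, bmi, waist_cm, hba1c, homa,
#'   medication indicators).
#' @param meal One meal row plus the [meal_features()] list.
#' @param context A [temporal_context()].
#' @param baseline Adjusted baseline, mg/dL.
#' @param registry The [feature_registry()].
#' @param penalty_table See [default_penalty_table()].
#' @param daily_activity Optional list: steps_day, active_minutes_day,
#'   sedentary_minutes_day.
#' @return Named numeric vector of length nrow(registry).
#' @export
assemble_features <- function(profile, meal, context, baseline,
                              registry = feature_registry(),
                              penalty_table = default_penalty_table(),
                              daily_activity = list(steps_day = 0,
                                                    active_minutes_day = 0,
                                                    sedentary_minutes_day = 0)) {
  profile <- as.list(profile)
  meal <- as.list(meal)
  mf <- meal_features(meal, meal$meal_history)
  hod <- as.numeric(format(meal$timestamp, "%H", tz = "UTC")) +
    as.numeric(format(meal$timestamp, "%M", tz = "UTC")) / 60
  meds <- c("metformin", "sulfonylurea", "dpp4")[c(
    profile$med_metformin, profile$med_sulfonylurea, profile$med_dpp4) == 1]
  v <- c(
    age = profile$age, sex_male = as.numeric(profile$sex == "M"),
    bmi = profile$bmi, waist_cm = profile$waist_cm,
    hba1c = profile$hba1c, homa = profile$homa,
    med_metformin = profile$med_metformin,
    med_sulfonylurea = profile$med_sulfonylurea,
    med_dpp4 = profile$med_dpp4, med_count = profile$med_count,
    med_penalty_total = sum(penalty_table[meds]),
    calories = meal$calories, carbs_g = meal$carbs_g,
    protein_g = meal$protein_g, fat_g = meal$fat_g, fiber_g = meal$fiber_g,
    glycemic_index = meal$glycemic_index, glycemic_load = mf$glycemic_load,
    carb_to_protein_ratio = mf$carb_to_protein_ratio,
    time_since_last_meal = mf$time_since_last_meal,
    meal_breakfast = as.numeric(meal$meal_type == "breakfast"),
    meal_lunch = as.numeric(meal$meal_type == "lunch"),
    meal_dinner = as.numeric(meal$meal_type == "dinner"),
    meal_snack = as.numeric(meal$meal_type == "snack"),
    hour_sin = sin(2 * pi * hod / 24), hour_cos = cos(2 * pi * hod / 24),
    baseline_adjusted = baseline,
    premeal_median = baseline - sum(penalty_table[meds]),
    trailing_slope = context$trailing_slope,
    trailing_mean = context$trailing_mean,
    trailing_sd = context$trailing_sd,
    steps_2h = context$steps_trailing,
    steps_day = daily_activity$steps_day,
    active_minutes_day = daily_activity$active_minutes_day,
    sedentary_minutes_day = daily_activity$sedentary_minutes_day,
    sleep_minutes = context$sleep_minutes,
    sleep_efficiency = context$sleep_efficiency
  )
  if (!identical(names(v), registry$name)) {
    stop_schema("assembled feature names do not match the registry")
  }
  v
}

#' Build the full feature table for a dataset
#'
#' Vectorized extraction of every meal's predictor row plus its observed
#' targets (glucoseMax, minutes to peak, delta over the adjusted baseline).
#' Meals whose pre-meal window holds fewer than 3 usable samples, whose
#' post-meal window is empty, or that lack a sleep record are excluded with a
#' logged reason.
#'
#' @param dataset A `glyco_dataset` or loaded `glyco_rawdata`.
#' @param registry The [feature_registry()].
#' @param penalty_table See [default_penalty_table()].
#' @param meal_window,baseline_window Minutes; default from the dataset
#'   config when present.
#' @return A data.table: meal_id, patient_id, timestamp, the 37 features,
#'   observed_peak, observed_minutes_to_peak, observed_delta, excluded,
#'   exclude_reason. Class `glyco_features`, attribute `registry_hash`.
#' @export
build_feature_table <- function(dataset, registry = feature_registry(),
                                penalty_table = default_penalty_table(),
                                meal_window = NULL, baseline_window = NULL) {
  cfg <- dataset$config
  if (is.null(meal_window)) meal_window <- cfg$meal_window %||% 120
  if (is.null(baseline_window)) baseline_window <- cfg$baseline_window %||% 60
  cgm <- dataset$cgm
  if ("quality_flag" %in% names(cgm)) cgm <- cgm[quality_flag != "outlier"]
  meals <- data.table::copy(dataset$meals)
  data.table::setorder(meals, patient_id, timestamp)
  meals[, `:=`(lo_pre = timestamp - baseline_window * 60, hi_pre = timestamp,
               hi_post = timestamp + meal_window * 60)]

  pre <- cgm[meals, on = .(patient_id, timestamp > lo_pre,
                           timestamp <= hi_pre),
             .(n_pre = sum(!is.na(x.glucose_mgdl)),
               premeal_median = median(x.glucose_mgdl),
               trailing_mean = mean(x.glucose_mgdl),
               trailing_sd = sd(x.glucose_mgdl),
               trailing_slope = {
                 tm <- as.numeric(x.timestamp, units = "secs") / 60
                 if (.N >= 2 && var(tm) > 0) cov(tm, x.glucose_mgdl) / var(tm)
                 else NA_real_
               }),
             by = .EACHI][, .(n_pre, premeal_median, trailing_mean,
                              trailing_sd, trailing_slope)]
  post <- cgm[meals, on = .(patient_id, timestamp > hi_pre,
                            timestamp <= hi_post),
              .(n_post = sum(!is.na(x.glucose_mgdl)),
                observed_peak = suppressWarnings(max(x.glucose_mgdl)),
                observed_minutes_to_peak = {
                  i <- which.max(x.glucose_mgdl)
                  if (length(i)) as.numeric(x.timestamp[i] -
                    i.timestamp[1], units = "secs") / 60 else NA_real_
                }),
              by = .EACHI][, .(n_post, observed_peak, observed_minutes_to_peak)]
  ft <- cbind(meals[, .(meal_id, patient_id, timestamp, meal_type, calories,
                        carbs_g, protein_g, fat_g, fiber_g, glycemic_index,
                        glycemic_load)], pre, post)

  # trailing 2 h steps
  meals[, `:=`(lo2 = timestamp - 7200, hi2 = timestamp)]
  st <- dataset$activity[meals, on = .(patient_id, timestamp >= lo2,
                                       timestamp < hi2),
                         .(steps_2h = sum(x.steps, na.rm = TRUE)),
                         by = .EACHI][, .(steps_2h)]
  ft[, steps_2h := st$steps_2h]

  # same-day activity summary and prior-night sleep
  act_day <- dataset$activity[, .(steps_day = sum(steps),
                                  active_minutes_day = sum(active_minutes),
                                  sedentary_minutes_day = sum(sedentary_minutes)),
                              by = .(patient_id, date = as.Date(timestamp))]
  ft[, date := as.Date(timestamp)]
  ft <- act_day[ft, on = .(patient_id, date)]
  ft <- dataset$sleep[, .(patient_id, date, sleep_minutes,
                          sleep_efficiency = efficiency)][
    ft, on = .(patient_id, date)]

  # profile join
  ft <- dataset$profiles[, .(patient_id, age, sex, bmi, waist_cm, hba1c,
                             homa, med_metformin, med_sulfonylurea, med_dpp4,
                             med_count)][ft, on = "patient_id"]

  # engineered scalars
  pen_tbl <- penalty_table
  ft[, med_penalty_total := med_metformin * pen_tbl[["metformin"]] +
       med_sulfonylurea * pen_tbl[["sulfonylurea"]] +
       med_dpp4 * pen_tbl[["dpp4"]]]
  ft[, baseline_adjusted := premeal_median + med_penalty_total]
  ft[, sex_male := as.numeric(sex == "M")]
  ft[, carb_to_protein_ratio := carbs_g / pmax(protein_g, 1)]
  data.table::setorder(ft, patient_id, timestamp)
  ft[, time_since_last_meal := {
    d <- as.numeric(diff(as.numeric(timestamp))) / 60
    pmin(960, c(960, d))
  }, by = patient_id]
  ft[, first_meal := time_since_last_meal == 960 &
       seq_len(.N) == 1, by = patient_id]
  hod <- as.numeric(format(ft$timestamp, "%H", tz = "UTC")) +
    as.numeric(format(ft$timestamp, "%M", tz = "UTC")) / 60
  ft[, `:=`(hour_sin = sin(2 * pi * hod / 24),
            hour_cos = cos(2 * pi * hod / 24))]
  ft[, `:=`(meal_breakfast = as.numeric(meal_type == "breakfast"),
            meal_lunch = as.numeric(meal_type == "lunch"),
            meal_dinner = as.numeric(meal_type == "dinner"),
            meal_snack = as.numeric(meal_type == "snack"))]
  ft[, glycemic_load := glycemic_index / 100 * carbs_g]

  # targets and exclusions
  ft[, observed_delta := observed_peak - baseline_adjusted]
  ft[, excluded := FALSE]
  ft[, exclude_reason := NA_character_]
  ft[is.na(n_pre) | n_pre < 3,
     `:=`(excluded = TRUE, exclude_reason = "no baseline")]
  ft[excluded == FALSE & (is.na(n_post) | n_post < 1),
     `:=`(excluded = TRUE, exclude_reason = "no post-meal samples")]
  ft[excluded == FALSE & is.na(sleep_minutes),
     `:=`(excluded = TRUE, exclude_reason = "no sleep record")]
  ft[excluded == FALSE & is.na(trailing_slope),
     `:=`(excluded = TRUE, exclude_reason = "no trailing glucose")]

  keep <- c("meal_id", "patient_id", "timestamp", registry$name,
            "observed_peak", "observed_minutes_to_peak", "observed_delta",
            "excluded", "exclude_reason")
  out <- ft[, ..keep]
  data.table::setattr(out, "registry_hash", registry_hash(registry))
  data.table::setattr(out, "class", c("glyco_features", class(out)))
  out[]
}

#' Extract the feature matrix from a feature table
#'
#' @param features A `glyco_features` table.
#' @param registry The registry the model expects.
#' @param include_excluded Keep excluded rows?
#' @return Numeric matrix with registry columns, rownames = meal_id.
#' @export
feature_matrix <- function(features, registry = feature_registry(),
                           include_excluded = FALSE) {
  if (!include_excluded) features <- features[excluded == FALSE]
  miss <- setdiff(registry$name, names(features))
  if (length(miss)) {
    stop_schema(sprintf("feature table lacks registry column(s): %s",
                        paste(miss, collapse = ", ")))
  }
  m <- as.matrix(features[, registry$name, with = FALSE])
  rownames(m) <- features$meal_id
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
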