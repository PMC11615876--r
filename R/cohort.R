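# Synthetic cohort generator.
#
# Ground-truth mechanism: each virtual patient carries a basal glucose level,
# a circadian modulation, and linear sensitivities that map a meal's
# composition and the patient's recent behaviour onto a postprandial rise:
#
#   carb_term = carb_sensitivity * carbs_g * GI/100
#   rise      = max(0, carb_term
#                      - fiber_damping * fiber_g
#                      - protein_fat_damping * (protein_g + fat_g)
#                      - activity_modifier
#                      + sleep_penalty * sleep_deficit_h)
#
# where activity_modifier = min(0.5, activity_damping * steps_2h/1000) *
# carb_term (recent walking blunts the excursion, capped at half) and
# sleep_deficit_h = max(0, 7 - prior-night sleep hours) (short sleep worsens
# it). The response curve is a linear rise to the peak at t_peak minutes
# followed by exponential decay with time constant tau; closed-form peaks make
# exact oracles possible downstream.

MEAL_T_PEAK <- 45   # minutes to peak after a meal
MEAL_TAU <- 25      # exponential decay constant, minutes
KERNEL_EXTENT <- 180  # kernel support truncated here (decay < 1% of rise)

#' Generate a cohort of virtual patients
#'
#' Draws observable profiles and latent ground-truth response parameters from
#' documented distributions. Carbohydrate sensitivity is linked to HbA1c, HOMA
#' and BMI (insulin resistance drives PPGR) with a small idiosyncratic
#' residual, so that a cross-patient model can in principle explain most of
#' the response variance. Parameter distributions:
#' basal glucose ~ Normal(110, 15) truncated to \[80, 170\] mg/dL; circadian
#' amplitude ~ U(5, 12) mg/dL; carb sensitivity = 0.8 + 0.4 (HbA1c - 5.5) +
#' 0.4 log(HOMA/3) + 0.015 (BMI - 25) + Normal(0, 0.05), floored at 0.3
#' mg/dL per effective gram; fiber damping ~ Normal(1.1, 0.15); protein/fat
#' damping ~ Normal(0.22, 0.04); activity damping ~ U(0.03, 0.06) per 1000
#' steps; sleep penalty ~ U(1, 2.5) mg/dL per deficit hour; per-medication
#' baseline depression ~ U(4, 9) mg/dL.
#'
#' @param config A [sim_config()].
#' @return A `glyco_cohort` data.table, one row per patient, holding both the
#'   observable profile and the latent ground-truth parameters.
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  n <- as.integer(config$n_patients)
  with_seed(config$seed, {
    ct <- data.table(
      patient_id = sprintf("P%03d", seq_len(n)),
      age = round(runif(n, 30, 68)),
      sex = sample(c("F", "M"), n, replace = TRUE),
      bmi = round(rnorm_trunc(n, 29, 4, 19, 45), 1),
      hba1c = round(rnorm_trunc(n, 7.8, 1.1, 5.8, 11.5), 1),
      homa = round(exp(rnorm(n, log(3), 0.4)), 2)
    )
    ct[, waist_cm := round(76 + 1.9 * (bmi - 25) + rnorm(n, 0, 4), 1)]
    ct[, med_metformin := as.integer(runif(n) < 0.65)]
    ct[, med_sulfonylurea := as.integer(runif(n) < 0.25)]
    ct[, med_dpp4 := as.integer(runif(n) < 0.15)]
    ct[, med_count := med_metformin + med_sulfonylurea + med_dpp4]
    ct[, med_metformin_dose := med_metformin *
          sample(c(500, 1000, 2000), n, replace = TRUE)]
    ct[, med_sulfonylurea_dose := med_sulfonylurea *
          sample(c(1, 2, 4), n, replace = TRUE)]
    ct[, med_dpp4_dose := med_dpp4 * sample(c(50, 100), n, replace = TRUE)]
    ct[, steps_daily_mean := round(rnorm_trunc(n, 7000, 2000, 2000, 14000))]
    ct[, sleep_mean_min := round(rnorm_trunc(n, 415, 35, 330, 480))]
    # latent ground-truth parameters
    ct[, basal_glucose := rnorm_trunc(n, 110, 15, 80, 170)]
    ct[, circadian_amplitude := runif(n, 5, 12)]
    ct[, carb_sensitivity := pmax(0.3, 0.8 + 0.4 * (hba1c - 5.5) +
          0.4 * log(homa / 3) + 0.015 * (bmi - 25) + rnorm(n, 0, 0.05))]
    ct[, fiber_damping := rnorm_trunc(n, 1.1, 0.15, 0.5, 1.7)]
    ct[, protein_fat_damping := rnorm_trunc(n, 0.22, 0.04, 0.08, 0.36)]
    ct[, activity_damping := runif(n, 0.03, 0.06)]
    ct[, sleep_penalty := runif(n, 1.0, 2.5)]
    ct[, med_effect := runif(n, 4, 9)]
    ct[, noise_sd := config$noise_sd]
    data.table::setattr(ct, "class", c("glyco_cohort", class(ct)))
    ct[]
  })
}

# circadian baseline: peaks around 08:00 (dawn phenomenon)
baseline_level <- function(patient) {
  pmax(72, patient$basal_glucose - patient$med_effect * patient$med_count)
}

circadian_term <- function(patient, hour_of_day) {
  patient$circadian_amplitude * sin(2 * pi * (hour_of_day - 2) / 24)
}

# closed-form noiseless rise for one meal in one context
true_rise <- function(patient, meal, context) {
  carb_term <- patient$carb_sensitivity * meal$carbs_g *
    meal$glycemic_index / 100
  act <- pmin(0.5, patient$activity_damping * context$steps_2h / 1000) *
    carb_term
  rise <- carb_term -
    patient$fiber_damping * meal$fiber_g -
    patient$protein_fat_damping * (meal$protein_g + meal$fat_g) -
    act +
    patient$sleep_penalty * context$sleep_deficit_h
  pmax(0, rise)
}

# response kernel evaluated at offsets (minutes since meal)
response_kernel <- function(offset_min, rise) {
  ifelse(offset_min <= 0 | offset_min > KERNEL_EXTENT, 0,
         ifelse(offset_min <= MEAL_T_PEAK,
                rise * offset_min / MEAL_T_PEAK,
                rise * exp(-(offset_min - MEAL_T_PEAK) / MEAL_TAU)))
}

#' Simulate the glucose curve of a single meal
#'
#' Evaluates the ground-truth response kernel for one patient, meal and
#' temporal context on the CGM grid, on top of the patient's meal-time
#' baseline (held fixed over the segment), optionally with sensor noise.
#'
#' @param patient One cohort row (list or single-row data.frame) with the
#'   latent ground-truth parameters.
#' @param meal List with carbs_g, protein_g, fat_g, fiber_g, glycemic_index.
#' @param context List with steps_2h (steps in the trailing 2 h),
#'   sleep_deficit_h (hours below 7 h the prior night) and hour_of_day of the
#'   meal. Missing entries default to 0 steps, 0 deficit, 08:00.
#' @param noise_sd_override Sensor noise sd, mg/dL; defaults to the patient's.
#' @param cgm_interval Sampling interval, minutes.
#' @param window Segment length, minutes.
#' @return A data.table (offset_min, glucose_mgdl) with attributes
#'   `true_rise`, `true_peak` and `true_peak_offset`.
#' @export
simulate_meal_response <- function(patient, meal, context = list(),
                                   noise_sd_override = NULL,
                                   cgm_interval = 5, window = 180) {
  patient <- as.list(patient)
  meal <- as.list(meal)
  macros <- unlist(meal[c("carbs_g", "protein_g", "fat_g", "fiber_g")])
  if (anyNA(macros) || any(macros < 0)) {
    stop_invalid_meal("meal macronutrients must be present and >= 0")
  }
  ctx <- list(steps_2h = 0, sleep_deficit_h = 0, hour_of_day = 8)
  ctx[names(context)] <- context
  sdn <- if (is.null(noise_sd_override)) patient$noise_sd else noise_sd_override
  if (sdn < 0) stop_invalid_config("noise sd must be >= 0")
  rise <- true_rise(patient, meal, ctx)
  off <- seq(0, window, by = cgm_interval)
  base <- baseline_level(patient) + circadian_term(patient, ctx$hour_of_day)
  g <- base + response_kernel(off, rise)
  if (sdn > 0) g <- g + rnorm(length(g), 0, sdn)
  out <- data.table(offset_min = off, glucose_mgdl = g)
  data.table::setattr(out, "true_rise", rise)
  data.table::setattr(out, "true_peak", base + rise)
  data.table::setattr(out, "true_peak_offset", MEAL_T_PEAK)
  out[]
}

# compose one meal from the food table: main meals get a main plus a side,
# snacks a single item; glycemic index is the carb-weighted mean
compose_meal <- function(foods, meal_type) {
  n_items <- if (meal_type == "snack") 1L else 2L
  idx <- sample(nrow(foods), n_items)
  portion <- round(runif(n_items, 0.75, 1.4), 2)
  it <- foods[idx]
  carbs <- sum(it$carbs_g * portion)
  gi <- if (carbs > 0) sum(it$carbs_g * portion * it$glycemic_index) / carbs else 0
  list(
    food_ids = paste(it$food_id, collapse = ";"),
    portions = paste(portion, collapse = ";"),
    calories = sum(it$calories * portion),
    carbs_g = carbs,
    protein_g = sum(it$protein_g * portion),
    fat_g = sum(it$fat_g * portion),
    fiber_g = sum(it$fiber_g * portion),
    glycemic_index = gi,
    glycemic_load = gi / 100 * carbs
  )
}

# hourly activity weights: zero overnight, bumps morning and evening
ACTIVITY_WEIGHTS <- local({
  w <- numeric(24)
  w[8:23] <- c(0.6, 1.2, 0.9, 0.7, 0.8, 0.9, 0.7, 0.6,
               0.6, 0.7, 1.0, 1.4, 1.1, 0.7, 0.4, 0.2)  # hours 7..22
  w / sum(w)
})

#' Simulate the full study streams for a cohort
#'
#' Produces CGM traces, meal logs, hourly activity, nightly sleep, observable
#' profiles and a ground-truth PPGR table, all on one shared UTC clock.
#' Patients enroll on a rolling schedule spread evenly over
#' `enrollment_span_days`, as in a trial with staggered recruitment.
#'
#' @param cohort A [generate_cohort()] result.
#' @param config The same [sim_config()].
#' @return A `glyco_dataset` list with elements cgm, meals, activity, sleep,
#'   profiles, truth, cohort, config.
#' @export
simulate_study <- function(cohort, config) {
  validate_sim_config(config)
  if (!nrow(cohort)) stop_invalid_input("cohort must be nonempty")
  foods <- default_food_table()
  n <- nrow(cohort)
  span <- config$enrollment_span_days
  enroll <- if (n == 1) 0 else round(seq(0, span, length.out = n))
  t0_all <- as_utc(config$start_date) + enroll * 86400
  interval <- config$cgm_interval
  mpd <- config$meals_per_day
  meal_base_hours <- sort(c(8, 13, 19, 16)[seq_len(mpd)])
  meal_types <- c("breakfast", "lunch", "dinner",
                  "snack")[match(meal_base_hours, c(8, 13, 19, 16))]
  jitter_grid <- seq(-45, 45, by = interval)
  n_samp <- as.integer(config$days * 24 * 60 / interval)

  with_seed(config$seed + 1L, {
    per_patient <- lapply(seq_len(n), function(i) {
      p <- as.list(cohort[i])
      t0 <- t0_all[i]
      ts <- t0 + (seq_len(n_samp) - 1) * interval * 60
      hod <- (as.numeric(ts - t0, units = "mins") / 60) %% 24

      # nightly sleep: night ending on the morning of each study day
      sleep <- data.table(
        patient_id = p$patient_id,
        date = as.Date(t0) + 0:(config$days - 1),
        sleep_minutes = round(rnorm_trunc(config$days, p$sleep_mean_min,
                                          40, 240, 600)),
        efficiency = round(rnorm_trunc(config$days, 0.88, 0.05, 0.6, 0.99), 3)
      )
      sleep[, deficit_h := pmax(0, 7 - sleep_minutes / 60)]

      # hourly steps
      hours <- t0 + (0:(config$days * 24 - 1)) * 3600
      w <- ACTIVITY_WEIGHTS[(as.integer(format(hours, "%H", tz = "UTC")) %% 24) + 1]
      steps <- round(p$steps_daily_mean * w * exp(rnorm(length(w), 0, 0.35)))
      activity <- data.table(patient_id = p$patient_id, timestamp = hours,
                             steps = steps)
      activity[, active_minutes := pmin(60, round(steps / 90))]
      activity[, sedentary_minutes := 60 - active_minutes]

      # meals
      n_meals <- config$days * mpd
      meal_rows <- vector("list", n_meals)
      g0 <- baseline_level(p) + circadian_term(p, hod)  # noiseless trace
      k <- 0L
      for (d in 0:(config$days - 1)) {
        for (j in seq_len(mpd)) {
          k <- k + 1L
          jit <- sample(jitter_grid, 1)
          m_min <- d * 1440 + meal_base_hours[j] * 60 + jit
          m_ts <- t0 + m_min * 60
          meal <- compose_meal(foods, meal_types[j])
          night <- sleep[date == as.Date(t0) + d]
          steps_2h <- activity[timestamp >= m_ts - 7200 & timestamp < m_ts,
                               sum(steps)]
          ctx <- list(steps_2h = steps_2h, sleep_deficit_h = night$deficit_h,
                      hour_of_day = (m_min / 60) %% 24)
          rise <- true_rise(p, meal, ctx)
          # add the kernel onto the noiseless grid
          i0 <- m_min / interval  # meals are on-grid by construction
          n_off <- KERNEL_EXTENT / interval
          idx <- (i0 + 1):(i0 + n_off) + 1  # grid indices after the meal
          keep <- idx <= n_samp
          g0[idx[keep]] <- g0[idx[keep]] +
            response_kernel((seq_len(n_off) * interval)[keep], rise)
          meal_rows[[k]] <- c(list(patient_id = p$patient_id,
                                   meal_id = sprintf("%s_m%04d", p$patient_id, k),
                                   timestamp = m_ts, meal_type = meal_types[j]),
                              meal, list(true_rise = rise,
                                         steps_2h = steps_2h,
                                         sleep_deficit_h = night$deficit_h))
        }
      }
      meals <- rbindlist(meal_rows)

      noise <- if (config$noise_sd > 0) rnorm(n_samp, 0, config$noise_sd) else 0
      cgm <- data.table(patient_id = p$patient_id, timestamp = ts,
                        glucose_mgdl = pmin(400, pmax(40, g0 + noise)))

      # ground truth per meal from the noiseless trace
      sec <- as.numeric(ts)
      truth <- meals[, {
        msec <- as.numeric(timestamp)
        win <- which(sec > msec & sec <= msec + config$meal_window * 60)
        pre <- which(sec > msec - config$baseline_window * 60 & sec <= msec)
        pk <- which.max(g0[win])
        .(true_peak = g0[win][pk],
          true_minutes_to_peak = (sec[win][pk] - msec) / 60,
          true_baseline = median(g0[pre]))
      }, by = .(patient_id, meal_id, timestamp, true_rise, steps_2h,
                sleep_deficit_h)]
      truth[, true_delta := true_peak - true_baseline]
      meals[, c("true_rise", "steps_2h", "sleep_deficit_h") := NULL]
      list(cgm = cgm, meals = meals, activity = activity, sleep = sleep,
           truth = truth)
    })

    profiles <- cohort[, .(patient_id, age, sex, bmi, hba1c, homa, waist_cm,
                           med_metformin, med_sulfonylurea, med_dpp4,
                           med_count, med_metformin_dose,
                           med_sulfonylurea_dose, med_dpp4_dose)]
    ds <- list(
      cgm = rbindlist(lapply(per_patient, `[[`, "cgm")),
      meals = rbindlist(lapply(per_patient, `[[`, "meals")),
      activity = rbindlist(lapply(per_patient, `[[`, "activity")),
      sleep = rbindlist(lapply(per_patient, `[[`, "sleep")),
      profiles = profiles,
      truth = rbindlist(lapply(per_patient, `[[`, "truth")),
      cohort = cohort,
      config = config
    )
    ds$cgm[, quality_flag := "ok"]
    class(ds) <- "glyco_dataset"
    ds
  })
}

#' @export
print.glyco_dataset <- function(x, ...) {
  cat("<glyco_dataset>\n")
  cat(sprintf("  patients: %d  CGM samples: %d  meals: %d\n",
              nrow(x$profiles), nrow(x$cgm), nrow(x$meals)))
  cat(sprintf("  span: %s .. %s (UTC)\n",
              format(min(x$cgm$timestamp)), format(max(x$cgm$timestamp))))
  invisible(x)
}

#' Inject missingness and outliers into a simulated dataset
#'
#' Removes CGM samples completely at random at `missing_rate` and turns a
#' further `outlier_rate` fraction into sensor artifacts: single-sample
#' impulses displaced by 80-200 mg/dL from the true reading, in a direction
#' chosen among those that keep the corrupted value inside the 40-500 mg/dL
#' sensor range (so the realized displacement is always the documented
#' magnitude). Injected outliers are recorded in a hidden `truth_outlier`
#' column so cleaning can be scored against the injection.
#'
#' @param dataset A `glyco_dataset`.
#' @param config A [sim_config()] providing missing_rate, outlier_rate, seed.
#' @return The corrupted `glyco_dataset`.
#' @export
corrupt_dataset <- function(dataset, config) {
  if (config$missing_rate < 0 || config$missing_rate >= 1 ||
      config$outlier_rate < 0 || config$outlier_rate >= 1) {
    stop_invalid_config("missing_rate and outlier_rate must be in [0, 1)")
  }
  if (config$missing_rate == 0 && config$outlier_rate == 0) return(dataset)
  with_seed(config$seed + 2L, {
    cgm <- data.table::copy(dataset$cgm)
    keep <- runif(nrow(cgm)) >= config$missing_rate
    cgm <- cgm[keep]
    out <- runif(nrow(cgm)) < config$outlier_rate
    if (any(out)) {
      x <- cgm$glucose_mgdl[out]
      n_out <- length(x)
      mag <- runif(n_out, 80, 200)
      # direction: down only where the full magnitude fits above the 40
      # mg/dL sensor floor; up is capped at the 500 mg/dL ceiling
      can_down <- x - mag >= 40
      down <- can_down & (runif(n_out) < 0.5)
      shift <- ifelse(down, -mag, pmin(mag, 500 - x))
      cgm[out, glucose_mgdl := glucose_mgdl + shift]
    }
    cgm[, truth_outlier := out]
    dataset$cgm <- cgm
    dataset
  })
}

#' Write a simulated dataset to CSV/JSON files
#'
#' Emits cgm.csv, meals.csv, activity.csv, sleep.csv, profiles.json and
#' truth_ppgr.csv with ISO-8601 UTC timestamps and glucose in mg/dL.
#'
#' @param dataset A `glyco_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  iso <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  cgm <- data.table::copy(dataset$cgm)[, timestamp := iso(timestamp)]
  meals <- data.table::copy(dataset$meals)[, timestamp := iso(timestamp)]
  act <- data.table::copy(dataset$activity)[, timestamp := iso(timestamp)]
  truth <- data.table::copy(dataset$truth)[, timestamp := iso(timestamp)]
  data.table::fwrite(cgm, file.path(dir, "cgm.csv"))
  data.table::fwrite(meals, file.path(dir, "meals.csv"))
  data.table::fwrite(act, file.path(dir, "activity.csv"))
  data.table::fwrite(dataset$sleep, file.path(dir, "sleep.csv"))
  data.table::fwrite(truth, file.path(dir, "truth_ppgr.csv"))
  jsonlite::write_json(dataset$profiles, file.path(dir, "profiles.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
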