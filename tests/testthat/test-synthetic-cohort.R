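test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(n_patients = 0), class = "glycotwin_invalid_config")
  expect_error(sim_config(missing_rate = 1), class = "glycotwin_invalid_config")
  expect_error(sim_config(outlier_rate = 1.2), class = "glycotwin_invalid_config")
  expect_error(sim_config(meals_per_day = 0), class = "glycotwin_invalid_config")
  expect_error(sim_config(cgm_interval = 0), class = "glycotwin_invalid_config")
})

test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- sim_config(n_patients = 8, days = 2, seed = 42)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  ds1 <- simulate_study(generate_cohort(cfg), cfg)
  ds2 <- simulate_study(generate_cohort(cfg), cfg)
  expect_identical(ds1$cgm, ds2$cgm)
  expect_identical(ds1$meals, ds2$meals)
  expect_identical(ds1$truth, ds2$truth)
})

test_that("basal glucose matches its documented distribution at large n", {
  co <- generate_cohort(sim_config(n_patients = 1000, days = 1, seed = 1))
  # basal ~ Normal(110, 15) truncated to [80, 170]; 3 SE of the mean
  se <- 15 / sqrt(1000)
  expect_lt(abs(mean(co$basal_glucose) - 110), 3 * se)
  expect_true(all(co$basal_glucose >= 80 & co$basal_glucose <= 170))
  expect_true(all(co$carb_sensitivity >= 0.3))
  expect_true(all(co$noise_sd >= 0))
})

test_that("meal response kernel obeys its closed form", {
  meal <- list(carbs_g = 60, protein_g = 10, fat_g = 5, fiber_g = 2,
               glycemic_index = 50)
  # null mechanism: all sensitivities zero, no noise -> flat at baseline
  flat <- simulate_meal_response(flat_patient(), meal)
  expect_true(all(flat$glucose_mgdl == 100))

  # linearity in carbs when every damping term is zero
  p <- flat_patient(carb_sensitivity = 2)
  r1 <- attr(simulate_meal_response(p, meal), "true_rise")
  meal2 <- meal; meal2$carbs_g <- 120
  r2 <- attr(simulate_meal_response(p, meal2), "true_rise")
  expect_equal(r2, 2 * r1)
  expect_equal(r1, 2 * 60 * 50 / 100)

  bad <- meal; bad$carbs_g <- -5
  expect_error(simulate_meal_response(p, bad), class = "glycotwin_invalid_meal")
})

test_that("noiseless peak is monotone non-decreasing in carbohydrates", {
  co <- generate_cohort(sim_config(n_patients = 5, days = 1, seed = 9))
  meal <- list(carbs_g = 0, protein_g = 15, fat_g = 10, fiber_g = 4,
               glycemic_index = 60)
  ctx <- list(steps_2h = 1200, sleep_deficit_h = 0.5)
  for (i in seq_len(nrow(co))) {
    rises <- vapply(seq(0, 120, by = 5), function(cb) {
      m <- meal; m$carbs_g <- cb
      attr(simulate_meal_response(as.list(co[i]), m, ctx,
                                  noise_sd_override = 0), "true_rise")
    }, numeric(1))
    expect_true(all(diff(rises) >= -1e-12))
  }
})

test_that("study simulation produces consistent, aligned streams", {
  cfg <- sim_config(n_patients = 2, days = 1, seed = 3, noise_sd = 0,
                    enrollment_span_days = 0)
  ds <- simulate_study(generate_cohort(cfg), cfg)
  expect_equal(nrow(ds$truth), 2 * 1 * 3)  # patients x days x meals
  # strictly increasing CGM timestamps at the configured spacing
  for (pid in ds$profiles$patient_id) {
    tt <- ds$cgm[patient_id == pid, timestamp]
    expect_true(all(as.numeric(diff(tt), units = "mins") == cfg$cgm_interval))
  }
  # every meal has a recorded ground-truth peak
  expect_true(all(ds$meals$meal_id %in% ds$truth$meal_id))
})

test_that("noiseless extraction recovers generator truth exactly", {
  tn <- tiny_noiseless()
  m <- merge(tn$features[excluded == FALSE], tn$ds$truth, by = "meal_id")
  expect_equal(m$observed_peak, m$true_peak, tolerance = 1e-12)
  expect_equal(m$premeal_median, m$true_baseline, tolerance = 1e-12)
})

test_that("noisy peak extraction error matches the folded-normal magnitude", {
  cfg <- sim_config(n_patients = 10, days = 20, seed = 13, noise_sd = 12,
                    enrollment_span_days = 30)
  ds <- simulate_study(generate_cohort(cfg), cfg)
  ft <- build_feature_table(ds)
  m <- merge(ft[excluded == FALSE], ds$truth, by = "meal_id")
  # the folded-normal closed form E|peak_obs - peak_true| = sqrt(2/pi) sigma
  # describes extraction where the peak sample dominates; condition on meals
  # whose rise is resolved above the noise (>= 2 sigma), where flat-curve
  # max-of-noise inflation does not apply
  m <- m[true_rise >= 2 * 12]
  expect_gte(nrow(m), 200)
  dev <- mean(abs(m$observed_peak - m$true_peak))
  expect_lt(abs(dev - sqrt(2 / pi) * 12) / (sqrt(2 / pi) * 12), 0.15)
})

test_that("dataset corruption injects the configured rates deterministically", {
  cfg <- sim_config(n_patients = 2, days = 18, seed = 5, noise_sd = 12,
                    enrollment_span_days = 0)
  ds <- simulate_study(generate_cohort(cfg), cfg)

  clean_cfg <- cfg  # zero rates: identity
  expect_identical(corrupt_dataset(ds, clean_cfg), ds)

  cfg$missing_rate <- 0.2
  n0 <- nrow(ds$cgm)
  expect_gte(n0, 10000)
  cor1 <- corrupt_dataset(ds, cfg)
  removed <- n0 - nrow(cor1$cgm)
  expect_lt(abs(removed / n0 - 0.2), 0.01)
  expect_identical(cor1$cgm, corrupt_dataset(ds, cfg)$cgm)

  cfg$outlier_rate <- 0.05
  cor2 <- corrupt_dataset(ds, cfg)
  expect_true("truth_outlier" %in% names(cor2$cgm))
  expect_gt(sum(cor2$cgm$truth_outlier), 0)

  cfg$missing_rate <- 1.0
  expect_error(corrupt_dataset(ds, cfg), class = "glycotwin_invalid_config")
})
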