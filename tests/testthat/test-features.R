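meal_t <- as.POSIXct("2023-03-01 08:00:00", tz = "UTC")

test_that("medication-penalized baseline is median plus configured penalties", {
  tr <- make_trace(rep(90, 20), start = "2023-03-01 06:45:00")
  expect_equal(baseline_glucose(tr, meal_t), 90)
  expect_equal(baseline_glucose(tr, meal_t, "metformin",
                                penalty_table = c(metformin = 8)), 98)
  # additive and order-independent over the medication list
  pt <- c(metformin = 6, dpp4 = 4)
  expect_equal(baseline_glucose(tr, meal_t, c("metformin", "dpp4"), pt),
               baseline_glucose(tr, meal_t, c("dpp4", "metformin"), pt))
  expect_equal(baseline_glucose(tr, meal_t, c("metformin", "dpp4"), pt), 100)

  empty <- make_trace(rep(90, 5), start = "2023-03-01 10:00:00")
  expect_error(baseline_glucose(empty, meal_t),
               class = "glycotwin_insufficient_data")
})

test_that("glucoseMax takes the window maximum with earliest-tie rule", {
  tr <- make_trace(rep(100, 40), start = "2023-03-01 08:05:00")
  gm <- glucose_max(tr, meal_t)
  expect_equal(gm$peak, 100)
  expect_equal(gm$minutes_to_peak, 5)

  g <- rep(100, 40); g[9] <- 180  # +45 min at 5-min spacing from 08:05
  gm2 <- glucose_max(make_trace(g, start = "2023-03-01 08:05:00"), meal_t)
  expect_equal(gm2$peak, 180)
  expect_equal(gm2$minutes_to_peak, 45)

  g3 <- rep(100, 40); g3[c(6, 12)] <- 150  # +30 and +60 min
  gm3 <- glucose_max(make_trace(g3, start = "2023-03-01 08:05:00"), meal_t)
  expect_equal(gm3$minutes_to_peak, 30)

  expect_error(glucose_max(tr, meal_t + 86400),
               class = "glycotwin_insufficient_data")
})

test_that("normalized impact is delta and relative fraction", {
  ni <- normalized_impact(160, 100)
  expect_equal(ni$delta, 60)
  expect_equal(ni$relative, 0.6)
  expect_equal(normalized_impact(100, 100)$delta, 0)
  expect_error(normalized_impact(100, 0), class = "glycotwin_invalid_input")
})

test_that("meal-level features follow their definitions", {
  meal <- list(carbs_g = 60, protein_g = 20, fat_g = 10, fiber_g = 3,
               glycemic_index = 50, glycemic_load = 30, timestamp = meal_t)
  mf <- meal_features(meal)
  expect_equal(mf$carb_to_protein_ratio, 3)
  expect_true(mf$first_meal)
  expect_equal(mf$time_since_last_meal, 960)  # capped first-meal value

  mf2 <- meal_features(meal, meal_history = meal_t - 3 * 3600)
  expect_false(mf2$first_meal)
  expect_equal(mf2$time_since_last_meal, 180)

  # glycemic load reconciliation: GL = GI/100 x carbs
  meal$carbs_g <- 40
  expect_equal(meal_features(meal)$glycemic_load, 20)
})

test_that("temporal context captures trend, variability and behaviour", {
  tr <- make_trace(c(100, 110, 120), start = "2023-03-01 07:50:00")
  act <- data.table::data.table(patient_id = "T01",
                                timestamp = meal_t - 3600, steps = 700)
  slp <- data.table::data.table(patient_id = "T01",
                                date = as.Date("2023-03-01"),
                                sleep_minutes = 400, efficiency = 0.9)
  ctx <- temporal_context(tr, act, slp, meal_t)
  expect_equal(ctx$trailing_slope, 2)  # mg/dL per minute
  expect_equal(ctx$trailing_mean, 110)
  expect_equal(ctx$steps_trailing, 700)
  expect_equal(ctx$sleep_minutes, 400)

  flat <- temporal_context(make_trace(rep(100, 5),
                                      start = "2023-03-01 07:40:00"),
                           act, slp, meal_t)
  expect_equal(flat$trailing_slope, 0)
  expect_equal(flat$trailing_sd, 0)

  one <- make_trace(100, start = "2023-03-01 07:55:00")
  expect_error(temporal_context(one, act, slp, meal_t),
               class = "glycotwin_insufficient_data")
})

test_that("assembled vectors match the 37-entry registry exactly", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 37)
  tn <- tiny_noiseless()
  keep <- tn$features[excluded == FALSE]
  X <- feature_matrix(keep)
  expect_identical(colnames(X), reg$name)
  expect_false(anyNA(X))

  # purity: the same dataset assembles to the same table
  ft2 <- build_feature_table(tn$ds)
  expect_identical(as.data.frame(tn$features), as.data.frame(ft2))

  # registry mismatch is a schema error
  expect_error(feature_matrix(keep, registry = data.table::data.table(
    name = c(reg$name, "extra"), group = "x", type = "numeric")),
    class = "glycotwin_schema_error")
})

test_that("meals without a usable pre-meal window are excluded with a reason", {
  tn <- tiny_noiseless()
  ds <- tn$ds
  target_meal <- ds$meals[5]
  cgm <- ds$cgm[!(patient_id == target_meal$patient_id &
                    timestamp > target_meal$timestamp - 60 * 60 &
                    timestamp <= target_meal$timestamp)]
  ds2 <- ds
  ds2$cgm <- cgm
  ft <- build_feature_table(ds2)
  row <- ft[meal_id == target_meal$meal_id]
  expect_true(row$excluded)
  expect_equal(row$exclude_reason, "no baseline")
  expect_equal(sum(ft$excluded), 1)
})
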