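test_that("temporal-gap folds partition rows and honour the gap", {
  # ten weeks of hourly rows
  times <- as.POSIXct("2023-01-01", tz = "UTC") + seq(0, 70 * 86400, by = 3600)
  folds <- make_folds(times, k = 5, gap_days = 14)
  # every row validated exactly once
  expect_equal(sort(unlist(folds$val_idx)), seq_along(times))
  expect_equal(tabulate(folds$fold, 5), lengths(folds$val_idx))
  # min time distance between train and val of each fold >= 14 days
  for (f in 1:5) {
    vt <- times[folds$val_idx[[f]]]
    tt <- times[folds$train_idx[[f]]]
    dmin <- min(vapply(as.numeric(vt), function(v)
      min(abs(as.numeric(tt) - v)), numeric(1)))
    expect_gte(dmin, 14 * 86400)
  }
  # a 3-week study cannot support k = 5 with a 14-day gap
  short <- as.POSIXct("2023-01-01", tz = "UTC") + seq(0, 21 * 86400, by = 3600)
  expect_error(make_folds(short, k = 5, gap_days = 14),
               class = "glycotwin_infeasible_folds")
})

test_that("ensemble averaging equals the arithmetic mean", {
  expect_equal(ensemble_average(5), 5)
  expect_equal(ensemble_average(c(2, 4, 6)), 4)
  expect_error(ensemble_average(numeric()), class = "glycotwin_invalid_input")
  set.seed(2)
  for (i in 1:25) {
    x <- rnorm(sample(1:200, 1))
    expect_equal(ensemble_average(x), sum(x) / length(x))
  }
})

test_that("training rejects degenerate targets and is seed-deterministic", {
  sn <- small_noisy()
  folds <- make_folds(sn$keep$timestamp)
  expect_error(train_ppgr(sn$keep, rep(5, nrow(sn$keep)),
                          model_config(seed = 1), folds),
               class = "glycotwin_degenerate_target")

  m1 <- small_model()
  m2 <- train_ppgr(sn$keep, sn$keep$observed_delta,
                   model_config(seed = 21), folds)
  expect_identical(m1$report$pooled, m2$report$pooled)
  expect_identical(m1$report$outer_predictions, m2$report$outer_predictions)
})

test_that("a noiseless truth inside the model class is recovered", {
  rf <- recovery_fit()
  expect_gte(nrow(rf$features), 600)
  op <- rf$model$report$outer_predictions
  expect_lt(mean(abs(op$observed - op$predicted)), 5)
})

test_that("prediction is pure, registry-checked and monotone in carbs", {
  rf <- recovery_fit()
  X <- feature_matrix(rf$features)[1:5, , drop = FALSE]
  expect_identical(predict(rf$model, X), predict(rf$model, X))
  expect_error(predict(rf$model, X[, -1, drop = FALSE]),
               class = "glycotwin_schema_error")

  # carb-only probe: 100 grid points, glycemic load moves with carbs
  base <- feature_matrix(rf$features)[10, ]
  grid <- seq(5, 120, length.out = 100)
  probe <- do.call(rbind, lapply(grid, function(cb) {
    v <- base
    v["carbs_g"] <- cb
    v["glycemic_load"] <- v["glycemic_index"] / 100 * cb
    v["carb_to_protein_ratio"] <- cb / max(v["protein_g"], 1)
    v
  }))
  pred <- predict(rf$model, probe)$pred_delta
  expect_gte(mean(diff(pred) >= -1e-9), 0.95)
})

test_that("corrective updates trigger on drift and improve post-shift error", {
  rf <- recovery_fit()
  m <- rf$model
  # no new rows, or rows the model already explains: version unchanged
  expect_identical(corrective_update(m, feature_matrix(rf$features)[0, ],
                                     numeric()), m)
  within <- corrective_update(m, feature_matrix(rf$features)[1:50, ],
                              rf$targets[1:50])
  expect_equal(within$version, m$version)

  # regime shift: the true carb response doubles (2 -> 4 per GL gram)
  X <- feature_matrix(rf$features)
  shift_targets <- 4 * rf$features$glycemic_load
  upd_idx <- 1:400
  eval_idx <- 401:nrow(X)
  updated <- corrective_update(m, X[upd_idx, ], shift_targets[upd_idx])
  expect_equal(updated$version, m$version + 1L)
  mae_old <- mean(abs(shift_targets[eval_idx] -
                        predict(m, X[eval_idx, ])$pred_delta))
  mae_new <- mean(abs(shift_targets[eval_idx] -
                        predict(updated, X[eval_idx, ])$pred_delta))
  expect_lt(mae_new, mae_old)
})

test_that("the random-forest backend trains and predicts deterministically", {
  sn <- small_noisy()
  folds <- make_folds(sn$keep$timestamp)
  cfg <- model_config(algorithm = "random_forest",
                      n_estimators_grid = 100, max_depth_grid = c(5, 7),
                      seed = 21)
  m1 <- train_ppgr(sn$keep, sn$keep$observed_delta, cfg, folds)
  expect_true(all(is.finite(m1$report$outer_predictions$predicted)))
  expect_lt(m1$report$pooled$rmse, 30)
  m2 <- train_ppgr(sn$keep, sn$keep$observed_delta, cfg, folds)
  expect_identical(m1$report$pooled, m2$report$pooled)
})

test_that("training reports include residual diagnostics", {
  m <- small_model()
  expect_true(is.finite(m$report$residual_normality_p))
  expect_true(is.finite(m$report$residual_lag1_autocorrelation))
  expect_true(abs(m$report$residual_lag1_autocorrelation) <= 1)
})
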