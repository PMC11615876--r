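# Model and CGM performance metrics.

#' Regression error metrics
#'
#' MSE = mean((y - yhat)^2), RMSE = sqrt(MSE), MAE = mean(|y - yhat|),
#' R^2 = 1 - SS_res / SS_tot. When var(y) = 0, R^2 is undefined and reported
#' as NA with an `r_squared_defined = FALSE` flag.
#'
#' @param y Observed values, mg/dL.
#' @param yhat Predicted values, mg/dL.
#' @return A list: mse, rmse, mae, r_squared, r_squared_defined, n.
#' @export
regression_metrics <- function(y, yhat) {
  if (length(y) != length(yhat) || !length(y)) {
    stop_invalid_input("y and yhat must be equal-length, nonempty")
  }
  e <- y - yhat
  mse <- mean(e^2)
  ss_tot <- sum((y - mean(y))^2)
  defined <- ss_tot > 0
  list(mse = mse, rmse = sqrt(mse), mae = mean(abs(e)),
       r_squared = if (defined) 1 - sum(e^2) / ss_tot else NA_real_,
       r_squared_defined = defined, n = length(y))
}

#' Rank-based AUC for spike classification
#'
#' Labels each observation as spike / non-spike by `spike_def` applied to the
#' observed impacts, then computes the area under the ROC curve of the
#' predicted scores via the Mann-Whitney statistic with midranks for ties.
#'
#' @param observed Observed impacts (delta mg/dL, or peaks for the absolute
#'   rule).
#' @param predicted Predicted scores (higher = more likely spike).
#' @param spike_def A [spike_definition()].
#' @return AUC in \[0, 1\].
#' @export
spike_auc <- function(observed, predicted, spike_def = spike_definition()) {
  if (length(observed) != length(predicted)) {
    stop_invalid_input("observed and predicted must have equal length")
  }
  lab <- apply_spike_rule(observed, spike_def)
  n1 <- sum(lab); n0 <- sum(!lab)
  if (n1 == 0 || n0 == 0) {
    glyco_abort("both spike and non-spike classes are required",
                "glycotwin_undefined_auc")
  }
  r <- rank(predicted)  # midranks
  (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Spike definition
#'
#' What counts as a glucose spike: a rise over the adjusted baseline beyond
#' `threshold` (default rule, 40 mg/dL), or an absolute peak above
#' `threshold` ("peak_above_absolute", typically 180 mg/dL).
#'
#' @param rule "delta_above_threshold" or "peak_above_absolute".
#' @param threshold mg/dL (> 0).
#' @export
spike_definition <- function(rule = c("delta_above_threshold",
                                      "peak_above_absolute"),
                             threshold = NULL) {
  rule <- match.arg(rule)
  if (is.null(threshold)) {
    threshold <- if (rule == "delta_above_threshold") 40 else 180
  }
  if (threshold <= 0) stop_invalid_config("spike threshold must be > 0")
  structure(list(rule = rule, threshold = threshold),
            class = "spike_definition")
}

apply_spike_rule <- function(observed, spike_def) {
  observed > spike_def$threshold
}

#' Fraction of predictions within tolerance
#'
#' @param y,yhat Equal-length vectors, mg/dL.
#' @param tol Tolerance, mg/dL.
#' @return Fraction of |y - yhat| <= tol.
#' @export
within_tolerance <- function(y, yhat, tol = 40) {
  if (length(y) != length(yhat) || !length(y)) {
    stop_invalid_input("y and yhat must be equal-length, nonempty")
  }
  mean(abs(y - yhat) <= tol)
}

#' CGM summary metrics
#'
#' Time-in-range (percentage of samples inside \[low, high\], bounds
#' inclusive), glycemic variability (SD of glucose computed per day, then
#' averaged across days), and percentage of time above `high`.
#'
#' @param trace CGM data.table (timestamp, glucose_mgdl).
#' @param low,high Target range bounds, mg/dL.
#' @return A list: tir_pct, sd_daily, pct_above_high.
#' @export
cgm_summary <- function(trace, low = 70, high = 180) {
  if (!nrow(trace)) stop_insufficient_data("empty trace")
  g <- trace$glucose_mgdl
  day <- as.Date(trace$timestamp)
  sds <- tapply(g, day, sd)
  list(tir_pct = 100 * mean(g >= low & g <= high),
       sd_daily = mean(sds, na.rm = TRUE),
       pct_above_high = 100 * mean(g > high))
}

#' Validation report for a trained model on a dataset
#'
#' Computes every metric on pooled outer-fold predictions only (the training
#' report's held-out predictions): regression metrics on peaks, spike AUC,
#' fraction within 40 mg/dL, plus bootstrap confidence intervals
#' (percentile, B resamples of the pooled prediction pairs). The report
#' embeds the seeds and configuration hash and round-trips through JSON.
#'
#' @param model A trained `ppgr_model`.
#' @param features The `glyco_features` table the model was trained on
#'   (non-excluded rows in training order).
#' @param spike_def A [spike_definition()].
#' @param out Optional JSON path.
#' @param B Bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @return A `metrics_report` list.
#' @export
validation_report <- function(model, features, spike_def = spike_definition(),
                              out = NULL, B = 500, seed = 1) {
  op <- model$report$outer_predictions
  ft <- features[excluded == FALSE]
  if (nrow(ft) != nrow(op)) {
    stop_schema("features do not match the model's training rows")
  }
  base <- ft$baseline_adjusted
  obs_peak <- op$observed + base
  pred_peak <- pmax(1, op$predicted + base)
  reg <- regression_metrics(obs_peak, pred_peak)
  auc <- tryCatch(spike_auc(op$observed, op$predicted, spike_def),
                  error = function(e) NA_real_)
  frac40 <- within_tolerance(obs_peak, pred_peak, 40)

  boot <- with_seed(seed, {
    stat <- function(idx) {
      m <- regression_metrics(obs_peak[idx], pred_peak[idx])
      c(rmse = m$rmse, mae = m$mae, r_squared = m$r_squared)
    }
    draws <- vapply(seq_len(B), function(b)
      stat(sample(length(obs_peak), replace = TRUE)), numeric(3))
    apply(draws, 1, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  })
  report <- list(
    n = reg$n,
    metrics = list(mse = reg$mse, rmse = reg$rmse, mae = reg$mae,
                   r_squared = reg$r_squared, auc = auc,
                   within_40_pct = 100 * frac40),
    ci95 = list(rmse = unname(boot[, "rmse"]), mae = unname(boot[, "mae"]),
                r_squared = unname(boot[, "r_squared"])),
    per_fold = lapply(model$report$folds, function(f)
      f[c("fold", "n_train", "n_val", "mse", "rmse", "mae", "r_squared")]),
    spike_rule = unclass(spike_def),
    bootstrap_B = B,
    seed = seed,
    model_seed = model$config$seed,
    config_hash = rlang::hash(model$config),
    residual_normality_p = model$report$residual_normality_p,
    residual_lag1_autocorrelation = model$report$residual_lag1_autocorrelation
  )
  class(report) <- c("metrics_report", "list")
  if (!is.null(out)) {
    jsonlite::write_json(unclass(report), out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  report
}
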