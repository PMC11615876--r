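# The Glucose Impact predictor: a gradient-boosted (or random forest) tree
# ensemble over the 37 static features plus engineered temporal-lag features,
# trained with temporal-gap k-fold cross-validation and nested hyperparameter
# selection. The default target is the delta (glucoseMax minus the
# medication-adjusted baseline); the peak is reconstructed by adding the
# baseline back.

#' Model configuration
#'
#' Grids default to a small capped subset of the supported ranges
#' (gradient boosting: depth 3-5, learning rate 0.01-0.1, up to 500 rounds
#' with early stopping; random forest: 100-300 trees, depth 3-7,
#' min_samples_split 2, sqrt feature subsampling) so a desk-scale nested CV
#' stays fast; pass fuller grids explicitly when exploring.
#'
#' @param algorithm "gradient_boosting" or "random_forest".
#' @param learning_rate_grid,max_depth_grid,n_estimators_grid Hyperparameter
#'   grids searched on the inner folds.
#' @param subsample Row subsampling per boosting round.
#' @param l2_lambda L2 regularization weight.
#' @param early_stopping Early-stopping patience, boosting rounds.
#' @param nrounds_max Ceiling on boosting rounds.
#' @param min_samples_split Minimum samples to split a node (random forest).
#' @param temporal_encoder "lag_features" (default): the trailing-glucose
#'   lag/trend features in the registry carry the temporal state consumed by
#'   the trees.
#' @param inner_frac Fraction of each training block held out (time-ordered,
#'   most recent) for inner tuning and early stopping.
#' @param seed Integer seed.
#' @return A `model_config` list.
#' @export
model_config <- function(algorithm = c("gradient_boosting", "random_forest"),
                         learning_rate_grid = c(0.05, 0.1),
                         max_depth_grid = c(3, 5),
                         n_estimators_grid = c(100, 300),
                         subsample = 0.8, l2_lambda = 1,
                         early_stopping = 25, nrounds_max = 400,
                         min_samples_split = 2,
                         temporal_encoder = "lag_features",
                         inner_frac = 0.2, seed = 1) {
  algorithm <- match.arg(algorithm)
  cfg <- list(algorithm = algorithm,
              learning_rate_grid = learning_rate_grid,
              max_depth_grid = max_depth_grid,
              n_estimators_grid = n_estimators_grid,
              subsample = subsample, l2_lambda = l2_lambda,
              early_stopping = early_stopping, nrounds_max = nrounds_max,
              min_samples_split = min_samples_split,
              temporal_encoder = temporal_encoder,
              inner_frac = inner_frac, seed = as.integer(seed))
  if (!length(cfg$learning_rate_grid) || !length(cfg$max_depth_grid) ||
      !length(cfg$n_estimators_grid)) {
    stop_invalid_config("hyperparameter grids must be nonempty")
  }
  class(cfg) <- "model_config"
  cfg
}

#' Temporal-gap k-fold assignment
#'
#' Splits rows into k contiguous-in-time validation blocks (equal row
#' counts). For each fold, training rows are all rows at least `gap_days`
#' away from every validation row of that fold; rows inside the gap are
#' dropped from that fold's training set. Every row is validated exactly
#' once.
#'
#' @param times POSIXct vector, one per row.
#' @param k Number of folds.
#' @param gap_days Minimum train-validation distance, days.
#' @return A `glyco_folds` list: fold (integer per row), train_idx (list of
#'   training row indices per fold), val_idx, k, gap_days, times.
#' @export
make_folds <- function(times, k = 5, gap_days = 14) {
  n <- length(times)
  if (n < k) stop_invalid_input("fewer rows than folds")
  r <- rank(times, ties.method = "first")
  fold <- ceiling(r * k / n)
  gap <- gap_days * 86400
  val_idx <- lapply(seq_len(k), function(f) which(fold == f))
  train_idx <- lapply(seq_len(k), function(f) {
    lo <- min(times[val_idx[[f]]]); hi <- max(times[val_idx[[f]]])
    which(times <= lo - gap | times >= hi + gap)
  })
  empty <- vapply(train_idx, length, integer(1)) == 0
  if (any(empty)) {
    glyco_abort(sprintf(
      "study span too short for k=%d with a %g-day gap (fold %s has no training rows)",
      k, gap_days, paste(which(empty), collapse = ",")),
      "glycotwin_infeasible_folds")
  }
  out <- list(fold = fold, train_idx = train_idx, val_idx = val_idx,
              k = k, gap_days = gap_days, times = times)
  class(out) <- "glyco_folds"
  out
}

# one backend fit; returns list(predict_fn, best_iter)
fit_backend <- function(X, y, Xval, yval, combo, config, fixed_rounds = NULL) {
  if (config$algorithm == "gradient_boosting") {
    dtrain <- xgboost::xgb.DMatrix(X, label = y)
    evals <- list(train = dtrain)
    use_es <- is.null(fixed_rounds) && !is.null(Xval)
    if (use_es) {
      evals <- list(valid = xgboost::xgb.DMatrix(Xval, label = yval))
    }
    params <- list(objective = "reg:squarederror", eta = combo$learning_rate,
                   max_depth = combo$max_depth, lambda = config$l2_lambda,
                   subsample = config$subsample, nthread = 1,
                   seed = config$seed)
    fit <- xgboost::xgb.train(
      params = params, data = dtrain,
      nrounds = fixed_rounds %||% config$nrounds_max,
      evals = evals, verbose = 0,
      early_stopping_rounds = if (use_es) config$early_stopping else NULL)
    best0 <- suppressWarnings(
      as.integer(xgboost::xgb.attr(fit, "best_iteration")))
    best <- if (is.null(fixed_rounds) && length(best0) && !is.na(best0))
      best0 + 1L else fixed_rounds %||% config$nrounds_max
    predict_fn <- function(newX) {
      predict(fit, xgboost::xgb.DMatrix(newX), iterationrange = c(1, best))
    }
    list(predict_fn = predict_fn, fit = fit, best_iter = best,
         val_rmse = if (!is.null(Xval))
           sqrt(mean((yval - predict_fn(Xval))^2)) else NA_real_)
  } else {
    df <- as.data.frame(X)
    fit <- ranger::ranger(
      x = df, y = y, num.trees = combo$n_estimators,
      max.depth = combo$max_depth, mtry = floor(sqrt(ncol(X))),
      min.node.size = config$min_samples_split, seed = config$seed,
      num.threads = 1)
    list(predict_fn = function(newX)
           predict(fit, data = as.data.frame(newX))$predictions,
         fit = fit, best_iter = combo$n_estimators,
         val_rmse = if (!is.null(Xval))
           sqrt(mean((yval - predict(fit, data = as.data.frame(Xval))$predictions)^2))
         else NA_real_)
  }
}

grid_combos <- function(config) {
  if (config$algorithm == "gradient_boosting") {
    expand.grid(learning_rate = config$learning_rate_grid,
                max_depth = config$max_depth_grid)
  } else {
    expand.grid(n_estimators = config$n_estimators_grid,
                max_depth = config$max_depth_grid)
  }
}

# time-ordered inner split of a training block: most recent inner_frac held out
inner_split <- function(idx, times, frac) {
  o <- idx[order(times[idx])]
  n_val <- max(1L, floor(length(o) * frac))
  list(train = head(o, length(o) - n_val), val = tail(o, n_val))
}

#' Train the PPGR predictor with nested temporal-gap cross-validation
#'
#' For each outer fold, hyperparameters are chosen on an inner time-ordered
#' holdout of that fold's training block only (grid search with early
#' stopping for boosting); outer-fold predictions are produced by a model
#' refit on the whole training block with the chosen combination. The final
#' model is refit on all rows with the modal chosen combination. The training
#' report retains per-fold metrics, pooled outer-fold predictions, and
#' residual diagnostics (normality p-value, lag-1 autocorrelation).
#'
#' @param features `glyco_features` table or numeric matrix with registry
#'   columns (non-excluded rows).
#' @param targets Observed per-meal target (default usage: delta = glucoseMax
#'   minus adjusted baseline), mg/dL.
#' @param config A [model_config()].
#' @param folds A [make_folds()] over the same rows.
#' @return A `ppgr_model`.
#' @export
train_ppgr <- function(features, targets, config = model_config(),
                       folds = NULL) {
  reg <- feature_registry()
  X <- if (is.matrix(features)) features else feature_matrix(features, reg)
  if (!identical(colnames(X), reg$name)) {
    stop_schema("feature columns do not match the registry")
  }
  n <- nrow(X)
  if (n < 50) stop_invalid_input("training requires >= 50 rows")
  if (length(targets) != n) stop_invalid_input("targets length mismatch")
  if (var(targets) == 0) {
    glyco_abort("targets have zero variance", "glycotwin_degenerate_target")
  }
  if (is.null(folds)) {
    times <- if (!is.matrix(features)) features[excluded == FALSE]$timestamp
    else stop_invalid_input("folds must be supplied with a matrix input")
    folds <- make_folds(times, 5, 14)
  }
  combos <- grid_combos(config)
  times <- folds$times

  fold_reports <- list()
  outer_pred <- rep(NA_real_, n)
  for (f in seq_len(folds$k)) {
    tr <- folds$train_idx[[f]]
    va <- folds$val_idx[[f]]
    sp <- inner_split(tr, times, config$inner_frac)
    inner_fits <- lapply(seq_len(nrow(combos)), function(ci) {
      f <- fit_backend(X[sp$train, , drop = FALSE], targets[sp$train],
                       X[sp$val, , drop = FALSE], targets[sp$val],
                       combos[ci, , drop = FALSE], config)
      list(val_rmse = f$val_rmse, best_iter = f$best_iter)
    })
    inner_rmse <- vapply(inner_fits, `[[`, numeric(1), "val_rmse")
    best_ci <- which.min(inner_rmse)
    # refit on the whole training block with the round count selected by
    # inner early stopping; the inner holdout is used for selection only
    refit <- fit_backend(X[tr, , drop = FALSE], targets[tr], NULL, NULL,
                         combos[best_ci, , drop = FALSE], config,
                         fixed_rounds = inner_fits[[best_ci]]$best_iter)
    outer_pred[va] <- refit$predict_fn(X[va, , drop = FALSE])
    fold_reports[[f]] <- c(
      list(fold = f, n_train = length(tr), n_val = length(va),
           inner_rmse = min(inner_rmse), combo = best_ci),
      as.list(combos[best_ci, , drop = FALSE]),
      regression_metrics(targets[va], outer_pred[va]))
  }
  chosen_counts <- table(vapply(fold_reports, `[[`, numeric(1), "combo"))
  final_ci <- as.integer(names(chosen_counts)[which.max(chosen_counts)])
  # round count for the final model: early stopping on the most recent 10%
  # (time-ordered), then refit on all rows at that count
  sp_all <- inner_split(seq_len(n), times, 0.1)
  probe <- fit_backend(X[sp_all$train, , drop = FALSE], targets[sp_all$train],
                       X[sp_all$val, , drop = FALSE], targets[sp_all$val],
                       combos[final_ci, , drop = FALSE], config)
  final <- fit_backend(X, targets, NULL, NULL,
                       combos[final_ci, , drop = FALSE], config,
                       fixed_rounds = probe$best_iter)

  resid <- targets - outer_pred
  ord <- order(times)
  r_ord <- resid[ord]
  shap_n <- min(length(resid), 5000)
  shap_idx <- unique(round(seq(1, length(resid), length.out = shap_n)))
  shap_p <- tryCatch(
    stats::shapiro.test(resid[shap_idx])$p.value,
    error = function(e) NA_real_)
  lag1 <- if (n > 2) cor(r_ord[-1], r_ord[-length(r_ord)]) else NA_real_

  report <- list(
    folds = fold_reports,
    pooled = regression_metrics(targets[!is.na(outer_pred)],
                                outer_pred[!is.na(outer_pred)]),
    outer_predictions = data.table(row = seq_len(n), fold = folds$fold,
                                   observed = targets, predicted = outer_pred),
    chosen_combo = as.list(combos[final_ci, , drop = FALSE]),
    residual_normality_p = shap_p,
    residual_lag1_autocorrelation = lag1,
    seed = config$seed
  )
  model <- list(fit = final$fit, predict_fn = final$predict_fn,
                algorithm = config$algorithm,
                params = as.list(combos[final_ci, , drop = FALSE]),
                best_iter = final$best_iter,
                config = config, registry_hash = registry_hash(reg),
                registry_names = reg$name,
                train_X = X, train_y = targets, train_times = times,
                version = 1L, report = report)
  class(model) <- "ppgr_model"
  model
}

#' @export
print.ppgr_model <- function(x, ...) {
  cat(sprintf("<ppgr_model v%d> %s, %d training rows\n", x$version,
              x$algorithm, nrow(x$train_X)))
  p <- x$report$pooled
  cat(sprintf("  outer-fold pooled: RMSE %.2f  MAE %.2f  R2 %.3f\n",
              p$rmse, p$mae, p$r_squared))
  invisible(x)
}

check_registry <- function(model, X) {
  if (!identical(colnames(X), model$registry_names)) {
    stop_schema("feature columns do not match the model's registry")
  }
}

#' Predict PPGR for new feature rows
#'
#' @param object A `ppgr_model`.
#' @param features `glyco_features` table or registry-column matrix.
#' @param ... Unused.
#' @return A data.table: pred_delta (mg/dL over adjusted baseline) and
#'   pred_peak (mg/dL, reconstructed by adding the row's adjusted baseline,
#'   floored at 1), plus model_version.
#' @export
predict.ppgr_model <- function(object, features, ...) {
  reg_names <- object$registry_names
  X <- if (is.matrix(features)) features else {
    ft <- features[excluded == FALSE]
    as.matrix(ft[, reg_names, with = FALSE])
  }
  check_registry(object, X)
  delta <- object$predict_fn(X)
  data.table(pred_delta = delta,
             pred_peak = pmax(1, delta + X[, "baseline_adjusted"]),
             model_version = object$version)
}

#' Corrective update on feedback data
#'
#' Compares observed to predicted excursions on newly logged meals; when the
#' mean observed-minus-predicted excess exceeds the policy threshold, the
#' model is retrained on the union of the original and new rows under the
#' same configuration and chosen hyperparameters, and the version increments.
#' Otherwise the model is returned unchanged.
#'
#' @param model A `ppgr_model`.
#' @param new_features Registry-column matrix or `glyco_features` rows.
#' @param new_targets Observed targets for the new rows.
#' @param policy List: threshold (mg/dL mean excess, default 15).
#' @return A `ppgr_model` (possibly the input, unchanged).
#' @export
corrective_update <- function(model, new_features, new_targets,
                              policy = list(threshold = 15)) {
  X <- if (is.matrix(new_features)) new_features else {
    ft <- new_features[excluded == FALSE]
    as.matrix(ft[, model$registry_names, with = FALSE])
  }
  if (nrow(X) == 0) return(model)
  check_registry(model, X)
  pred <- model$predict_fn(X)
  excess <- mean(new_targets - pred)
  if (excess <= policy$threshold) return(model)
  X_all <- rbind(model$train_X, X)
  y_all <- c(model$train_y, new_targets)
  n_val <- max(1L, floor(nrow(X_all) * 0.1))
  ord <- seq_len(nrow(X_all))  # new rows are appended, i.e. most recent
  tr <- head(ord, length(ord) - n_val); va <- tail(ord, n_val)
  refit <- fit_backend(X_all[tr, , drop = FALSE], y_all[tr],
                       X_all[va, , drop = FALSE], y_all[va],
                       as.data.frame(model$params), model$config)
  model$fit <- refit$fit
  model$predict_fn <- refit$predict_fn
  model$best_iter <- refit$best_iter
  model$train_X <- X_all
  model$train_y <- y_all
  model$version <- model$version + 1L
  model
}
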