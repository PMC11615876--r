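# Multiple imputation by chained equations with Rubin pooling.
#
# Continuous variables are imputed by Bayesian linear regression (draw the
# residual variance from its scaled inverse-chi-square posterior, the
# coefficients from their normal posterior, then add residual noise), which
# propagates parameter uncertainty into the between-imputation variance —
# the property Rubin's rules rely on. Categorical variables use multinomial
# logistic regression with a draw from the fitted class probabilities.
# Alternatives: predictive mean matching (pmm) and a random-forest imputer.

# one Bayesian-linear-regression imputation draw for a continuous variable
draw_norm <- function(y_obs, X_obs, X_mis) {
  fit <- stats::lm.fit(X_obs, y_obs)
  ok <- !is.na(fit$coefficients)
  Xo <- X_obs[, ok, drop = FALSE]
  Xm <- X_mis[, ok, drop = FALSE]
  beta_hat <- fit$coefficients[ok]
  n <- length(y_obs); p <- ncol(Xo)
  df <- max(n - p, 1)
  sigma2 <- sum(fit$residuals^2) / stats::rchisq(1, df)
  XtX_inv <- tryCatch(chol2inv(chol(crossprod(Xo))), error = function(e) NULL)
  if (is.null(XtX_inv)) {
    beta <- beta_hat
  } else {
    beta <- beta_hat + drop(chol(XtX_inv * sigma2) %*% rnorm(p))
  }
  drop(Xm %*% beta) + rnorm(nrow(Xm), 0, sqrt(sigma2))
}

# predictive mean matching: impute by borrowing observed donors whose
# predicted mean is closest to the missing row's predicted mean
draw_pmm <- function(y_obs, X_obs, X_mis, donors = 5) {
  fit <- stats::lm.fit(X_obs, y_obs)
  ok <- !is.na(fit$coefficients)
  pred_obs <- drop(X_obs[, ok, drop = FALSE] %*% fit$coefficients[ok])
  pred_mis <- drop(X_mis[, ok, drop = FALSE] %*% fit$coefficients[ok])
  vapply(pred_mis, function(pm) {
    idx <- order(abs(pred_obs - pm))[seq_len(min(donors, length(pred_obs)))]
    y_obs[idx[sample(length(idx), 1)]]
  }, numeric(1))
}

draw_polyreg <- function(y_obs, df_obs, df_mis) {
  fit <- suppressWarnings(nnet::multinom(y ~ ., data = cbind(y = y_obs, df_obs),
                                         trace = FALSE, maxit = 200))
  pr <- predict(fit, newdata = df_mis, type = "probs")
  lev <- levels(y_obs)
  if (is.null(dim(pr))) {  # two-level outcome: probs of second level
    pr <- cbind(1 - pr, pr)
  }
  factor(apply(pr, 1, function(p) sample(lev, 1, prob = p)), levels = lev)
}

draw_rf <- function(y_obs, df_obs, df_mis) {
  fit <- randomForest::randomForest(x = df_obs, y = y_obs, ntree = 50)
  if (is.factor(y_obs)) {
    pr <- predict(fit, df_mis, type = "prob")
    lev <- colnames(pr)
    factor(apply(pr, 1, function(p) sample(lev, 1, prob = p)),
           levels = levels(y_obs))
  } else {
    res_sd <- sd(y_obs - predict(fit, df_obs))
    predict(fit, df_mis) + rnorm(nrow(df_mis), 0, res_sd)
  }
}

#' Multiple imputation by chained equations
#'
#' Produces `m` completed copies of `table`. Each variable with missing cells
#' is visited in turn and re-imputed from a regression on all other
#' variables, cycling `max_iter` times per imputation; observed cells are
#' never altered.
#'
#' @param table A data.frame with numeric and/or factor columns; at least one
#'   variable must be fully observed and no variable may be 50% or more
#'   missing.
#' @param m Number of imputed datasets.
#' @param seed Integer seed; fully determines the result.
#' @param method_map Optional named character vector mapping column names to
#'   "norm", "pmm", "polyreg" or "rf"; defaults are "norm" for continuous and
#'   "polyreg" for factors.
#' @param max_iter Chained-equation cycles per imputation.
#' @return An `imputation_result` list: m, datasets (list of completed
#'   data.frames), methods.
#' @export
mice_impute <- function(table, m = 5, seed = 1, method_map = NULL,
                        max_iter = 10) {
  table <- as.data.frame(table)
  if (m < 2) stop_invalid_input("m must be >= 2")
  chr <- vapply(table, is.character, logical(1))
  table[chr] <- lapply(table[chr], factor)
  miss_frac <- vapply(table, function(x) mean(is.na(x)), numeric(1))
  if (any(miss_frac == 1)) {
    glyco_abort(sprintf("variable(s) entirely missing: %s",
                        paste(names(table)[miss_frac == 1], collapse = ", ")),
                "glycotwin_unimputable")
  }
  if (!any(miss_frac == 0)) {
    stop_invalid_input("at least one fully observed variable is required")
  }
  if (any(miss_frac >= 0.5)) {
    stop_invalid_input("missingness must be < 50% per variable")
  }
  vars <- names(table)[miss_frac > 0]
  methods <- setNames(
    ifelse(vapply(table[vars], is.factor, logical(1)), "polyreg", "norm"),
    vars)
  if (!is.null(method_map)) methods[names(method_map)] <- method_map
  if (!length(vars)) {
    out <- list(m = m, datasets = replicate(m, table, simplify = FALSE),
                methods = methods)
    class(out) <- "imputation_result"
    return(out)
  }
  miss_idx <- lapply(table[vars], function(x) which(is.na(x)))

  datasets <- with_seed(seed, {
    lapply(seq_len(m), function(im) {
      cur <- table
      for (v in vars) {  # initialize by sampling observed values
        obs <- cur[[v]][!is.na(cur[[v]])]
        cur[[v]][miss_idx[[v]]] <- sample(obs, length(miss_idx[[v]]),
                                          replace = TRUE)
      }
      for (iter in seq_len(max_iter)) {
        for (v in vars) {
          mi <- miss_idx[[v]]
          others <- setdiff(names(cur), v)
          rhs <- cur[others]
          y_full <- table[[v]]
          if (methods[[v]] %in% c("norm", "pmm")) {
            X <- stats::model.matrix(~ ., data = rhs)
            cur[[v]][mi] <- if (methods[[v]] == "norm") {
              draw_norm(y_full[-mi], X[-mi, , drop = FALSE],
                        X[mi, , drop = FALSE])
            } else {
              draw_pmm(y_full[-mi], X[-mi, , drop = FALSE],
                       X[mi, , drop = FALSE])
            }
          } else if (methods[[v]] == "polyreg") {
            cur[[v]][mi] <- as.character(
              draw_polyreg(y_full[-mi], rhs[-mi, , drop = FALSE],
                           rhs[mi, , drop = FALSE]))
          } else if (methods[[v]] == "rf") {
            drawn <- draw_rf(y_full[-mi], rhs[-mi, , drop = FALSE],
                             rhs[mi, , drop = FALSE])
            cur[[v]][mi] <- if (is.factor(drawn)) as.character(drawn) else drawn
          } else {
            stop_invalid_config(sprintf("unknown method '%s'", methods[[v]]))
          }
        }
      }
      cur
    })
  })
  out <- list(m = m, datasets = datasets, methods = methods)
  class(out) <- "imputation_result"
  out
}

#' Pool estimates across imputed datasets by Rubin's rules
#'
#' The pooled estimate is the mean of the per-imputation estimates; total
#' variance is the mean within-imputation variance plus (1 + 1/m) times the
#' between-imputation variance of the estimates.
#'
#' @param estimates Numeric vector, one estimate per imputed dataset.
#' @param variances Numeric vector of their within-imputation variances.
#' @return A list: estimate, variance, df (classic Rubin degrees of freedom;
#'   Inf when the imputations agree exactly), and a 95% CI.
#' @export
rubin_pool <- function(estimates, variances) {
  if (length(estimates) != length(variances)) {
    stop_invalid_input("estimates and variances must have the same length")
  }
  m <- length(estimates)
  if (m < 2) stop_invalid_input("pooling requires m >= 2 estimates")
  qbar <- mean(estimates)
  wbar <- mean(variances)
  b <- var(estimates)
  total <- wbar + (1 + 1 / m) * b
  df <- if (b == 0) Inf else (m - 1) * (1 + wbar / ((1 + 1 / m) * b))^2
  half <- qt(0.975, df = df) * sqrt(total)
  list(estimate = qbar, variance = total, df = df,
       ci = c(qbar - half, qbar + half),
       within = wbar, between = b)
}

#' Compare an outcome across missing-data strategies
#'
#' Computes `outcome_fn` under complete-case analysis and under multiple
#' imputation with each requested method (chained-equation Bayesian
#' regression, predictive mean matching, random forest), and flags methods
#' whose outcome deviates from the chained-equation reference by more than
#' `rel_tol` in relative terms.
#'
#' @param table Data.frame with missing cells.
#' @param outcome_fn Function mapping a completed data.frame to a scalar.
#' @param methods Character subset of c("complete_case", "mice", "pmm", "rf").
#' @param rel_tol Relative deviation beyond which a method is flagged.
#' @param m,seed Passed to [mice_impute()].
#' @return A data.table: method, outcome, rel_dev, flagged.
#' @export
sensitivity_suite <- function(table, outcome_fn,
                              methods = c("complete_case", "mice", "pmm", "rf"),
                              rel_tol = 0.1, m = 5, seed = 1) {
  table <- as.data.frame(table)
  num_cols <- names(table)[vapply(table, is.numeric, logical(1))]
  run_mi <- function(mm) {
    imp <- mice_impute(table, m = m, seed = seed, method_map = mm)
    mean(vapply(imp$datasets, outcome_fn, numeric(1)))
  }
  res <- lapply(methods, function(meth) {
    val <- switch(meth,
      complete_case = outcome_fn(table[complete.cases(table), , drop = FALSE]),
      mice = run_mi(NULL),
      pmm = run_mi(setNames(rep("pmm", length(num_cols)), num_cols)),
      rf = run_mi(setNames(rep("rf", length(names(table))), names(table))),
      stop_invalid_config(sprintf("unknown method '%s'", meth)))
    data.table(method = meth, outcome = val)
  })
  out <- rbindlist(res)
  ref <- if ("mice" %in% out$method) out[method == "mice", outcome] else
    out$outcome[1]
  out[, rel_dev := abs(outcome - ref) / max(abs(ref), .Machine$double.eps)]
  out[, flagged := rel_dev > rel_tol]
  out[]
}
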