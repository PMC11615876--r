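#' @import data.table
#' @importFrom stats rnorm runif median mad sd var quantile lm predict coef
#'   complete.cases setNames qt pnorm approx
#' @importFrom utils head tail
NULL

# condition constructor: all package errors carry a subclass so callers and
# tests can dispatch on the failure mode rather than on message text
glyco_abort <- function(message, class) {
  rlang::abort(message, class = c(class, "glycotwin_error"))
}

stop_invalid_config <- function(msg) glyco_abort(msg, "glycotwin_invalid_config")
stop_invalid_input <- function(msg) glyco_abort(msg, "glycotwin_invalid_input")
stop_invalid_meal <- function(msg) glyco_abort(msg, "glycotwin_invalid_meal")
stop_insufficient_data <- function(msg) glyco_abort(msg, "glycotwin_insufficient_data")
stop_schema <- function(msg) glyco_abort(msg, "glycotwin_schema_error")

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# truncated-normal draw by resampling; fine for the mild truncations used here
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

as_utc <- function(x) as.POSIXct(x, tz = "UTC")

#' Arithmetic mean of per-tree predictions
#'
#' The ensemble prediction of a random forest (and, at fixed weighting, of any
#' bagged tree collection) is the unweighted average of its member trees'
#' predictions.
#'
#' @param tree_predictions Numeric vector, one prediction per tree.
#' @return A single numeric, the ensemble prediction.
#' @export
ensemble_average <- function(tree_predictions) {
  if (length(tree_predictions) == 0) {
    stop_invalid_input("at least one tree prediction is required")
  }
  if (!is.numeric(tree_predictions)) {
    stop_invalid_input("tree predictions must be numeric")
  }
  mean(tree_predictions)
}
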