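# Multi-objective dietary recommendation: argmin over candidate foods of
#   predicted PPGR + lambda1 * nutrient variability + lambda2 * preference
# with hard dietary exclusions applied as pre-filters (never as penalties),
# and traffic-light (GFY/OFY/RFY) classification against a per-patient
# Nutrition Rules Table.

#' Recommendation configuration
#'
#' `lambda1` weights nutrient variability (Euclidean distance in macro
#' calorie-proportion space, range ~0-1.4) and `lambda2` weights the soft
#' preference penalty. The defaults (100 and 10) put both terms on a
#' mg/dL-comparable scale; they are package defaults, not values estimated
#' from data.
#'
#' @param lambda1,lambda2 Non-negative regularization weights.
#' @param top_k Number of foods returned.
#' @export
recommendation_config <- function(lambda1 = 100, lambda2 = 10, top_k = 10) {
  if (lambda1 < 0 || lambda2 < 0) {
    stop_invalid_config("lambda1 and lambda2 must be >= 0")
  }
  structure(list(lambda1 = lambda1, lambda2 = lambda2, top_k = top_k),
            class = "recommendation_config")
}

#' Preference profile
#'
#' @param excluded_tags Tags that hard-exclude a food (e.g. "contains_nut"
#'   for a nut allergy).
#' @param required_tags Tags a food must carry (e.g. "vegetarian").
#' @param dislikes Named non-negative weights; names match food_ids or tags.
#' @param targets Target macro calorie proportions, named c(carbs, protein,
#'   fat), summing to 1.
#' @export
preference_profile <- function(excluded_tags = character(),
                               required_tags = character(),
                               dislikes = numeric(),
                               targets = c(carbs = 0.5, protein = 0.2,
                                           fat = 0.3)) {
  if (any(dislikes < 0)) stop_invalid_config("dislike weights must be >= 0")
  structure(list(excluded_tags = excluded_tags,
                 required_tags = required_tags,
                 dislikes = dislikes, targets = targets),
            class = "preference_profile")
}

food_tags <- function(food) {
  tags <- food$tags
  if (is.null(tags) || is.na(tags) || !nzchar(tags)) character() else
    strsplit(tags, ";", fixed = TRUE)[[1]]
}

#' Macro-proportion distance from the nutrient-density target
#'
#' Converts the candidate's macronutrients to calorie shares (4/4/9 kcal per
#' gram of carbohydrate/protein/fat) and returns the Euclidean distance to
#' the target proportions; 0 iff the proportions match.
#'
#' @param food One food row (carbs_g, protein_g, fat_g).
#' @param targets Target proportions, named c(carbs, protein, fat).
#' @return Non-negative scalar.
#' @export
nutrient_variability <- function(food, targets = c(carbs = 0.5, protein = 0.2,
                                                   fat = 0.3)) {
  food <- as.list(food)
  if (any(unlist(food[c("carbs_g", "protein_g", "fat_g")]) < 0)) {
    stop_invalid_input("nutrients must be >= 0")
  }
  kcal <- c(carbs = 4 * food$carbs_g, protein = 4 * food$protein_g,
            fat = 9 * food$fat_g)
  total <- sum(kcal)
  if (total <= 0) {
    glyco_abort("macro proportions are undefined for a zero-calorie item",
                "glycotwin_undefined_proportions")
  }
  sqrt(sum((kcal / total - targets[names(kcal)])^2))
}

#' Soft preference penalty (or hard exclusion)
#'
#' Returns `Inf` for hard-excluded foods (an excluded tag present, or a
#' required tag absent) — such foods are removed before scoring, never merely
#' penalized. Otherwise returns the sum of matching dislike weights.
#'
#' @param food One food row.
#' @param profile A [preference_profile()].
#' @return Non-negative scalar, or Inf meaning excluded.
#' @export
preference_penalty <- function(food, profile = preference_profile()) {
  food <- as.list(food)
  tags <- food_tags(food)
  if (length(intersect(tags, profile$excluded_tags)) ||
      length(setdiff(profile$required_tags, tags))) {
    return(Inf)
  }
  keys <- c(food$food_id, tags)
  sum(profile$dislikes[intersect(names(profile$dislikes), keys)])
}

#' Multi-objective score of one candidate
#'
#' score = predicted_ppgr + lambda1 * variability + lambda2 * penalty.
#'
#' @param predicted_ppgr Predicted impact, mg/dL.
#' @param variability [nutrient_variability()] of the candidate.
#' @param penalty [preference_penalty()] of the candidate (finite).
#' @param config A [recommendation_config()].
#' @return The score (mg/dL-equivalent).
#' @export
objective_score <- function(predicted_ppgr, variability, penalty,
                            config = recommendation_config()) {
  if (config$lambda1 < 0 || config$lambda2 < 0) {
    stop_invalid_config("lambda1 and lambda2 must be >= 0")
  }
  if (!is.finite(penalty)) {
    stop_invalid_input("hard-excluded foods must be filtered before scoring")
  }
  predicted_ppgr + config$lambda1 * variability + config$lambda2 * penalty
}

#' Nutrition Rules Table
#'
#' Per-patient thresholds on predicted impact: impact <= t_green is GFY
#' ("Green For You"), <= t_orange is OFY, above is RFY.
#'
#' @param t_green,t_orange Thresholds, mg/dL; t_green < t_orange.
#' @param version Integer version.
#' @param provenance "initial" or "feedback-adjusted".
#' @export
nutrition_rules_table <- function(t_green, t_orange, version = 1L,
                                  provenance = "initial") {
  if (!(t_green < t_orange)) {
    glyco_abort("t_green must be < t_orange", "glycotwin_invalid_nrt")
  }
  structure(list(t_green = t_green, t_orange = t_orange,
                 version = as.integer(version), provenance = provenance),
            class = "nutrition_rules_table")
}

#' Initial NRT from a population of predicted impacts
#'
#' Thresholds default to the empirical tertiles of the supplied impacts.
#'
#' @param impacts Predicted impacts, mg/dL.
#' @export
nrt_from_impacts <- function(impacts) {
  q <- quantile(impacts, c(1 / 3, 2 / 3), names = FALSE, type = 7)
  if (q[1] >= q[2]) q[2] <- q[1] + 1e-6
  nutrition_rules_table(q[1], q[2])
}

#' Classify foods into GFY / OFY / RFY
#'
#' @param impacts Predicted impacts per food, mg/dL.
#' @param nrt A [nutrition_rules_table()].
#' @return Character vector in c("GFY", "OFY", "RFY"), one label per food.
#' @export
classify_foods <- function(impacts, nrt) {
  if (!inherits(nrt, "nutrition_rules_table")) {
    glyco_abort("nrt must be a nutrition_rules_table", "glycotwin_invalid_nrt")
  }
  ifelse(impacts <= nrt$t_green, "GFY",
         ifelse(impacts <= nrt$t_orange, "OFY", "RFY"))
}

#' Adjust an NRT from observed responses
#'
#' Re-estimates the thresholds as the empirical tertiles of the patient's
#' trailing observed impacts (default policy); below `min_obs` observations
#' the table is returned unchanged with a warning.
#'
#' @param nrt The current [nutrition_rules_table()].
#' @param observed data.frame with food_id and impact (mg/dL) columns.
#' @param policy List: min_obs (default 10), window (most recent
#'   observations considered, default 90).
#' @return A new (or the unchanged) `nutrition_rules_table`.
#' @export
adjust_nrt <- function(nrt, observed, policy = list(min_obs = 10, window = 90)) {
  if (!all(c("food_id", "impact") %in% names(observed))) {
    stop_invalid_input("observed responses need food_id and impact columns")
  }
  x <- tail(observed$impact, policy$window %||% 90)
  if (length(x) < (policy$min_obs %||% 10)) {
    warning("too few observations to adjust the NRT; returning it unchanged")
    return(nrt)
  }
  q <- quantile(x, c(1 / 3, 2 / 3), names = FALSE, type = 7)
  if (q[1] >= q[2]) q[2] <- q[1] + 1e-6
  nutrition_rules_table(q[1], q[2], version = nrt$version + 1L,
                        provenance = "feedback-adjusted")
}

#' Patient state for recommendation time
#'
#' @param profile One profile row (as in the profiles table).
#' @param context A [temporal_context()].
#' @param baseline Adjusted baseline, mg/dL.
#' @param timestamp POSIXct "now".
#' @param meal_type Meal slot being planned.
#' @param meal_history POSIXct vector of earlier meals.
#' @export
patient_state <- function(profile, context, baseline, timestamp,
                          meal_type = "lunch", meal_history = NULL) {
  structure(list(profile = as.list(profile), context = context,
                 baseline = baseline, timestamp = as_utc(timestamp),
                 meal_type = meal_type, meal_history = meal_history),
            class = "patient_state")
}

# features for "this patient eats this candidate now", one row per candidate
candidate_features <- function(candidates, state,
                               registry = feature_registry(),
                               penalty_table = default_penalty_table()) {
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    fd <- as.list(candidates[i])
    meal <- list(calories = fd$calories, carbs_g = fd$carbs_g,
                 protein_g = fd$protein_g, fat_g = fd$fat_g,
                 fiber_g = fd$fiber_g, glycemic_index = fd$glycemic_index,
                 glycemic_load = fd$glycemic_index / 100 * fd$carbs_g,
                 timestamp = state$timestamp, meal_type = state$meal_type,
                 meal_history = state$meal_history)
    assemble_features(state$profile, meal, state$context, state$baseline,
                      registry, penalty_table,
                      daily_activity = list(
                        steps_day = state$context$steps_trailing,
                        active_minutes_day = 0, sedentary_minutes_day = 0))
  })
  X <- do.call(rbind, rows)
  rownames(X) <- candidates$food_id
  X
}

#' Recommend foods for a patient
#'
#' Hard-excluded candidates are removed; the remainder are scored by the
#' PPGR model plus the multi-objective penalties and returned in ascending
#' score order (ties broken by lower predicted impact, then food_id). The
#' ranking equals exhaustive enumeration of the objective by construction.
#'
#' @param candidates Food table rows (see [default_food_table()]).
#' @param state A [patient_state()].
#' @param model A trained `ppgr_model`.
#' @param config A [recommendation_config()].
#' @param profile A [preference_profile()].
#' @param nrt Optional [nutrition_rules_table()] for GFY/OFY/RFY labels.
#' @return A `recommendation_set` data.table: food_id, name, pred_impact,
#'   variability, penalty, score, label (if nrt given), top_k rows.
#' @export
recommend_foods <- function(candidates, state, model,
                            config = recommendation_config(),
                            profile = preference_profile(), nrt = NULL) {
  pen <- vapply(seq_len(nrow(candidates)), function(i)
    preference_penalty(candidates[i], profile), numeric(1))
  keep <- is.finite(pen)
  if (!any(keep)) {
    glyco_abort("no candidate survives the hard exclusions",
                "glycotwin_empty_candidates")
  }
  cand <- candidates[keep]
  pen <- pen[keep]
  nv <- vapply(seq_len(nrow(cand)), function(i)
    nutrient_variability(cand[i], profile$targets), numeric(1))
  X <- candidate_features(cand, state)
  pred <- predict(model, X)
  score <- vapply(seq_len(nrow(cand)), function(i)
    objective_score(pred$pred_delta[i], nv[i], pen[i], config), numeric(1))
  out <- data.table(food_id = cand$food_id, name = cand$name,
                    pred_impact = pred$pred_delta, variability = nv,
                    penalty = pen, score = score)
  if (!is.null(nrt)) out[, label := classify_foods(pred_impact, nrt)]
  data.table::setorder(out, score, pred_impact, food_id)
  out <- head(out, config$top_k)
  data.table::setattr(out, "model_version", model$version)
  if (!is.null(nrt)) data.table::setattr(out, "nrt_version", nrt$version)
  data.table::setattr(out, "class", c("recommendation_set", class(out)))
  out[]
}
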