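test_that("nutrient variability is the macro-proportion distance", {
  # proportions equal to the target -> 0  (total 400 kcal: 50/20/13.33 g)
  on_target <- list(carbs_g = 50, protein_g = 20, fat_g = 40 / 3)
  expect_equal(nutrient_variability(on_target), 0, tolerance = 1e-12)

  # candidate proportions (0.5, 0.2, 0.3) vs targets (0.5, 0.3, 0.2)
  off <- nutrient_variability(on_target,
                              targets = c(carbs = 0.5, protein = 0.3,
                                          fat = 0.2))
  expect_equal(off, sqrt(0.02))

  zero <- list(carbs_g = 0, protein_g = 0, fat_g = 0)
  expect_error(nutrient_variability(zero),
               class = "glycotwin_undefined_proportions")
})

test_that("preferences hard-exclude or softly penalize", {
  nutty <- list(food_id = "F034", carbs_g = 6, protein_g = 5.5, fat_g = 15,
                tags = "vegetarian;contains_nut")
  prof <- preference_profile(excluded_tags = "contains_nut")
  expect_identical(preference_penalty(nutty, prof), Inf)

  expect_equal(preference_penalty(nutty, preference_profile()), 0)
  disl <- preference_profile(dislikes = c(F034 = 3))
  expect_equal(preference_penalty(nutty, disl), 3)

  # a required tag that is absent also excludes
  meat <- list(food_id = "F027", tags = "")
  veg <- preference_profile(required_tags = "vegetarian")
  expect_identical(preference_penalty(meat, veg), Inf)
})

test_that("objective score composes its three terms linearly", {
  cfg0 <- recommendation_config(lambda1 = 0, lambda2 = 0)
  expect_equal(objective_score(33, 5, 2, cfg0), 33)
  expect_equal(objective_score(33, 5, 0, recommendation_config(2, 0)), 43)
  expect_error(recommendation_config(lambda1 = -1),
               class = "glycotwin_invalid_config")
  expect_error(objective_score(33, 5, Inf), class = "glycotwin_invalid_input")
})

test_that("traffic-light classification partitions foods monotonically", {
  nrt <- nutrition_rules_table(30, 60)
  expect_identical(classify_foods(c(10, 40, 90), nrt),
                   c("GFY", "OFY", "RFY"))
  expect_identical(classify_foods(rep(25, 4), nrt), rep("GFY", 4))
  # partition: every impact gets exactly one label, monotone in impact
  x <- sort(runif(50, 0, 100))
  lab <- classify_foods(x, nrt)
  expect_true(all(lab %in% c("GFY", "OFY", "RFY")))
  expect_true(all(diff(match(lab, c("GFY", "OFY", "RFY"))) >= 0))
  expect_error(nutrition_rules_table(60, 30), class = "glycotwin_invalid_nrt")
})

test_that("NRT feedback adjustment re-estimates tertile thresholds", {
  nrt <- nutrition_rules_table(30, 60)
  obs <- data.frame(food_id = letters[1:6], impact = c(10, 20, 30, 40, 50, 60))
  # hand tertiles of {10..60}: 26.67 and 43.33 (type-7 quantiles)
  adj <- adjust_nrt(nrt, obs, policy = list(min_obs = 5, window = 90))
  expect_equal(adj$t_green, 80 / 3, tolerance = 1e-9)
  expect_equal(adj$t_orange, 130 / 3, tolerance = 1e-9)
  expect_equal(adj$version, 2L)
  expect_equal(adj$provenance, "feedback-adjusted")

  expect_warning(keep <- adjust_nrt(nrt, obs[1:3, ]), regexp = "too few")
  expect_identical(keep, nrt)

  # shrinking impacts shrink the thresholds: small-impact foods turn GFY
  tiny <- data.frame(food_id = letters[1:12],
                     impact = seq(2, 8, length.out = 12))
  adj2 <- adjust_nrt(nrt, tiny)
  expect_lt(adj2$t_orange, nrt$t_orange)
  expect_identical(classify_foods(7.9, adj2) %in% c("OFY", "RFY"), TRUE)
  expect_identical(classify_foods(3, adj2), "GFY")
})

make_state <- function() {
  sn <- small_noisy()
  pid <- sn$ds$profiles$patient_id[1]
  now <- sn$keep[patient_id == pid][.N]
  ctx <- temporal_context(sn$ds$cgm[patient_id == pid],
                          sn$ds$activity[patient_id == pid],
                          sn$ds$sleep[patient_id == pid], now$timestamp)
  patient_state(sn$ds$profiles[patient_id == pid], ctx,
                now$baseline_adjusted, now$timestamp)
}

test_that("recommendation equals exhaustive enumeration of the objective", {
  model <- small_model()
  state <- make_state()
  foods <- default_food_table()
  set.seed(14)
  cand <- foods[sample(nrow(foods), 50, replace = TRUE)]
  cand[, food_id := sprintf("C%03d", .I)]  # distinct ids for tie-breaking
  cfg <- recommendation_config(lambda1 = runif(1, 0, 200),
                               lambda2 = runif(1, 0, 20),
                               top_k = nrow(cand))
  prof <- preference_profile(dislikes = c(contains_gluten = 2))
  rec <- recommend_foods(cand, state, model, cfg, prof)

  # brute force: score every surviving candidate independently
  pen <- vapply(seq_len(nrow(cand)), function(i)
    preference_penalty(cand[i], prof), numeric(1))
  keep <- which(is.finite(pen))
  brute <- data.table::rbindlist(lapply(keep, function(i) {
    nv <- nutrient_variability(cand[i], prof$targets)
    pp <- predict(model, glycotwin:::candidate_features(cand[i], state))$pred_delta
    data.table::data.table(food_id = cand$food_id[i],
                           score = objective_score(pp, nv, pen[i], cfg),
                           pred = pp)
  }))
  data.table::setorder(brute, score, pred, food_id)
  expect_identical(rec$food_id, brute$food_id)
  expect_equal(rec$score, brute$score)
})

test_that("argmin selection respects exclusions and ties", {
  model <- small_model()
  state <- make_state()
  foods <- default_food_table()
  cfg <- recommendation_config(lambda1 = 0, lambda2 = 0, top_k = 3)
  rec <- recommend_foods(foods, state, model, cfg)
  # with zero penalties the ranking is ascending predicted impact
  expect_true(all(diff(rec$pred_impact) >= 0))
  best <- rec$food_id[1]

  # hard-excluding the winner promotes the runner-up
  prof <- preference_profile(excluded_tags = strsplit(
    foods[food_id == best, tags], ";")[[1]][1])
  if (!is.na(foods[food_id == best, tags]) &&
      nzchar(foods[food_id == best, tags])) {
    rec2 <- recommend_foods(foods, state, model, cfg, prof)
    expect_false(best %in% rec2$food_id)
  }

  all_out <- preference_profile(required_tags = "no_such_tag")
  expect_error(recommend_foods(foods, state, model, cfg, all_out),
               class = "glycotwin_empty_candidates")
})

test_that("a GFY-only diet lowers simulated glucose peaks versus random", {
  model <- small_model()
  state <- make_state()
  sn <- small_noisy()
  foods <- default_food_table()
  pid <- state$profile$patient_id
  patient <- as.list(sn$ds$cohort[patient_id == pid])

  pred <- predict(model, glycotwin:::candidate_features(foods, state))$pred_delta
  nrt <- nrt_from_impacts(pred)
  labels <- classify_foods(pred, nrt)
  gfy <- which(labels == "GFY")
  expect_gte(length(gfy), 3)

  true_rise_of <- function(idx) {
    vapply(idx, function(i) {
      attr(simulate_meal_response(patient, as.list(foods[i]),
                                  list(steps_2h = 800, sleep_deficit_h = 0.3),
                                  noise_sd_override = 0), "true_rise")
    }, numeric(1))
  }
  set.seed(30)
  gfy_meals <- sample(gfy, 90, replace = TRUE)       # 30 days x 3 meals
  random_meals <- sample(nrow(foods), 90, replace = TRUE)
  expect_lt(mean(true_rise_of(gfy_meals)), mean(true_rise_of(random_meals)))
})
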