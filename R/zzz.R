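# silence NSE notes from data.table column references
utils::globalVariables(c(
  ".", ".N", ".SD", "..keep", "active_minutes", "active_minutes_day",
  "baseline_adjusted", "bmi", "carb_sensitivity", "carb_to_protein_ratio",
  "carbs_g", "circadian_amplitude", "date", "efficiency", "excluded",
  "exclude_reason", "fiber_damping", "first_meal", "food_id", "glucose_mgdl",
  "glycemic_index", "glycemic_load", "hba1c", "hi2", "hi_post", "hi_pre",
  "homa", "hour_cos", "hour_sin", "i.timestamp", "impact", "label", "lo2",
  "lo_pre", "meal_breakfast", "meal_dinner", "meal_id", "meal_lunch",
  "meal_snack", "meal_type", "med_count", "med_dpp4", "med_dpp4_dose",
  "med_effect", "med_metformin", "med_metformin_dose", "med_penalty_total",
  "med_sulfonylurea", "med_sulfonylurea_dose", "method", "n_post", "n_pre",
  "name", "noise_sd", "observed_delta", "observed_minutes_to_peak",
  "observed_peak", "outcome", "patient_id", "pred_impact", "premeal_median",
  "protein_fat_damping", "protein_g", "quality_flag", "rel_dev", "score",
  "sedentary_minutes", "sedentary_minutes_day", "sex", "sex_male",
  "sleep_efficiency", "sleep_mean_min", "sleep_minutes", "sleep_penalty",
  "steps", "steps_2h", "steps_daily_mean", "steps_day", "tags",
  "time_since_last_meal", "timestamp", "trailing_mean", "trailing_sd",
  "trailing_slope", "truth_outlier", "waist_cm", "x.glucose_mgdl",
  "x.steps", "x.timestamp", "deficit_h", "basal_glucose", "activity_damping",
  "flagged", "age"
))
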