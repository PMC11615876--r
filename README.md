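# glycotwin

A desk-scale **digital twin** for postprandial glycemic response (PPGR) in
type 2 diabetes. The package covers the full loop a CGM-driven precision
nutrition platform runs: simulate a cohort of virtual patients with
continuous glucose monitoring, meal, activity and sleep streams from an
explicit ground-truth mechanism; clean and impute the streams; engineer the
predictor rows of a glucose-peak model; train and validate the model under
leakage-safe temporal cross-validation; and turn its predictions into
ranked, traffic-light-labelled dietary recommendations.

It is written for biostatisticians and ML engineers who want a fully
testable, reproducible reference implementation of this pipeline — every
stage is scored against a generator whose ground truth is known exactly,
so end-to-end identities (noiseless extraction recovers truth bit for bit)
and statistical properties (coverage, recall, recovery error) are asserted
in the test suite rather than assumed.

## The core model

Each logged meal is summarized by its **glucoseMax** — the maximum glucose
in the 120-minute post-meal window — normalized against a
medication-penalized baseline (pre-meal median plus a per-drug-class
penalty for pharmacologically lowered baselines). A gradient-boosted tree
ensemble predicts the excursion

> delta = glucoseMax − adjusted baseline

from 37 features: demographics, labs (HbA1c, HOMA), medications, meal
composition (macros, fiber, glycemic index/load, carbohydrate-to-protein
ratio, time since last meal), time of day, recent glucose trend
(lag/slope/variability features carrying the temporal state), activity and
sleep. Validation uses 5-fold cross-validation with **contiguous-in-time
folds and a 14-day gap** between training and validation rows, with
hyperparameters chosen on inner time-ordered holdouts only.

Recommendations minimize

> score(food) = PPGR_predicted + λ₁ · nutrient variability + λ₂ · preference penalty

over a candidate food table (hard dietary exclusions are pre-filters, never
penalties), and foods are classified **GFY/OFY/RFY** (Green/Orange/Red For
You) against per-patient Nutrition Rules Table thresholds that update from
trailing observed responses.

## Worked example

Simulate a 10-patient study, train the PPGR model with temporal-gap CV, and
rank foods for one patient:

```r
library(glycotwin)

cfg    <- sim_config(n_patients = 10, days = 20, seed = 21, noise_sd = 12)
ds     <- clean_cgm(simulate_study(generate_cohort(cfg), cfg))
ft     <- build_feature_table(ds)
keep   <- ft[excluded == FALSE]
folds  <- make_folds(keep$timestamp, k = 5, gap_days = 14)
model  <- train_ppgr(keep, keep$observed_delta, model_config(seed = 21), folds)
model
#> <ppgr_model v1> gradient_boosting, 600 training rows
#>   outer-fold pooled: RMSE 15.77  MAE 12.03  R2 0.737
```

The printed metrics are pooled over held-out temporal folds: on average the
predicted glucose peak is within ~12 mg/dL of the observed one, and the
model explains ~74% of the excursion variance in this small cohort (the
60-patient benchmark reaches R² ≈ 0.9). Ranking foods for the first
patient's next meal:

```r
pid  <- ds$profiles$patient_id[1]
now  <- keep[patient_id == pid][.N]
ctx  <- temporal_context(ds$cgm[patient_id == pid],
                         ds$activity[patient_id == pid],
                         ds$sleep[patient_id == pid], now$timestamp)
st   <- patient_state(ds$profiles[patient_id == pid], ctx,
                      now$baseline_adjusted, now$timestamp)
nrt  <- nrt_from_impacts(model$report$outer_predictions$predicted)
recommend_foods(default_food_table(), st, model,
                recommendation_config(top_k = 5), nrt = nrt)
#>    food_id                name pred_impact score  label
#> 1:    F022      chickpea curry        22.1  30.3    GFY
#> 2:    F023   kidney bean curry        20.4  36.7    GFY
#> 3:    F021    dal lentil curry        21.4  37.1    GFY
#> 4:    F033 vegetable soup bowl        26.9  41.1    GFY
#> 5:    F025    plain yogurt cup        21.2  45.1    GFY
```

`pred_impact` is the predicted excursion in mg/dL for this patient eating
that food now; `score` adds the nutrient-balance and preference terms; the
`label` column is the patient's traffic-light class. Low-glycemic,
fiber-rich foods surface first, as they should for this mechanism.

`run_pipeline(run_config(seed = 1), "out/")` executes the whole chain and
writes every artifact (cleaned data, features, registry, training and
validation reports, recommendations) with an embedded config hash; a thin
command-line wrapper lives at `inst/cli/glycotwin.R`.

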