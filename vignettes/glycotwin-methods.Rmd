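---
title: "Models and methods behind glycotwin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind glycotwin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

glycotwin is a desk-scale digital-twin pipeline for postprandial glycemic
response (PPGR) in type 2 diabetes: it simulates a cohort of virtual
patients with continuous glucose monitoring (CGM), meal, activity and sleep
streams from an explicit ground-truth mechanism; repairs and imputes the
streams; engineers the predictor rows of a gradient-boosted glucose-peak
model; validates it under temporal-gap cross-validation; and drives a
multi-objective dietary recommendation engine. This vignette explains the
models, the tunable parameters, the numerical choices, and what the
synthetic experiments can and cannot show.

## The synthetic cohort and its ground-truth mechanism

No public dataset accompanies this problem, so the package's first-class
citizen is a generator whose ground truth is known exactly. Each virtual
patient carries an observable profile (age, sex, BMI, waist circumference,
HbA1c, HOMA index, medication indicators and doses) and latent response
parameters. A meal's noiseless glucose rise is

    carb_term = carb_sensitivity * carbs_g * GI/100
    rise      = max(0, carb_term
                       - fiber_damping * fiber_g
                       - protein_fat_damping * (protein_g + fat_g)
                       - min(0.5, activity_damping * steps_2h/1000) * carb_term
                       + sleep_penalty * sleep_deficit_h)

on top of a circadian baseline `basal - med_effect * n_medications +
amplitude * sin(2*pi*(hour - 2)/24)` (a morning acrophase, echoing the dawn
phenomenon). The response curve rises linearly to its peak at 45 minutes and
decays exponentially with a 25-minute time constant; sensor noise is i.i.d.
Gaussian per sample. The piecewise rise/decay form was chosen for its
closed-form peak, which gives every downstream stage an exact oracle: on a
noiseless run, `glucose_max()` recovers the generator's truth bit for bit.

Parameter distributions (documented in `?generate_cohort`) were chosen once
to yield traces resembling a type-2-diabetes cohort: basal glucose
Normal(110, 15) truncated to 80–170 mg/dL, HbA1c around 7.8%, 30–70% on
common oral agents, rises averaging ~35–40 mg/dL. Two distributional choices
matter most:

* **Carbohydrate sensitivity is linked to observables.** It is a linear
  function of HbA1c, log-HOMA and BMI plus a small idiosyncratic residual
  (SD 0.05 mg/dL per effective gram). Insulin resistance genuinely drives
  PPGR magnitude, and the link is what makes a *cross-patient* model able to
  explain most response variance — the benchmark is designed so the
  ground-truth explainable variance exceeds the targets the model must meet.
  Real cohorts carry far more unexplained inter-individual variation; the
  simulation's R² values should be read as validating the pipeline, not as
  clinical performance claims.
* **Enrollment is rolling.** Patients start wearing the sensor on dates
  spread evenly over 70 calendar days (configurable), as in a trial with
  staggered recruitment. A single shared start date would make 5-fold
  cross-validation with a 14-day temporal gap infeasible on a 30-day study —
  the middle folds would have no training data at the required distance.

Meals sit at breakfast/lunch/dinner (and optionally an afternoon snack) with
±45-minute jitter snapped to the CGM grid, composed from a bundled 42-item
food table (macros, fiber, glycemic index per typical portion; a stand-in
for production food-composition databases). Meal windows never overlap under
these defaults; attribution of overlapping excursions is deliberately out of
scope. `corrupt_dataset()` injects missingness (completely at random) and
sensor artifacts — single-sample impulses displaced 80–200 mg/dL in a
direction that keeps the value inside the 40–500 mg/dL sensor range — with a
hidden truth column so the cleaning stage can be scored.

## Cleaning and imputation

`flag_outliers()` is a Hampel-style impulse detector. Each sample is scored
by its deviation from a short rolling median (default window 3: the sample
and its two neighbours), in units of a per-trace noise scale estimated from
first differences (MAD(diff)/sqrt(2)). Both choices are deliberate. A long
median window lags genuine postprandial rises and flags real peaks — in
early development a 125-minute window flagged thousands of true meal peaks,
visible as flagged samples clustering exactly 45 minutes after meals. And a
*local* MAD over a handful of samples is itself so variable that dividing by
it produces mass false positives; the first-difference estimate is barely
perturbed by smooth physiological trends. Flagged values are retained but
excluded from feature extraction; flagging is idempotent and monotone in the
threshold (default z > 5).

`interpolate_gaps()` fills interior gaps up to 30 minutes linearly on the
sensor grid, flags the filled samples, and never extrapolates endpoints.
Longer gaps propagate as missing; feature assembly then drops affected meal
rows with a logged reason rather than guessing.

`mice_impute()` implements multiple imputation by chained equations:
continuous variables by Bayesian linear regression (residual variance drawn
from its scaled inverse-chi-square posterior, coefficients from their normal
posterior, residual noise added), categorical variables by multinomial
logistic regression with a draw from the fitted class probabilities;
five imputations and ten cycles by default, with predictive-mean-matching
and random-forest variants available for sensitivity analysis. The Bayesian
draws matter: without parameter uncertainty the between-imputation variance
collapses and Rubin-pooled intervals undercover. `rubin_pool()` combines
estimates as the mean with total variance `W + (1 + 1/m) B`. Convergence of
the chains is not monitored formally; ten cycles is a pragmatic cap for the
low-dimensional tables involved.

## Features

`feature_registry()` fixes 37 predictors in a frozen order: demographics
(4), labs (2), medications (5), meal composition including the
carbohydrate-to-protein ratio (denominator floored at 1 g) and time since
last meal (capped at 960 minutes; the cap doubles as the first-meal value)
(9), meal-type one-hot (4), time-of-day sine/cosine (2), recent glucose (5),
activity (4), and sleep (2). The registry is configuration: its hash is
stamped into every trained model and checked at prediction time.

The pre-meal baseline is the **median over the 60 minutes before the meal**
plus a per-medication penalty (defaults 4–12 mg/dL by drug class;
configuration, not estimates) compensating for pharmacologically lowered
baselines. Sixty minutes rather than a shorter window is a
noise-versus-drift tradeoff: 12 samples shrink the median's noise variance
to ~pi/2 sigma²/12 while circadian drift over the hour stays under ~2
mg/dL. The model target is the **delta** (observed `glucoseMax` in the
120-minute post-meal window minus the adjusted baseline); peaks are
reconstructed by adding the baseline back, so peak-scale and delta-scale
errors are numerically identical. Both the delta and the relative impact
(delta/baseline) are exposed, since either normalization is defensible.

## The PPGR model

The predictor is a gradient-boosted tree ensemble (xgboost; a random-forest
backend via ranger is available) over the 37 static features. Temporal
state enters through engineered lag features — trailing slope, mean and SD
of the previous hour's glucose, trailing steps, prior-night sleep — rather
than a recurrent encoder: at desk scale the lag features satisfy the same
temporal-dependency contract deterministically and cheaply, and they feed
the same tree ensemble, realizing the combined static-plus-temporal
prediction form.

Validation uses **temporal-gap 5-fold cross-validation**: contiguous-in-time
validation blocks, training rows at least 14 days from every validation row
of their fold, rows inside the gap dropped from that fold's training set.
Hyperparameters are chosen by nested selection — a grid search (learning
rate {0.05, 0.1} × depth {3, 5}, up to 400 rounds, L2 regularization,
subsample 0.8, early stopping with 25-round patience) evaluated on a
time-ordered inner holdout (the most recent 20% of the fold's training
block) — after which the fold's model is refit on the full training block at
the selected round count. The capped grid is deliberate: a wider grid
(learning rate 0.03, 500 rounds) changed pooled benchmark error by under
0.1%, so the small grid stands. The final deployed model refits on all rows
with the modal fold choice. Early-stopping slices are always time-ordered
(most recent data held out), consistent with the temporal-gap philosophy —
a random slice would leak future context backwards.

Residual diagnostics (a normality p-value and the lag-1 autocorrelation of
time-ordered outer-fold residuals) are computed into every training report
rather than assumed. `corrective_update()` implements feedback retraining:
when newly logged meals run hotter than predicted by more than a policy
threshold (default mean excess 15 mg/dL), the model retrains on the union
under its existing hyperparameters and the version increments; otherwise it
is returned untouched.

## Recommendation engine

Candidates are scored by

    score = PPGR_predicted + lambda1 * nutrient_variability
                           + lambda2 * preference_penalty

and the lowest-scoring foods are returned (ties: lower predicted impact,
then food id); the ranking provably equals exhaustive enumeration, which the
test suite asserts against a brute-force oracle. "Nutrient variability" is
formalized — the source framework names but never defines it — as the
Euclidean distance between the candidate's macro calorie shares (4/4/9 kcal
per gram) and the patient's target proportions; the formula is isolated
behind one function so it can be swapped. Hard dietary exclusions
(allergens, diet rules) are pre-filters, never penalties: an excluded food
cannot be outscored into a recommendation. Since the variability distance
lives in [0, ~1.4] and the preference penalty in small integers while PPGR
is tens of mg/dL, the default weights lambda1 = 100 and lambda2 = 10 put
all three terms on a comparable mg/dL scale; both are configuration flagged
as package defaults, not fitted values.

Foods are classified Green/Orange/Red For You by per-patient thresholds
(the Nutrition Rules Table). Initial thresholds are population tertiles of
predicted impact; `adjust_nrt()` re-estimates them as empirical tertiles
(type-7 quantiles) of the patient's trailing observed impacts — a
patient-relative rather than absolute-mg/dL reading of the thresholds,
chosen because it keeps the three classes populated as a patient's
metabolism improves — with a minimum of 10 observations and a version bump
on every adjustment.

## Metrics

`regression_metrics()` computes MSE, RMSE, MAE and R² in their closed
forms; R² is flagged undefined when the observed variance is zero rather
than returning a misleading number. Spike classification uses a rank-based
AUC (Mann–Whitney with midranks), with a spike defined by default as a rise
above the adjusted baseline exceeding 40 mg/dL — "spike" is never defined
in the source framework, so the definition is explicit configuration with
an absolute-180 mg/dL alternative. CGM summaries report time-in-range
(70–180 mg/dL, bounds inclusive, sample-weighted), glycemic variability as
the per-day SD averaged across days, and percent time above range.
Validation reports attach percentile bootstrap confidence intervals
(B = 500 by default) and are seed-deterministic.

## The desk benchmark and problem sizes

The package's reference experiment (`desk_benchmark()`) simulates 60
patients × 30 days × 3 meals/day (5400 meals) at sensor noise 12 mg/dL,
cleans, featurizes, and trains under the scheme above; all reported metrics
come from pooled outer-fold predictions, and the experiment is repeated over
five seeds. A 7 mg/dL low-noise variant is used for the squared-error
summary. A single seed runs in about half a minute on one CPU. The unit
tests use smaller cohorts (3–10 patients, 5–20 days) chosen as the smallest
sizes at which each property is statistically unambiguous.

Two accounting facts set the floor for what any model can score here. The
observed `glucoseMax` is a maximum over ~24 noisy samples, which at noise 7
mg/dL contributes ~41 mg/dL² of irreducible target variance (plus ~6 from
the baseline median); and training on fully noiseless data shows the tree
ensemble's own generalization limit on this cohort's response surface is
~30 mg/dL² (held-out MAE ≈ 4 mg/dL). Pooled squared errors therefore bottom
out near 70–75 mg/dL² at the low-noise setting even though held-out MAE,
RMSE, R² and AUC are comfortable; readers comparing squared-error figures
across systems should keep the extraction-noise floor in mind.

## Known limitations

The generator's linear kernel omits insulin dynamics (no ODE model by
design), meal-overlap attribution, sensor drift and calibration error, and
microbiome or free-text meal effects. The imputation chains are not
convergence-monitored. The recurrent temporal encoder is an interface
option, not an implemented backend. Recommendation scoring is per-food;
multi-item meal optimization is out of scope. Everything the tests prove is
proved on this mechanism; transfer to real CGM cohorts is an empirical
question the package cannot settle.
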