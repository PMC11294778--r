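# glycattn

Interpretable transformer prediction of poor glycemic control from
irregularly spaced HbA1c time series.

## What problem this solves

Patients with type 2 diabetes are monitored through HbA1c laboratory tests
taken at irregular intervals — typically 7–8 tests a year spread over 53
possible weeks. Clinicians need an early, interpretable warning that a
patient's glycemic control will become *poor* (any HbA1c ≥ 8% within the
next year) despite usual care, so they can consider extraordinary treatment
intensification. `glycattn` is for quantitative clinical researchers who
want to build, probe, and evaluate such a predictor end to end without
access to protected hospital data.

## The model

Irregular measurements are quantized onto a Monday–Sunday weekly grid
(`ceil(N·365/7)` slots for an N-year history; 53 for one year), averaging
within weeks and leaving empty weeks missing — no imputation or
normalization. A transformer encoder–decoder then scores each reference
date:

* a **masked self-attention encoder** whose key-padding mask assigns
  missing weeks attention weight exactly 0, with **causal masking** so week
  *t* sees only weeks ≤ *t*; self-attention weights are learned by
  **self-supervised pretraining** (predicting the next observed HbA1c,
  mean-squared error at observed targets only);
* a **cross-attention decoder** with a single learned classification query
  whose weights over the weeks are learned by supervised training with
  **focal loss** `FL = −α(1−p_t)^γ log p_t` (γ = 2, α = 0.25 by default);
* an **F1-maximizing decision threshold** selected on training scores.

Attention weights double as the interpretation: per-week self-attention
salience and cross-attention curves, per instance and averaged over
model-vs-comparator concordance groups. Evaluation follows a rolling-origin
protocol (train on year *y−1* references, test on year *y*) with ROC-AUC,
PR-AUC, accuracy, and F1 plus percentile-bootstrap 95% CIs. A
gradient-boosted tree comparator (xgboost, native missing values) consumes
the same grid. A seeded synthetic cohort generator (AR(1) set-point dynamics,
seasonal cosine, gamma-renewal visits; ~7.7 tests/patient-year, record mean
7.1% (SD 1.1), ~85% weekly missingness, ~27–33% instance prevalence) stands
in for the hospital EHR.

## Worked example

```r
library(glycattn)

cfg    <- cohort_config(n_patients = 500, start_date = "2009-01-01",
                        end_date = "2013-12-31", seed = 101)
cohort <- generate_cohort(cfg)
train  <- build_instances(cohort, 2011)   # reference dates in 2011
test   <- build_instances(cohort, 2012)   # held-out following year

model  <- train_glycemic_model(train, model_config(profile = "desk"),
                               seed = 202)
scores <- predict(model, test)
roc_auc(scores, test$label)
```

On this seed the run prints (a few minutes on one CPU):

```
train: 3792 instances, 30.2% positive | test: 3874 instances, 28.7% positive
held-out ROC-AUC: 0.985   PR-AUC: 0.965   accuracy: 0.939   F1: 0.898
```

so the desk-scale model separates future poor control from good control
almost perfectly on the synthetic benchmark, where the outcome is driven by
recent HbA1c levels — the same signal the attention curves expose:

```r
recs <- extract_attention(model, test[1:400])
colMeans(t(sapply(recs, cross_attention_recency)))
#>  recent  oldest
#>   0.323   0.139
```

i.e. the classification query puts over twice as much cross-attention mass
on the most recent quarter of observed weeks as on the oldest quarter.
`run_rolling_origin()` repeats the whole procedure across test years,
`history_length_sweep()` across 1–5-year input windows, and
`group_attention_profile()` reproduces the group-averaged attention curves.
The full-scale configuration (4+4 layers, hidden 128, batch 512, 20,000
iterations) is `model_config()`'s default. See
`vignettes/glycattn-methods.Rmd` for the model, the generator's assumptions,
and what the synthetic benchmark does and does not demonstrate.

## A command-line interface

`inst/cli/glycattn.R` wraps simulation, preprocessing, and rolling-origin
evaluation for shell use:

```sh
Rscript inst/cli/glycattn.R simulate --n-patients 500 --seed 17 --out cohort.csv
Rscript inst/cli/glycattn.R preprocess --in cohort.csv --year 2011 --out train.csv
Rscript inst/cli/glycattn.R evaluate --cohort cohort.csv --test-years 2011:2012 --profile desk --out reports/
```
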