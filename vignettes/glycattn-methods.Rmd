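---
title: "Predicting poor glycemic control from irregular HbA1c series: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting poor glycemic control from irregular HbA1c series: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycattn)
```

## The problem

Hemoglobin A1c (HbA1c) reflects average blood glucose over the preceding one
to two months and is the standard monitoring measure in type 2 diabetes.
Clinicians must judge, from a patient's HbA1c trajectory under usual care,
whether glycemic control will become poor — here defined as any HbA1c at or
above 8% within the coming year — early enough to intensify treatment beyond
the usual adjustments. Two features make this hard to automate: laboratory
tests arrive at irregular, patient-specific intervals (roughly 7–8 tests per
year against 53 possible weeks), and HbA1c carries seasonal and transient
fluctuations that obscure the underlying trend.

`glycattn` implements an attention-based sequence model for this task
together with everything needed to exercise it end to end: a synthetic
cohort generator, weekly-grid preprocessing, two-stage training, temporal
(rolling-origin) evaluation with bootstrap confidence intervals, and
attention-weight interpretability.

## Data representation

Measurements are quantized onto a **Monday-to-Sunday weekly grid**: an
N-year history window ending at a reference date (itself an HbA1c test date)
becomes `ceiling(N * 365 / 7)` slots — 53 for one year. Multiple
measurements in one week are averaged; weeks without a measurement are
**missing**, represented by an explicit mask, never by imputation,
interpolation, or normalization. A "1 year" window or horizon is exactly 365
days, matching the grid arithmetic. The measurement taken on the reference
date itself is part of the input window (the outcome horizon starts strictly
after the reference date); `include_reference_week = FALSE` is available to
study the alternative convention.

An instance's label is positive when any measurement in the 365 days after
the reference date is at or above the 8% threshold (the comparison is
inclusive). Instances whose horizon extends past the last recorded date are
dropped rather than labeled from a truncated window.

## Model

The model is a transformer encoder–decoder operating on the weekly grid:

* **Embedding.** Each observed week's scalar HbA1c value is linearly
  projected to the hidden dimension and added to a fixed sinusoidal
  positional encoding of the week index. Because the positional encoding is
  not learned, the parameter count is independent of the input width and one
  model accepts 1- to 5-year histories.
* **Masked self-attention encoder.** Pre-norm attention blocks with two
  masks applied jointly: a *key-padding mask* that gives missing weeks
  attention weight exactly 0 (missing data are skipped, not filled in), and
  a *causal mask* so position *t* attends only to weeks at or before *t*.
  Rows of every attention matrix are therefore probability vectors over the
  observed, non-future weeks.
* **Cross-attention decoder.** A single learned classification query
  cross-attends to the encoder states through the decoder blocks; a linear
  layer and sigmoid produce the probability of poor control. The single
  query yields one weight per week per head — the quantity the
  interpretability module averages and reports. No extra causal mask is
  needed in the decoder: every encoder position is already in the past of
  the reference date.
* **Heads.** A next-value regression head drives self-supervised
  pretraining; the classification head drives the supervised stage.

The full-scale configuration is 4 encoder layers, 4 decoder layers, 4 heads,
hidden size 128, feed-forward width 512, Adam at learning rate 1e-4, batch
512, 20,000 iterations per stage with no early stopping, and focal loss for
the supervised stage.

Internally the encoder computes only on the observed weeks of each instance
(packed sequences). This is an exact reformulation, not an approximation:
masked positions receive zero attention everywhere and all other operations
are position-wise, so no masked position can influence any output. The test
suite asserts this bit-exactly by resampling the values stored at missing
slots and requiring identical predictions.

## Training

1. **Self-supervised pretraining.** The causal encoder plus regression head
   minimize the mean squared error of predicting, at every observed week
   that has a later observed week, the *next observed* HbA1c value. Missing
   slots contribute nothing to the loss. (An alternative reading of the
   pretraining target — the value at week *t + 1* only when observed — is a
   strict subset of these targets; we use the next-observed-value form
   because it supplies a target at every eligible position under 85%
   missingness.) The loss is plain MSE: focal loss is a classification
   construct and applies to the supervised stage.
2. **Supervised training.** The decoder, classification query, and output
   head minimize focal loss
   `FL = -alpha * (1 - p_t)^gamma * log(p_t)` (defaults `gamma = 2`,
   `alpha = 0.25`; `gamma = 0, alpha = 1` recovers cross-entropy). The
   encoder is **frozen** by default — self-attention weights are the product
   of pretraining, cross-attention weights of supervised training — with
   `freeze_encoder = FALSE` available for joint fine-tuning.
3. **Decision threshold.** The probability cut-off is chosen to maximize F1
   on the *training* scores by an exhaustive scan over all distinct score
   values plus 0 and 1, breaking ties toward the higher threshold (fewer
   positive calls).

Both stages use Adam, uniform-with-replacement minibatches under a single
seed, and a fixed iteration budget; identical seeds give bit-identical
weights. Dropout defaults to 0 and inference is always deterministic.

A documented **desk profile** (`model_config(profile = "desk")`: 2+2 layers,
hidden 64, feed-forward 256, batch 64, 2,000 iterations, learning rate 1e-3)
is used throughout the tests and the acceptance script; the learning rate is
raised one decade from the full profile as the standard compensation for the
eight-fold smaller batch.

## Synthetic cohort generator

No patient-level data ship with the package; the generator produces cohorts
with the statistical structure of a large specialist-care diabetes clinic:

* **Visit process:** gamma-renewal inter-test gaps with mean
  `365.25 / 7.7` days; the default shape (`rate / sd^2`, about 1) makes
  per-year test counts mean 7.7 with SD 2.8. At most one test per calendar
  day; several tests may share a week, exercising within-week averaging.
* **Value process:** patient set point `mu_i` (Gaussian across patients)
  plus a weekly AR(1) deviation (coefficient 0.9), a seasonal cosine
  (amplitude 0.25%, peaking in mid-February — winter peaks of the order of
  0.2–0.3% are typical of the seasonality reported for HbA1c), a small
  patient-specific linear drift, and measurement noise. The between-patient
  spread is solved internally so the marginal record SD equals the
  configured 1.1% at mean 7.1%.
* **Outcome regime:** under the defaults, one-year instances show roughly
  27–33% positive labels and about 85% weekly missingness, matching the
  regime the model is designed for. A `mu_offset` field can steer prevalence
  without touching the marginal moments.

What the generator deliberately does **not** emulate: treatment
intensification feedback (real poor-control cases occur *despite*
intensification), medication/diagnosis covariates, visit-rate dependence on
disease severity, non-Gaussian heavy tails of the HbA1c distribution, and
inter-hospital variation. Passing tests on this cohort therefore demonstrate
that the architecture, masking, training, and evaluation machinery work and
that the model can extract a recency-weighted autoregressive signal — they
do not certify clinical performance, which the original hospital data put at
ROC-AUC about 0.93 with the full-scale profile.

## Evaluation

* **Rolling-origin splits:** train on instances referenced in year
  *y − 1*, test on year *y*, sliding forward. The audit enforced in code is
  that every training reference date (hence every training *input*) precedes
  every test reference date. Note that with a one-year outcome horizon the
  training outcome windows of late *y − 1* references overlap the test
  horizon calendar-wise; this is inherent to the rolling-origin design with
  adjacent years and is shared by the original study's protocol.
* **Metrics:** ROC-AUC in the Mann–Whitney formulation; PR-AUC as the
  step-interpolated (average-precision) area — linear interpolation in PR
  space is optimistically biased and is not used; accuracy and F1 at the
  selected threshold. All are implemented directly and tested against
  brute-force enumeration at 1e-9.
* **Uncertainty:** percentile bootstrap (default 1000 record-level
  resamples, seeded); single-class resamples are redrawn and counted.
* **Pooling:** the pooled report concatenates per-year scores after
  re-centering each year's scores at its own threshold, so pooled accuracy
  and F1 respect the per-year decision rules while pooled AUCs are computed
  on the concatenated ranking. Per-year reports are always available
  alongside.
* **Comparator:** a gradient-boosted tree model (xgboost) consuming the
  same weekly grid with native `NA` missing values, used for accuracy
  comparison and for the concordance-group interpretability analysis.

## Interpretability

`extract_attention()` reduces attention to two per-week curves per instance:
self-attention *salience* (attention received by each week, averaged over
heads, layers, and observed query rows — the plotted reduction is an
averaging choice; per-head raw maps can be retained) and the classification
query's cross-attention (averaged over heads and layers; a probability
vector over observed weeks). `assign_groups()` forms the four
model-vs-comparator concordance groups (both right on positives, both right
on negatives, and the two discordant positive groups), and
`group_attention_profile()` averages HbA1c, salience, and cross-attention
per week over a group, counting only instances where the week is observed.

On the synthetic benchmark the recency property is checked quantitatively:
mean cross-attention mass on the most recent quarter of observed weeks
exceeds that on the oldest quarter.

## Numerical choices and edge cases

* Masked softmax subtracts the row maximum over allowed keys; forbidden keys
  are exact zeros (not small numbers); fully forbidden rows return all
  zeros rather than NaN, and such rows never reach any output.
* Focal-loss probabilities are clamped to `[1e-7, 1 - 1e-7]`.
* Layer normalization uses epsilon 1e-5; blocks are pre-norm, which trains
  stably at these depths without warm-up schedules.
* Weights are Glorot-uniform; all stochasticity (initialization, batch
  sampling, bootstrap) flows from user-supplied integer seeds.
* Degenerate inputs fail loudly: all-missing series, single-class training
  sets, empty groups, and all-equal score vectors each have a defined error
  or warning tested in the suite.
* Backpropagation is hand-written against the packed representation and is
  verified in the test suite by central finite differences on every
  parameter tensor.

## Problem sizes used in the checks

The test suite and acceptance script run the desk profile on a 500-patient,
5-year cohort (about 3,800 training and 3,800 test instances), a scale at
which the two training stages complete in a few minutes on one CPU while
leaving the learning signal intact; unit tests use smaller cohorts and
models chosen to exercise contracts rather than accuracy. The full-scale
profile is the package default for real use.

## Known limitations

* The generator's Gaussian set-point distribution reproduces the first two
  moments of the record distribution but not its exact tail fractions.
* Attention weights are a model-specific account of which weeks drove a
  prediction, not a causal attribution; the package reports them as plotted
  curves and group averages without claiming more.
* The comparator is a gradient-boosted tree implementation (xgboost) of the
  same model family as the original study's LightGBM reference, not that
  exact library.
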