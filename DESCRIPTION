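Package: glycattn
Title: Interpretable Transformer Prediction of Poor Glycemic Control from
    Irregular HbA1c Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts poor glycemic control (HbA1c >= 8% within one year)
    for patients with type 2 diabetes from irregularly spaced HbA1c
    laboratory series. Measurements are quantized onto a Monday-to-Sunday
    weekly grid with explicit missingness; a transformer encoder with
    key-padding and causal attention masks is pretrained by self-supervised
    next-value regression, and a cross-attention decoder with a learned
    classification query is trained with focal loss to score the risk of
    poor control. Includes a seeded synthetic cohort simulator (AR(1)
    latent dynamics with seasonal variation and a renewal visit process),
    rolling-origin temporal evaluation with bootstrap confidence intervals,
    an F1-maximizing decision threshold, attention-weight interpretability
    profiles, and a gradient-boosted tree comparator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    xgboost,
    pROC,
    optparse
Config/testthat/edition: 3
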