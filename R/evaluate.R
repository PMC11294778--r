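#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, counting ties as one half. Implemented directly
#' (rank statistic) so that it can be checked against brute-force pairwise
#' enumeration.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.numeric(labels) > 0.5
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L) {
    stop("roc_auc: both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) area over distinct score thresholds in
#' descending order: `sum_k (R_k - R_(k-1)) * P_k`, the average-precision
#' form. Step interpolation avoids the optimistic bias of linear
#' interpolation in PR space. With all scores equal the curve collapses to a
#' single point and the area equals the prevalence.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels; at least one positive required.
#' @return PR-AUC in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  y <- as.numeric(labels) > 0.5
  n_pos <- sum(y)
  if (n_pos == 0L) stop("pr_auc: no positive labels", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  # cumulative counts at each distinct threshold (groups of tied scores)
  last_of_group <- c(ss[-1] != ss[-length(ss)], TRUE)
  tp <- cumsum(ys)[last_of_group]
  np <- seq_along(ys)[last_of_group]
  prec <- tp / np
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

# Confusion-derived metrics of the rule score >= threshold.
#' Accuracy and F1 at a decision threshold
#'
#' Applies the decision rule `score >= threshold` and counts. `f1_at` returns
#' 0 when there are no predicted positives or no true positives.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @param threshold Decision threshold.
#' @return A proportion in `[0, 1]`.
#' @export
accuracy_at <- function(scores, labels, threshold) {
  y <- as.numeric(labels) > 0.5
  pred <- scores >= threshold
  mean(pred == y)
}

#' @rdname accuracy_at
#' @export
f1_at <- function(scores, labels, threshold) {
  y <- as.numeric(labels) > 0.5
  pred <- scores >= threshold
  tp <- sum(pred & y)
  if (tp == 0L) return(0)
  prec <- tp / sum(pred)
  rec <- tp / sum(y)
  2 * prec * rec / (prec + rec)
}

#' Percentile bootstrap confidence interval for a score metric
#'
#' Resamples records (score/label pairs) with replacement `n_boot` times
#' under a fixed seed and returns the 2.5th and 97.5th percentiles of the
#' metric. Resamples containing a single class are redrawn (up to 100
#' attempts each, counted and reported as an attribute); the call errors if
#' the metric is undefined on more than half of the resamples.
#'
#' @param metric_fn Function `(scores, labels) -> number`, e.g. [roc_auc()].
#' @param scores,labels The records to resample.
#' @param n_boot Number of bootstrap resamples (>= 2).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return Numeric `c(lower, upper)`; attribute `n_redrawn` counts redraws.
#' @export
bootstrap_ci <- function(metric_fn, scores, labels, n_boot = 1000L,
                         seed = 1L, conf = 0.95) {
  stopifnot(n_boot >= 2L, length(scores) == length(labels))
  set.seed(seed)
  n <- length(scores)
  vals <- numeric(n_boot)
  failed <- 0L; redrawn <- 0L
  for (b in seq_len(n_boot)) {
    v <- NA_real_
    for (attempt in seq_len(100L)) {
      idx <- sample.int(n, n, replace = TRUE)
      yb <- as.numeric(labels[idx])
      if (length(unique(yb > 0.5)) < 2L && length(unique(labels)) > 1L) {
        redrawn <- redrawn + 1L
        next
      }
      v <- tryCatch(metric_fn(scores[idx], labels[idx]),
                    error = function(e) NA_real_)
      break
    }
    if (is.na(v)) failed <- failed + 1L
    vals[b] <- v
  }
  if (failed > n_boot / 2) {
    stop("bootstrap_ci: metric undefined on more than half of the resamples",
         call. = FALSE)
  }
  a <- (1 - conf) / 2
  ci <- unname(quantile(vals, c(a, 1 - a), na.rm = TRUE))
  attr(ci, "n_redrawn") <- redrawn
  ci
}

#' Evaluation report for one scored test set
#'
#' Computes ROC-AUC, PR-AUC, accuracy and F1 at the decision threshold, with
#' percentile-bootstrap 95% confidence intervals (record-level resampling).
#'
#' @param scores Predicted probabilities on the test set.
#' @param labels True binary outcomes.
#' @param threshold Decision threshold (from [select_threshold()] on
#'   training data).
#' @param n_boot Bootstrap resamples per metric.
#' @param seed Seed for the bootstrap.
#' @param test_year,history_years Optional provenance fields carried in the
#'   report.
#' @return An `evaluation_report`: list with the four metrics, `ci95` (named
#'   list of `c(lower, upper)`), `n_records`, `n_positive`, `test_year`,
#'   `history_years`.
#' @export
evaluation_report <- function(scores, labels, threshold = 0.5,
                              n_boot = 1000L, seed = 1L,
                              test_year = NA_integer_,
                              history_years = NA_integer_) {
  y <- as.numeric(labels)
  thr <- if (inherits(threshold, "decision_threshold")) threshold$value
         else threshold
  metrics <- list(
    roc_auc = roc_auc(scores, y),
    pr_auc = pr_auc(scores, y),
    accuracy = accuracy_at(scores, y, thr),
    f1 = f1_at(scores, y, thr)
  )
  ci <- list(
    roc_auc = bootstrap_ci(roc_auc, scores, y, n_boot, seed),
    pr_auc = bootstrap_ci(pr_auc, scores, y, n_boot, seed + 1L),
    accuracy = bootstrap_ci(function(s, l) accuracy_at(s, l, thr),
                            scores, y, n_boot, seed + 2L),
    f1 = bootstrap_ci(function(s, l) f1_at(s, l, thr),
                      scores, y, n_boot, seed + 3L)
  )
  structure(c(metrics, list(
    ci95 = ci, threshold = thr,
    n_records = length(y), n_positive = sum(y > 0.5),
    prevalence = mean(y > 0.5),
    test_year = test_year, history_years = history_years
  )), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report (test year %s, %s-year history)\n",
              x$test_year, x$history_years))
  cat(sprintf("  n = %d records, %d positive (%.1f%%)\n",
              x$n_records, x$n_positive, 100 * x$prevalence))
  for (m in c("roc_auc", "pr_auc", "accuracy", "f1")) {
    cat(sprintf("  %-8s %.3f (95%% CI %.3f-%.3f)\n", m, x[[m]],
                x$ci95[[m]][1], x$ci95[[m]][2]))
  }
  invisible(x)
}

#' Gradient-boosted tree comparator
#'
#' Trains a gradient-boosted decision-tree classifier (xgboost) on the same
#' weekly grid used by the transformer, with missing slots passed natively as
#' `NA` features. Serves as the reference model for concordance-group
#' interpretability analyses and accuracy comparisons.
#'
#' @param instances A labeled `instance_set`.
#' @param seed Integer seed.
#' @param nrounds Boosting rounds.
#' @param max_depth,eta Tree depth and learning rate.
#' @return An object of class `gbt_comparator` with a `predict` method
#'   returning probabilities.
#' @export
train_comparator <- function(instances, seed = 1L, nrounds = 200L,
                             max_depth = 4L, eta = 0.1) {
  if (!requireNamespace("xgboost", quietly = TRUE)) {
    stop("train_comparator requires the xgboost package", call. = FALSE)
  }
  X <- instances$values
  X[!instances$observed] <- NA_real_
  colnames(X) <- paste0("week_", seq_len(ncol(X)))
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(instances$label),
                                 nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
  structure(list(booster = booster), class = "gbt_comparator")
}

#' @export
predict.gbt_comparator <- function(object, instances, ...) {
  X <- instances$values
  X[!instances$observed] <- NA_real_
  colnames(X) <- paste0("week_", seq_len(ncol(X)))
  as.numeric(predict(object$booster, xgboost::xgb.DMatrix(X, nthread = 1)))
}

# Audit that no test input or outcome information was available at training
# time: every training reference (input window end) precedes every test
# reference, and test outcome windows open strictly after that.
assert_no_leakage <- function(train_instances, test_instances) {
  stopifnot(max(train_instances$reference_date) <
              min(test_instances$reference_date))
  invisible(TRUE)
}

#' Rolling-origin temporal evaluation
#'
#' For each train/test year pair from [make_rolling_splits()]: builds
#' instances, pretrains the encoder, trains the decoder, selects the decision
#' threshold on training scores, scores the test year, and produces an
#' [evaluation_report()]. Also returns a pooled report over the concatenated
#' per-year test scores. Years whose training or test set contains a single
#' class are skipped with a warning.
#'
#' @param cohort Measurement table (see [generate_cohort()]).
#' @param config A [model_config()].
#' @param history_years Input window length N.
#' @param first_test_year,last_test_year Test year range.
#' @param seed Master seed; per-split seeds are derived from it.
#' @param n_boot Bootstrap resamples per report.
#' @param pretrain_iterations,supervised_iterations Optional per-stage
#'   iteration overrides (see [train_glycemic_model()]).
#' @param verbose Print per-year progress.
#' @return List with `per_year` (list of `evaluation_report`), `pooled`
#'   (one report over all years), and `models` (per-year fitted models).
#' @export
run_rolling_origin <- function(cohort, config, history_years = 1L,
                               first_test_year, last_test_year, seed = 1L,
                               n_boot = 200L, pretrain_iterations = NULL,
                               supervised_iterations = NULL,
                               verbose = FALSE) {
  history_years <- as.integer(history_years)
  splits <- make_rolling_splits(first_test_year, last_test_year)
  reports <- list(); models <- list()
  pooled_scores <- numeric(0); pooled_labels <- numeric(0)
  pooled_thr <- numeric(0)
  for (k in seq_len(nrow(splits))) {
    ty <- splits$test_reference_year[k]
    tr <- suppressWarnings(
      build_instances(cohort, splits$train_reference_year[k], history_years))
    te <- suppressWarnings(build_instances(cohort, ty, history_years))
    if (nrow(tr$values) == 0L || nrow(te$values) == 0L ||
        length(unique(tr$label)) < 2L || length(unique(te$label)) < 2L) {
      warning("rolling origin: skipping test year ", ty,
              " (empty or single-class instance set)")
      next
    }
    assert_no_leakage(tr, te)
    model <- train_glycemic_model(
      tr, config, seed = seed + 13L * k, pretrain_iterations =
        pretrain_iterations, supervised_iterations = supervised_iterations)
    scores <- predict(model, te)
    rpt <- evaluation_report(scores, te$label, model$threshold,
                             n_boot = n_boot, seed = seed + k,
                             test_year = ty, history_years = history_years)
    if (verbose) print(rpt)
    reports[[as.character(ty)]] <- rpt
    models[[as.character(ty)]] <- model
    pooled_scores <- c(pooled_scores, scores)
    pooled_labels <- c(pooled_labels, as.numeric(te$label))
    pooled_thr <- c(pooled_thr, rep(model$threshold$value, length(scores)))
  }
  pooled <- NULL
  if (length(pooled_scores) > 0L && length(unique(pooled_labels)) > 1L) {
    # pooled accuracy/F1 use each year's own threshold via shifted scores
    shifted <- pooled_scores - pooled_thr + 0.5
    pooled <- evaluation_report(shifted, pooled_labels, 0.5,
                                n_boot = n_boot, seed = seed,
                                test_year = NA_integer_,
                                history_years = history_years)
  }
  list(per_year = reports, pooled = pooled, models = models)
}

#' Sweep over history lengths at a fixed test year
#'
#' Re-runs the train/test procedure for several input window lengths N
#' (keeping the same train and test years), producing one report per N on
#' the same test reference dates where possible.
#'
#' @param cohort Measurement table.
#' @param config A [model_config()].
#' @param n_values Integer vector of history lengths (years).
#' @param fixed_test_year The single test year.
#' @param seed Master seed.
#' @param ... Passed to [run_rolling_origin()] (iteration overrides,
#'   `n_boot`).
#' @return Named list of `evaluation_report`, one per N.
#' @export
history_length_sweep <- function(cohort, config, n_values, fixed_test_year,
                                 seed = 1L, ...) {
  d <- as.Date(cohort$date)
  first_year <- as.integer(format(min(d), "%Y"))
  need <- fixed_test_year - 1L - max(n_values)
  if (need < first_year) {
    stop("history_length_sweep: cohort must start in ", need,
         " or earlier to support N = ", max(n_values),
         " (it starts in ", first_year, ")", call. = FALSE)
  }
  out <- list()
  for (N in n_values) {
    res <- run_rolling_origin(cohort, config, history_years = N,
                              first_test_year = fixed_test_year,
                              last_test_year = fixed_test_year,
                              seed = seed + N, ...)
    out[[as.character(N)]] <- res$per_year[[as.character(fixed_test_year)]]
  }
  out
}
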