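test_that("ROC-AUC handles separation, ties, and degenerate classes", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("PR-AUC handles perfect and constant scores", {
  expect_equal(pr_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(pr_auc(rep(0.3, 10), c(rep(1, 3), rep(0, 7))), 0.3)
  expect_error(pr_auc(c(0.1, 0.9), c(0, 0)), "no positive")
})

test_that("AUC implementations match brute-force enumeration", {
  set.seed(55)
  for (rep in 1:100) {
    n <- sample(5:30, 1)
    scores <- round(runif(n), 2)   # rounding forces ties
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels), roc_auc_brute(scores, labels),
                 tolerance = 1e-9)
    expect_equal(pr_auc(scores, labels), pr_auc_brute(scores, labels),
                 tolerance = 1e-9)
  }
})

test_that("ROC-AUC is invariant under strictly monotone score transforms", {
  set.seed(56)
  scores <- runif(40)
  labels <- rbinom(40, 1, 0.4)
  a <- roc_auc(scores, labels)
  expect_equal(roc_auc(exp(3 * scores), labels), a, tolerance = 1e-12)
  expect_equal(roc_auc(rank(scores), labels), a, tolerance = 1e-12)
})

test_that("accuracy at a threshold equals the direct confusion count", {
  set.seed(57)
  scores <- runif(50)
  labels <- rbinom(50, 1, 0.5)
  thr <- 0.45
  pred <- as.integer(scores >= thr)
  expect_equal(accuracy_at(scores, labels, thr),
               (sum(pred == 1 & labels == 1) + sum(pred == 0 & labels == 0)) / 50)
})

test_that("bootstrap intervals are seeded, ordered, and degenerate-safe", {
  set.seed(58)
  scores <- runif(80)
  labels <- rbinom(80, 1, 0.4)
  ci1 <- bootstrap_ci(roc_auc, scores, labels, n_boot = 200, seed = 4)
  ci2 <- bootstrap_ci(roc_auc, scores, labels, n_boot = 200, seed = 4)
  expect_identical(ci1, ci2)
  expect_lte(ci1[1], ci1[2])
  point <- roc_auc(scores, labels)
  expect_lte(ci1[1], point)
  expect_gte(ci1[2], point)
  # identical records give a zero-width interval
  ci0 <- bootstrap_ci(function(s, l) mean(s), rep(0.7, 30), rep(1, 30),
                      n_boot = 50, seed = 1)
  expect_equal(unname(ci0[1]), unname(ci0[2]))
})

test_that("evaluation reports carry consistent counts and interval order", {
  set.seed(59)
  scores <- runif(120)
  labels <- rbinom(120, 1, 0.3)
  r <- evaluation_report(scores, labels, threshold = 0.5, n_boot = 100,
                         seed = 2, test_year = 2014, history_years = 1)
  expect_equal(r$n_records, 120L)
  expect_equal(r$n_positive, sum(labels))
  for (m in c("roc_auc", "pr_auc", "accuracy", "f1")) {
    expect_lte(r$ci95[[m]][1], r$ci95[[m]][2])
  }
})

test_that("rolling origin produces one report per year without leakage", {
  coh <- small_cohort(n = 35, seed = 61, start = "2006-01-01",
                      end = "2012-12-31", visits_per_year_mean = 6)
  res <- run_rolling_origin(coh, tiny_model_config(), history_years = 1,
                            first_test_year = 2008, last_test_year = 2011,
                            seed = 3, n_boot = 50,
                            pretrain_iterations = 10L,
                            supervised_iterations = 10L)
  expect_length(res$per_year, 4L)
  expect_equal(vapply(res$per_year, `[[`, 0L, "test_year"),
               c(`2008` = 2008L, `2009` = 2009L, `2010` = 2010L,
                 `2011` = 2011L))
  expect_equal(res$pooled$n_records,
               sum(vapply(res$per_year, `[[`, 0L, "n_records")))
})

test_that("history sweep reports the N used and errors on a short cohort", {
  coh <- small_cohort(n = 25, seed = 62, start = "2008-01-01",
                      end = "2012-12-31")
  res <- history_length_sweep(coh, tiny_model_config(), n_values = c(1, 2),
                              fixed_test_year = 2011, seed = 4, n_boot = 50,
                              pretrain_iterations = 10L,
                              supervised_iterations = 10L)
  expect_equal(vapply(res, `[[`, 0L, "history_years"),
               c(`1` = 1L, `2` = 2L))
  expect_error(
    history_length_sweep(coh, tiny_model_config(), n_values = 1:5,
                         fixed_test_year = 2011, seed = 4),
    "2005")
})

test_that("the gradient-boosted comparator learns an easy outcome", {
  skip_if_not_installed("xgboost")
  coh <- small_cohort(n = 60, seed = 63)
  inst <- build_instances(coh, 2011)
  cmp <- train_comparator(inst, seed = 1, nrounds = 50)
  p <- predict(cmp, inst)
  expect_gt(roc_auc(p, inst$label), 0.8)
})
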