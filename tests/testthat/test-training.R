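test_that("pretraining is seeded-deterministic and ignores sentinel content", {
  coh <- small_cohort(n = 12, seed = 31)
  inst <- build_instances(coh, 2011)
  mcfg <- tiny_model_config(iterations = 5L)
  m1 <- pretrain_self_supervised(inst, mcfg, seed = 7, log_every = 1L)
  m2 <- pretrain_self_supervised(inst, mcfg, seed = 7, log_every = 1L)
  expect_identical(m1$params, m2$params)
  # spurious values at missing slots change the loss trace by exactly 0
  m3 <- pretrain_self_supervised(perturb_sentinels(inst), mcfg, seed = 7,
                                 log_every = 1L)
  expect_identical(m1$history$pretrain, m3$history$pretrain)
  expect_identical(m1$params, m3$params)
})

test_that("pretraining reduces the next-value regression error", {
  coh <- generate_cohort(cohort_config(
    n_patients = 40, start_date = "2009-06-01", end_date = "2012-12-31",
    measurement_noise_sd = 0, seed = 33))
  inst <- build_instances(coh, 2011)
  mcfg <- tiny_model_config(hidden_size = 16L, ffn_hidden = 32L,
                            batch_size = 32L, iterations = 300L)
  m <- pretrain_self_supervised(inst, mcfg, seed = 5, log_every = 10L)
  tr <- m$history$pretrain
  expect_lt(tr$loss[nrow(tr)], tr$loss[1])
  expect_lt(tr$loss[nrow(tr)], 1.0)  # well below the raw value scale
})

test_that("pretraining requires an instance with two observed values", {
  vals <- matrix(NA_real_, 2, 53)
  vals[, 20] <- 7.5   # single observation each: no next-value target
  inst <- manual_instances(vals)
  expect_error(pretrain_self_supervised(inst, tiny_model_config(), seed = 1),
               "two or more")
})

test_that("the encoder freeze contract holds bit-exactly", {
  coh <- small_cohort(n = 12, seed = 35)
  inst <- build_instances(coh, 2011)
  mcfg <- tiny_model_config(iterations = 8L)
  m <- pretrain_self_supervised(inst, mcfg, seed = 2)
  enc_names <- glycattn:::encoder_param_names(m$params)
  before <- m$params[enc_names]
  frozen <- train_supervised(inst, m, seed = 3, freeze_encoder = TRUE)
  expect_identical(frozen$params[enc_names], before)
  joint <- train_supervised(inst, m, seed = 3, freeze_encoder = FALSE)
  expect_false(identical(joint$params[enc_names], before))
  # decoder weights did move in both runs
  expect_false(identical(frozen$params$cls_w, m$params$cls_w))
})

test_that("supervised training rejects single-class sets naming the gap", {
  coh <- small_cohort(n = 10, seed = 36)
  inst <- build_instances(coh, 2011)
  mcfg <- tiny_model_config(iterations = 3L)
  m <- pretrain_self_supervised(inst, mcfg, seed = 1)
  all_neg <- inst
  all_neg$label[] <- FALSE
  expect_error(train_supervised(all_neg, m, seed = 1), "no positive")
  all_pos <- inst
  all_pos$label[] <- TRUE
  expect_error(train_supervised(all_pos, m, seed = 1), "no negative")
})

test_that("threshold selection maximizes F1 with ties toward fewer calls", {
  th <- select_threshold(c(0.1, 0.9), c(0, 1))
  expect_equal(th$value, 0.9)
  expect_equal(th$f1_at_threshold, 1.0)
  th2 <- select_threshold(c(0.2, 0.4, 0.6, 0.8), c(0, 1, 0, 1))
  cand <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
  brute <- vapply(cand, function(t) f1_at(c(0.2, 0.4, 0.6, 0.8),
                                          c(0, 1, 0, 1), t), 0)
  expect_equal(th2$f1_at_threshold, max(brute))
  expect_equal(th2$value, max(cand[brute >= max(brute) - 1e-12]))
  expect_error(select_threshold(c(0.3, 0.7), c(1, 1)), "no negative")
  expect_warning(th3 <- select_threshold(rep(0.4, 5), c(0, 1, 0, 1, 1)),
                 "identical")
  expect_equal(th3$value, 0.4)
})

test_that("selected threshold matches an exhaustive scan on random sets", {
  set.seed(91)
  for (rep in 1:200) {
    n <- sample(4:12, 1)
    scores <- round(runif(n), 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    th <- suppressWarnings(select_threshold(scores, labels))
    cand <- sort(unique(c(scores, 0, 1)))
    brute <- vapply(cand, function(t) f1_at(scores, labels, t), 0)
    expect_equal(th$f1_at_threshold, max(brute), tolerance = 1e-12)
    expect_equal(f1_at(scores, labels, th$value), max(brute),
                 tolerance = 1e-12)
  }
})

test_that("a separable outcome is learned to high training ROC-AUC", {
  coh <- small_cohort(n = 150, seed = 41, start = "2009-06-01",
                      end = "2012-12-31")
  inst <- build_instances(coh, 2011)
  # outcome driven entirely by the most recent observed value
  last_val <- vapply(seq_len(nrow(inst$values)), function(b) {
    obs <- which(inst$observed[b, ])
    inst$values[b, obs[length(obs)]]
  }, 0)
  inst$label <- last_val >= 8
  mcfg <- model_config(encoder_layers = 2L, decoder_layers = 2L, heads = 4L,
                       hidden_size = 32L, ffn_hidden = 64L, batch_size = 64L,
                       iterations = 400L, learning_rate = 1e-3)
  m <- train_glycemic_model(inst, mcfg, seed = 6,
                            pretrain_iterations = 200L)
  auc <- roc_auc(predict(m, inst), inst$label)
  expect_gte(auc, 0.95)
})
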