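test_that("masked softmax puts exact zeros on masked keys and sums to one", {
  expect_equal(masked_softmax(c(0, log(3)), c(FALSE, FALSE)), c(0.25, 0.75),
               tolerance = 1e-12)
  expect_equal(masked_softmax(c(5, 1, 2), c(FALSE, TRUE, TRUE)), c(1, 0, 0))
  expect_equal(masked_softmax(rep(2.7, 4), rep(FALSE, 4)), rep(0.25, 4))
  w <- masked_softmax(c(10, -3, 4), c(FALSE, TRUE, FALSE))
  expect_identical(w[2], 0)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_error(masked_softmax(c(1, 2), c(TRUE, TRUE)), "all entries")
})

test_that("series embedding has the configured shape and is deterministic", {
  model <- transformer_init(model_config(), seed = 1)  # hidden size 128
  coh <- small_cohort(n = 3, seed = 4)
  inst <- build_instances(coh, 2011)
  ser <- structure(list(values = inst$values[1, ],
                        observed = inst$observed[1, ],
                        reference_date = inst$reference_date[1],
                        history_years = 1L), class = "weekly_series")
  e1 <- embed_series(ser, model)
  e2 <- embed_series(ser, model)
  expect_equal(dim(e1$embeddings), c(53L, 128L))
  expect_identical(e1, e2)
  expect_identical(e1$key_padding_mask, !inst$observed[1, ])
  # sentinel content at masked slots cannot reach the embedding
  ser2 <- ser
  ser2$values[!ser2$observed] <- 123.4
  expect_identical(embed_series(ser2, model)$embeddings, e1$embeddings)
  none <- ser
  none$observed[] <- FALSE
  expect_error(embed_series(none, model), "no observed values")
})

test_that("encoder output respects the causal cone", {
  mcfg <- tiny_model_config()
  model <- transformer_init(mcfg, seed = 2)
  vals <- rep(NA_real_, 53)
  slots <- c(5, 14, 20, 33, 41, 50)
  vals[slots] <- c(6.8, 7.1, 7.4, 8.2, 7.9, 7.0)
  inst <- manual_instances(rbind(vals))
  s1 <- encoder_forward(model, inst)$states
  inst2 <- inst
  inst2$values[1, 33] <- 9.9   # perturb an observed mid-series week
  s2 <- encoder_forward(model, inst2)$states
  delta <- apply(abs(s1 - s2), 1, max)
  expect_true(all(delta[1:32] == 0))          # weeks before 33 unchanged
  expect_gt(max(delta[33:53]), 0)             # downstream weeks respond
})

test_that("sentinel edits at missing slots leave every output bit-identical", {
  mcfg <- tiny_model_config()
  model <- transformer_init(mcfg, seed = 3)
  coh <- small_cohort(n = 15, seed = 5)
  inst <- build_instances(coh, 2011)
  pert <- perturb_sentinels(inst)
  expect_false(identical(inst$values, pert$values))
  expect_identical(predict(model, inst), predict(model, pert))
  expect_identical(encoder_forward(model, inst)$states,
                   encoder_forward(model, pert)$states)
})

test_that("attention rows are stochastic over allowed keys with exact zeros", {
  mcfg <- tiny_model_config(encoder_layers = 2L)
  model <- transformer_init(mcfg, seed = 4)
  coh <- small_cohort(n = 6, seed = 6)
  inst <- build_instances(coh, 2011)[1:4]
  enc <- encoder_forward(model, inst, collect_attention = TRUE)
  expect_length(enc$attention, 2L)    # one map set per layer
  for (l in seq_along(enc$attention)) {
    A <- enc$attention[[l]]
    expect_equal(dim(A), c(53L, 53L, 4L * mcfg$heads))
    for (b in 1:4) {
      obs <- which(inst$observed[b, ])
      for (j in seq_len(mcfg$heads)) {
        M <- A[, , (b - 1L) * mcfg$heads + j]
        # masked keys: exactly zero everywhere
        expect_true(all(M[, -obs] == 0))
        # masked query rows: all zero
        expect_true(all(M[-obs, ] == 0))
        for (q in obs) {
          allowed <- obs[obs <= q]
          expect_equal(sum(M[q, allowed]), 1, tolerance = 1e-6)
          # causal: keys after the query week are exactly zero
          expect_true(all(M[q, setdiff(seq_len(53), allowed)] == 0))
        }
      }
    }
  }
})

test_that("decoder yields probabilities and stochastic cross-attention", {
  mcfg <- tiny_model_config()
  model <- transformer_init(mcfg, seed = 5)
  coh <- small_cohort(n = 6, seed = 7)
  inst <- build_instances(coh, 2011)[1:5]
  enc <- encoder_forward(model, inst)
  dec <- decoder_forward(model, enc$states, inst$observed,
                         collect_attention = TRUE)
  expect_true(all(dec$prob >= 0 & dec$prob <= 1))
  for (l in seq_along(dec$attention)) {
    A <- dec$attention[[l]]
    for (b in seq_len(5)) {
      obs <- inst$observed[b, ]
      for (j in seq_len(mcfg$heads)) {
        w <- A[1, , (b - 1L) * mcfg$heads + j]
        expect_equal(sum(w[obs]), 1, tolerance = 1e-6)
        expect_true(all(w[!obs] == 0))
      }
    }
  }
})

test_that("focal loss matches its closed form and reduces to cross-entropy", {
  expect_equal(focal_loss(0.5, 1, gamma = 0, alpha = 1), log(2),
               tolerance = 1e-9)
  expect_lt(focal_loss(1 - 1e-7, 1, gamma = 2, alpha = 1), 1e-6)
  expect_equal(focal_loss(0.9, 1, gamma = 2, alpha = 1),
               0.01 * (-log(0.9)), tolerance = 1e-9)
  set.seed(31)
  p <- runif(100, 0.01, 0.99)
  y <- rbinom(100, 1, 0.5)
  ce <- -log(ifelse(y == 1, p, 1 - p))   # independent cross-entropy oracle
  expect_equal(focal_loss(p, y, gamma = 0, alpha = 1, reduce = "none"), ce,
               tolerance = 1e-9)
  # out-of-range probabilities are clamped, never NaN
  expect_true(is.finite(focal_loss(0, 1)))
  expect_true(is.finite(focal_loss(1, 0)))
})

test_that("analytic gradients agree with central differences", {
  mcfg <- tiny_model_config()
  model <- transformer_init(mcfg, seed = 11)
  coh <- small_cohort(n = 8, seed = 12)
  inst <- build_instances(coh, 2011)[1:5]
  vm <- list(values = inst$values, observed = inst$observed)
  y <- as.numeric(inst$label)
  loss_fn <- function(params) {
    enc <- glycattn:::encoder_fwd(params, mcfg, vm$values, vm$observed)
    dec <- glycattn:::decoder_fwd(params, mcfg, enc$states,
                                  enc$pack$key_real)
    focal_loss(dec$prob, y, mcfg$focal_gamma, mcfg$focal_alpha)
  }
  params <- model$params
  enc <- glycattn:::encoder_fwd(params, mcfg, vm$values, vm$observed,
                                keep_cache = TRUE)
  dec <- glycattn:::decoder_fwd(params, mcfg, enc$states, enc$pack$key_real,
                                keep_cache = TRUE)
  dlogit <- glycattn:::focal_loss_dlogit(dec$prob, y, mcfg$focal_gamma,
                                         mcfg$focal_alpha)
  bwd <- glycattn:::decoder_bwd(params, mcfg, dlogit, dec, need_dmem = TRUE)
  grads <- c(bwd$grads, glycattn:::encoder_bwd(params, mcfg, bwd$dmem, enc))
  h <- 1e-5
  set.seed(13)
  for (nm in names(grads)) {
    x <- params[[nm]]
    for (k in sample(seq_along(x), min(2, length(x)))) {
      pp <- params
      pp[[nm]][k] <- x[k] + h
      lp <- loss_fn(pp)
      pp[[nm]][k] <- x[k] - h
      lm <- loss_fn(pp)
      num <- (lp - lm) / (2 * h)
      ana <- grads[[nm]][k]
      expect_lt(abs(num - ana), 1e-4 * max(1, abs(num)))
    }
  }
})

test_that("regression head is causal and has the right shape", {
  mcfg <- tiny_model_config()
  model <- transformer_init(mcfg, seed = 21)
  vals <- rep(NA_real_, 53)
  slots <- c(3, 11, 25, 38, 49)
  vals[slots] <- c(6.5, 7.0, 7.8, 8.1, 7.2)
  inst <- manual_instances(rbind(vals, vals))
  enc <- encoder_forward(model, inst)
  pred <- regression_head(model, enc$states)
  expect_equal(dim(pred), c(2L, 53L))
  # editing a late week leaves predictions at earlier weeks unchanged
  inst2 <- inst
  inst2$values[, 49] <- 9.5
  pred2 <- regression_head(model, encoder_forward(model, inst2)$states)
  expect_equal(pred2[, slots[slots < 49]], pred[, slots[slots < 49]],
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(pred2[, 49], pred[, 49])))
})

test_that("the same model accepts histories of different lengths", {
  mcfg <- tiny_model_config()
  model <- transformer_init(mcfg, seed = 22)
  coh <- small_cohort(n = 6, seed = 23, start = "2007-01-01",
                      end = "2012-12-31")
  i1 <- build_instances(coh, 2011, history_years = 1)
  i3 <- build_instances(coh, 2011, history_years = 3)
  expect_equal(ncol(i1$values), 53L)
  expect_equal(ncol(i3$values), 157L)
  p1 <- predict(model, i1)
  p3 <- predict(model, i3)   # same parameters, wider grid
  expect_true(all(is.finite(p1)) && all(is.finite(p3)))
  expect_gt(sum(i3$observed), sum(i1$observed))
})
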