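# Adam optimizer over flat named parameter lists.
adam_init <- function(params) {
  zero <- lapply(params, function(x) x * 0)
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Parameter names belonging to the encoder + embedding + regression head.
encoder_param_names <- function(params) {
  nm <- names(params)
  nm[grepl("^(emb_|enc|reg_)", nm)]
}

# Self-supervised targets: at every observed slot with a later observed slot,
# the target is that next observed value. NA elsewhere.
ssl_targets <- function(values, observed) {
  n <- nrow(values); W <- ncol(values)
  tgt <- matrix(NA_real_, n, W)
  for (b in seq_len(n)) {
    obs <- which(observed[b, ])
    if (length(obs) < 2L) next
    for (k in seq_len(length(obs) - 1L)) {
      tgt[b, obs[k]] <- values[b, obs[k + 1L]]
    }
  }
  tgt
}

# Gather a weekly-slot matrix (n x W) at the packed positions of `pack`,
# giving an Lmax x n matrix (NA at padding).
pack_matrix <- function(M, pack) {
  out <- matrix(NA_real_, pack$Lmax, pack$n)
  for (b in seq_len(pack$n)) {
    lb <- pack$L[b]
    out[seq_len(lb), b] <- M[b, pack$widx[seq_len(lb), b]]
  }
  out
}

log_train_line <- function(con, stage, iteration, loss) {
  if (is.null(con)) return(invisible())
  writeLines(jsonlite::toJSON(
    list(stage = stage, iteration = iteration, loss = loss),
    auto_unbox = TRUE, digits = NA), con)
}

#' Self-supervised encoder pretraining
#'
#' Optimizes the causal masked-attention encoder and the next-value
#' regression head by minimizing the mean squared error of predicting, at
#' every observed week that has a later observed week, the next observed
#' HbA1c value. Missing slots never contribute to the loss; adding sentinel
#' values at missing slots changes the loss by exactly zero. Adam with a
#' fixed iteration budget and no early stopping; minibatches are sampled
#' uniformly with replacement under the given seed, so identical calls give
#' identical weights.
#'
#' @param instances An `instance_set` (labels unused at this stage).
#' @param config A [model_config()].
#' @param seed Integer seed controlling initialization and batch sampling.
#' @param model Optional existing `glyc_transformer` to continue training.
#' @param log_every Record the running loss every this many iterations.
#' @param log_file Optional path for a JSON-lines training log.
#' @return The model with pretrained encoder weights and a `history$pretrain`
#'   data.frame of `(iteration, loss)`.
#' @export
pretrain_self_supervised <- function(instances, config, seed = 1L,
                                     model = NULL, log_every = 100L,
                                     log_file = NULL) {
  vm <- as_value_mask(instances)
  tgt <- ssl_targets(vm$values, vm$observed)
  usable <- which(rowSums(!is.na(tgt)) > 0L)
  if (length(usable) == 0L) {
    stop("pretraining requires at least one instance with two or more ",
         "observed values", call. = FALSE)
  }
  if (is.null(model)) model <- transformer_init(config, seed)
  cfg <- model$config
  params <- model$params
  opt <- adam_init(params[encoder_param_names(params)])
  set.seed(seed)
  con <- if (!is.null(log_file)) file(log_file, "w") else NULL
  if (!is.null(con)) on.exit(close(con))
  losses <- data.frame(iteration = integer(0), loss = numeric(0))

  for (it in seq_len(cfg$iterations)) {
    idx <- usable[sample.int(length(usable), min(cfg$batch_size,
                                                 length(usable)),
                             replace = TRUE)]
    bv <- vm$values[idx, , drop = FALSE]
    bm <- vm$observed[idx, , drop = FALSE]
    fwd <- encoder_fwd(params, cfg, bv, bm, causal = TRUE, keep_cache = TRUE,
                       dropout_active = TRUE)
    pk <- fwd$pack
    Yc <- lin(fwd$states, params$reg_w, params$reg_b)   # Lmax x 1 x B
    yhat <- matrix(Yc, nrow = pk$Lmax, ncol = pk$n)
    bt <- pack_matrix(tgt[idx, , drop = FALSE], pk)
    valid <- !is.na(bt)
    nv <- sum(valid)
    resid <- matrix(0, pk$Lmax, pk$n)
    resid[valid] <- yhat[valid] - bt[valid]
    loss <- sum(resid^2) / nv
    dY <- array(2 * resid / nv, dim = c(pk$Lmax, 1L, pk$n))
    grads <- list(
      reg_w = gx_cube_linear_dW(fwd$states, dY),
      reg_b = sum(dY)
    )
    dStates <- lin(dY, t(params$reg_w))
    grads <- c(grads, encoder_bwd(params, cfg, dStates, fwd))
    step <- adam_step(params, grads, opt, cfg$learning_rate)
    params <- step$params
    opt <- step$state
    if (it %% log_every == 0L || it == 1L || it == cfg$iterations) {
      losses <- rbind(losses, data.frame(iteration = it, loss = loss))
      log_train_line(con, "pretrain", it, loss)
    }
  }
  model$params <- params
  model$history$pretrain <- losses
  model
}

#' Supervised training of the classification decoder
#'
#' Minimizes the focal loss of the poor-control probability over labeled
#' instances. By default the pretrained encoder is frozen (its weights are
#' bit-identical before and after) and only the cross-attention decoder,
#' classification query, and output head are trained; set
#' `freeze_encoder = FALSE` for joint fine-tuning. Fixed iteration budget, no
#' early stopping, seeded uniform-with-replacement minibatches.
#'
#' @param instances A labeled `instance_set` containing both classes.
#' @param model A `glyc_transformer` (typically pretrained with
#'   [pretrain_self_supervised()]).
#' @param seed Integer seed for batch sampling.
#' @param freeze_encoder Keep encoder weights fixed (default `TRUE`).
#' @param log_every,log_file As in [pretrain_self_supervised()].
#' @return The model with trained decoder weights and a `history$supervised`
#'   loss trace.
#' @export
train_supervised <- function(instances, model, seed = 1L,
                             freeze_encoder = TRUE, log_every = 100L,
                             log_file = NULL) {
  vm <- as_value_mask(instances)
  y <- as.numeric(instances$label)
  if (all(y > 0.5)) {
    stop("supervised training set has no negative instances", call. = FALSE)
  }
  if (all(y < 0.5)) {
    stop("supervised training set has no positive instances", call. = FALSE)
  }
  cfg <- model$config
  params <- model$params
  n <- nrow(vm$values); W <- ncol(vm$values)
  set.seed(seed)
  con <- if (!is.null(log_file)) file(log_file, "w") else NULL
  if (!is.null(con)) on.exit(close(con))
  losses <- data.frame(iteration = integer(0), loss = numeric(0))

  mem_all <- NULL; key_real_all <- NULL
  if (freeze_encoder) {
    # encoder states are fixed: compute them once for the whole set
    Lg <- max(rowSums(vm$observed))
    mem_all <- array(0, dim = c(Lg, cfg$hidden_size, n))
    key_real_all <- matrix(FALSE, n, Lg)
    for (start in seq(1L, n, by = 512L)) {
      idx <- start:min(start + 511L, n)
      fwd <- encoder_fwd(params, cfg, vm$values[idx, , drop = FALSE],
                         vm$observed[idx, , drop = FALSE], causal = TRUE)
      Lc <- fwd$pack$Lmax
      mem_all[seq_len(Lc), , idx] <- fwd$states
      key_real_all[idx, seq_len(Lc)] <- fwd$pack$key_real
    }
  }

  dec_names <- setdiff(names(params), encoder_param_names(params))
  opt_names <- if (freeze_encoder) dec_names else names(params)
  opt <- adam_init(params[opt_names])

  for (it in seq_len(cfg$iterations)) {
    idx <- sample.int(n, min(cfg$batch_size, n), replace = TRUE)
    if (freeze_encoder) {
      mem <- mem_all[, , idx, drop = FALSE]
      kr <- key_real_all[idx, , drop = FALSE]
      enc <- NULL
    } else {
      enc <- encoder_fwd(params, cfg, vm$values[idx, , drop = FALSE],
                         vm$observed[idx, , drop = FALSE],
                         causal = TRUE, keep_cache = TRUE,
                         dropout_active = TRUE)
      mem <- enc$states
      kr <- enc$pack$key_real
    }
    dec <- decoder_fwd(params, cfg, mem, kr, keep_cache = TRUE,
                       dropout_active = TRUE)
    loss <- focal_loss(dec$prob, y[idx], cfg$focal_gamma, cfg$focal_alpha)
    dlogit <- focal_loss_dlogit(dec$prob, y[idx], cfg$focal_gamma,
                                cfg$focal_alpha)
    bwd <- decoder_bwd(params, cfg, dlogit, dec,
                       need_dmem = !freeze_encoder)
    grads <- bwd$grads
    if (!freeze_encoder) {
      grads <- c(grads, encoder_bwd(params, cfg, bwd$dmem, enc))
    }
    step <- adam_step(params, grads, opt, cfg$learning_rate)
    params <- step$params
    opt <- step$state
    if (it %% log_every == 0L || it == 1L || it == cfg$iterations) {
      losses <- rbind(losses, data.frame(iteration = it, loss = loss))
      log_train_line(con, "supervised", it, loss)
    }
  }
  model$params <- params
  model$history$supervised <- losses
  model
}

#' F1-maximizing decision threshold
#'
#' Scans every distinct score value (plus 0 and 1) as a candidate threshold
#' and returns the one maximizing the F1-score of the decision rule
#' `score >= threshold`; ties are broken toward the higher threshold (fewer
#' positive calls). Intended to be run on training-set scores.
#'
#' @param scores Predicted probabilities.
#' @param labels Binary labels; both classes must be present.
#' @param selected_on Optional identifier of the selection set, stored in the
#'   result.
#' @return A `decision_threshold`: list with `value`, `f1_at_threshold`,
#'   `selected_on`.
#' @examples
#' select_threshold(c(0.1, 0.9), c(0, 1))$value # 0.9
#' @export
select_threshold <- function(scores, labels, selected_on = NA_character_) {
  y <- as.numeric(labels)
  if (all(y > 0.5)) stop("select_threshold: no negative labels", call. = FALSE)
  if (all(y < 0.5)) stop("select_threshold: no positive labels", call. = FALSE)
  if (length(unique(scores)) == 1L) {
    warning("select_threshold: all scores identical; threshold degenerate")
    return(structure(list(value = scores[1L],
                          f1_at_threshold = f1_at(scores, y, scores[1L]),
                          selected_on = selected_on),
                     class = "decision_threshold"))
  }
  cand <- sort(unique(c(scores, 0, 1)))
  f1s <- vapply(cand, function(t) f1_at(scores, y, t), 0)
  best <- max(f1s)
  value <- max(cand[f1s >= best - 1e-12])
  structure(list(value = value, f1_at_threshold = best,
                 selected_on = selected_on),
            class = "decision_threshold")
}

#' End-to-end training pipeline
#'
#' Runs the two training stages on one instance set: self-supervised encoder
#' pretraining, supervised decoder training with the encoder frozen (by
#' default), and F1-maximizing threshold selection on the training scores.
#'
#' @param instances A labeled `instance_set`.
#' @param config A [model_config()].
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param freeze_encoder Passed to [train_supervised()].
#' @param pretrain_iterations,supervised_iterations Optional per-stage
#'   overrides of `config$iterations`.
#' @return A trained `glyc_transformer` with a stored decision threshold.
#' @export
train_glycemic_model <- function(instances, config, seed = 1L,
                                 freeze_encoder = TRUE,
                                 pretrain_iterations = NULL,
                                 supervised_iterations = NULL) {
  cfg_pre <- config
  if (!is.null(pretrain_iterations)) {
    cfg_pre$iterations <- as.integer(pretrain_iterations)
  }
  model <- pretrain_self_supervised(instances, cfg_pre, seed = seed)
  if (!is.null(supervised_iterations)) {
    model$config$iterations <- as.integer(supervised_iterations)
  }
  model <- train_supervised(instances, model, seed = seed + 1L,
                            freeze_encoder = freeze_encoder)
  model$config$iterations <- config$iterations
  scores <- predict(model, instances)
  model$threshold <- select_threshold(scores, instances$label,
                                      selected_on = "training instances")
  model
}
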