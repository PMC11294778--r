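#' Transformer model configuration
#'
#' Hyperparameters of the encoder/decoder attention model. The default
#' (`profile = "paper"`) is the full configuration: 4 encoder layers, 4
#' decoder layers, 4 heads, hidden size 128, feed-forward width 512, Adam at
#' learning rate 1e-4, batch 512, 20,000 iterations without early stopping,
#' focal loss. `profile = "desk"` is a documented scaled-down configuration
#' for laptop-scale experiments and continuous testing: 2 encoder and 2
#' decoder layers, hidden 64, feed-forward 256, batch 64, 2,000 iterations,
#' learning rate 1e-3 (standard small-batch rescaling).
#'
#' @param encoder_layers,decoder_layers Number of attention blocks.
#' @param heads Attention heads; must divide `hidden_size`.
#' @param hidden_size Model width (token dimension).
#' @param ffn_hidden Feed-forward inner width.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size (sampled uniformly with replacement).
#' @param iterations Fixed optimization budget; no early stopping.
#' @param focal_gamma Focal-loss focusing exponent (>= 0; 0 recovers
#'   cross-entropy).
#' @param focal_alpha Focal-loss scale in (0, 1].
#' @param dropout Dropout rate on the residual branches during training
#'   (default 0; inference is always deterministic).
#' @param profile Optional shorthand, `"paper"` or `"desk"`; explicit
#'   arguments override the profile.
#' @return A `model_config` object.
#' @export
model_config <- function(encoder_layers = 4L, decoder_layers = 4L,
                         heads = 4L, hidden_size = 128L, ffn_hidden = 512L,
                         learning_rate = 1e-4, batch_size = 512L,
                         iterations = 20000L, focal_gamma = 2.0,
                         focal_alpha = 0.25, dropout = 0.0,
                         profile = NULL) {
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("paper", "desk"))
    if (profile == "desk") {
      defaults <- list(encoder_layers = 2L, decoder_layers = 2L, heads = 4L,
                       hidden_size = 64L, ffn_hidden = 256L,
                       learning_rate = 1e-3, batch_size = 64L,
                       iterations = 2000L)
      supplied <- names(match.call())[-1]
      for (nm in names(defaults)) {
        if (!(nm %in% supplied)) assign(nm, defaults[[nm]])
      }
    }
  }
  cfg <- list(encoder_layers = as.integer(encoder_layers),
              decoder_layers = as.integer(decoder_layers),
              heads = as.integer(heads),
              hidden_size = as.integer(hidden_size),
              ffn_hidden = as.integer(ffn_hidden),
              learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              iterations = as.integer(iterations),
              focal_gamma = focal_gamma, focal_alpha = focal_alpha,
              dropout = dropout)
  stopifnot(cfg$hidden_size %% cfg$heads == 0L,
            cfg$encoder_layers >= 1L, cfg$decoder_layers >= 1L,
            cfg$heads >= 1L, cfg$iterations >= 1L, cfg$batch_size >= 1L,
            cfg$focal_gamma >= 0, cfg$focal_alpha > 0, cfg$focal_alpha <= 1,
            cfg$dropout >= 0, cfg$dropout < 1)
  structure(cfg, class = "model_config")
}

# Sinusoidal positional encoding over week index (0-based), W x H.
# Non-learned, so the same model accepts any input width.
pos_encoding <- function(W, H) {
  pos <- seq_len(W) - 1L
  pe <- matrix(0, W, H)
  for (i in seq_len(H %/% 2)) {
    freq <- 1 / 10000^((2 * (i - 1)) / H)
    pe[, 2 * i - 1] <- sin(pos * freq)
    pe[, 2 * i] <- cos(pos * freq)
  }
  pe
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize a transformer model
#'
#' Creates a `glyc_transformer` object with Glorot-uniform weights under a
#' fixed seed. The parameter count does not depend on the input width (the
#' positional encoding is fixed sinusoidal), so one model accepts histories
#' of any length.
#'
#' @param config A [model_config()].
#' @param seed Integer RNG seed for the initialization.
#' @return A `glyc_transformer`: list with `params` (flat named list of
#'   arrays), `config`, and `threshold` (`NULL` until selected).
#' @export
transformer_init <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  set.seed(seed)
  H <- config$hidden_size; FF <- config$ffn_hidden
  p <- list()
  p$emb_w <- glorot(1L, H)
  p$emb_b <- numeric(H)
  attn_block <- function(prefix) {
    b <- list()
    b[[paste0(prefix, "_ln1_g")]] <- rep(1, H)
    b[[paste0(prefix, "_ln1_b")]] <- numeric(H)
    for (nm in c("Wq", "Wk", "Wv", "Wo")) {
      b[[paste0(prefix, "_", nm)]] <- glorot(H, H)
    }
    for (nm in c("bq", "bk", "bv", "bo")) {
      b[[paste0(prefix, "_", nm)]] <- numeric(H)
    }
    b[[paste0(prefix, "_ln2_g")]] <- rep(1, H)
    b[[paste0(prefix, "_ln2_b")]] <- numeric(H)
    b[[paste0(prefix, "_W1")]] <- glorot(H, FF)
    b[[paste0(prefix, "_b1")]] <- numeric(FF)
    b[[paste0(prefix, "_W2")]] <- glorot(FF, H)
    b[[paste0(prefix, "_b2")]] <- numeric(H)
    b
  }
  for (l in seq_len(config$encoder_layers)) {
    p <- c(p, attn_block(paste0("enc", l)))
  }
  p$enc_lnf_g <- rep(1, H); p$enc_lnf_b <- numeric(H)
  p$reg_w <- glorot(H, 1L); p$reg_b <- 0
  p$dec_query <- rnorm(H, 0, 0.02)
  for (l in seq_len(config$decoder_layers)) {
    p <- c(p, attn_block(paste0("dec", l)))
  }
  p$dec_lnf_g <- rep(1, H); p$dec_lnf_b <- numeric(H)
  p$cls_w <- glorot(H, 1L); p$cls_b <- 0
  structure(list(params = p, config = config, threshold = NULL,
                 history = list()),
            class = "glyc_transformer")
}

#' @export
print.glyc_transformer <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, length, 0L))
  cat(sprintf(
    "glyc_transformer: %d+%d layers, %d heads, hidden %d, %s parameters\n",
    cfg$encoder_layers, cfg$decoder_layers, cfg$heads, cfg$hidden_size,
    format(n_par, big.mark = ",")))
  if (!is.null(x$threshold)) {
    cat(sprintf("  decision threshold: %.4f (F1 %.3f on selection set)\n",
                x$threshold$value, x$threshold$f1_at_threshold))
  }
  stages <- names(x$history)
  if (length(stages)) cat("  trained stages:", paste(stages, collapse = ", "), "\n")
  invisible(x)
}

#' Softmax restricted to unmasked entries
#'
#' Computes softmax weights over a score vector with masked entries receiving
#' weight exactly 0 and the remaining weights summing to 1. This is the
#' scalar-reference form of the attention masking used throughout the model
#' ("key padding"): missing weeks are excluded from attention entirely rather
#' than imputed.
#'
#' @param scores Numeric vector of attention scores.
#' @param mask Logical vector, `TRUE` where the entry is masked (ignored).
#' @return Numeric weight vector: zeros at masked entries, softmax over the
#'   rest.
#' @examples
#' masked_softmax(c(0, log(3)), c(FALSE, FALSE)) # 0.25, 0.75
#' @export
masked_softmax <- function(scores, mask) {
  stopifnot(length(scores) == length(mask))
  if (all(mask)) stop("masked_softmax: all entries are masked", call. = FALSE)
  w <- numeric(length(scores))
  s <- scores[!mask]
  e <- exp(s - max(s))
  w[!mask] <- e / sum(e)
  w
}

# ---- internal batched forward machinery ------------------------------------

# values: n x W with NA at missing; observed: n x W logical.
# Returns cube W x 1 x n of values with missing slots replaced by 0 before
# any computation (so sentinel content can never propagate).
values_cube <- function(values, observed) {
  n <- nrow(values); W <- ncol(values)
  v <- ifelse(observed, values, 0)
  v[is.na(v)] <- 0
  array(t(v), dim = c(W, 1L, n))
}

# Pack each instance's observed weeks into a dense prefix. Because masked
# slots can never influence any output (their attention weight is exactly 0
# and every op is position-wise), computing on observed positions only is
# mathematically identical to the full grid and roughly (W / L)^2 cheaper in
# attention. Week indices are kept for positional encoding and causal order.
pack_instances <- function(values, observed) {
  n <- nrow(values); W <- ncol(values)
  L <- as.integer(rowSums(observed))
  Lmax <- max(L)
  widx <- matrix(1L, Lmax, n)
  pv <- matrix(0, Lmax, n)
  key_real <- matrix(FALSE, n, Lmax)
  v <- values; v[!observed] <- 0; v[is.na(v)] <- 0
  for (b in seq_len(n)) {
    obs <- which(observed[b, ])
    widx[seq_len(L[b]), b] <- obs
    pv[seq_len(L[b]), b] <- v[b, obs]
    key_real[b, seq_len(L[b])] <- TRUE
  }
  list(n = n, W = W, L = L, Lmax = Lmax, widx = widx, pv = pv,
       key_real = key_real)
}

# Positional encodings gathered at packed week indices: Lmax x H x n cube.
packed_pe <- function(pack, H) {
  pe <- pos_encoding(pack$W, H)
  M <- pe[as.vector(pack$widx), , drop = FALSE]
  aperm(array(M, dim = c(pack$Lmax, pack$n, H)), c(1, 3, 2))
}

# Additive mask over packed positions: padding columns forbidden everywhere;
# packed week order is strictly increasing, so the causal constraint is
# exactly the lower triangle.
packed_amask <- function(pack, causal = TRUE) {
  Lmax <- pack$Lmax
  base <- matrix(0, Lmax, Lmax)
  if (causal) base[row(base) < col(base)] <- -Inf
  m <- array(base, dim = c(Lmax, Lmax, pack$n))
  for (b in seq_len(pack$n)) {
    if (pack$L[b] < Lmax) m[, (pack$L[b] + 1L):Lmax, b] <- -Inf
  }
  m
}

# Additive mask for a query of length n_query over keys given by a logical
# validity matrix (n x Lk).
key_amask <- function(key_real, n_query = 1L) {
  n <- nrow(key_real); Lk <- ncol(key_real)
  kp <- ifelse(t(key_real), 0, -Inf)        # Lk x n
  m <- array(0, dim = c(n_query, Lk, n))
  for (b in seq_len(n)) {
    m[, , b] <- matrix(kp[, b], n_query, Lk, byrow = TRUE)
  }
  m
}

# Scatter packed states (Lmax x H x n) back onto the weekly grid
# (W x H x n); missing weeks carry zero states (they are never attended).
scatter_states <- function(states, pack) {
  out <- array(0, dim = c(pack$W, dim(states)[2], pack$n))
  for (b in seq_len(pack$n)) {
    lb <- pack$L[b]
    out[pack$widx[seq_len(lb), b], , b] <- states[seq_len(lb), , b]
  }
  out
}

lin <- function(X, W, b = NULL) {
  if (is.null(b)) b <- numeric(ncol(W))
  gx_cube_linear(X, W, b)
}

# One pre-norm attention block (self- or cross-attention) with caches.
# X: query cube (Wq x H x n); mem: key/value cube (Wk x H x n) or NULL for
# self-attention; amask: additive mask (Wq x Wk x n).
attn_block_fwd <- function(p, prefix, X, mem, amask, heads, keep_cache,
                           drop_mask = NULL) {
  g <- function(nm) p[[paste0(prefix, "_", nm)]]
  dh <- ncol(g("Wq")) / heads
  ln1 <- gx_layernorm_fwd(X, g("ln1_g"), g("ln1_b"), 1e-5)
  kv_in <- if (is.null(mem)) ln1$y else mem
  Q <- lin(ln1$y, g("Wq"), g("bq"))
  K <- lin(kv_in, g("Wk"), g("bk"))
  V <- lin(kv_in, g("Wv"), g("bv"))
  Qh <- gx_split_heads(Q, heads)
  Kh <- gx_split_heads(K, heads)
  Vh <- gx_split_heads(V, heads)
  S <- gx_bmm(Qh, Kh, FALSE, TRUE) / sqrt(dh)
  A <- gx_masked_softmax(S, amask, heads)
  Ctx <- gx_bmm(A, Vh)
  Cm <- gx_merge_heads(Ctx, heads)
  O <- lin(Cm, g("Wo"), g("bo"))
  if (!is.null(drop_mask)) O <- O * drop_mask$attn
  X2 <- X + O
  ln2 <- gx_layernorm_fwd(X2, g("ln2_g"), g("ln2_b"), 1e-5)
  H1 <- lin(ln2$y, g("W1"), g("b1"))
  R <- pmax(H1, 0)
  F2 <- lin(R, g("W2"), g("b2"))
  if (!is.null(drop_mask)) F2 <- F2 * drop_mask$ffn
  out <- X2 + F2
  cache <- NULL
  if (keep_cache) {
    cache <- list(X = X, ln1 = ln1, kv_in = kv_in, Qh = Qh, Kh = Kh, Vh = Vh,
                  A = A, Cm = Cm, X2 = X2, ln2 = ln2, H1 = H1, R = R,
                  dh = dh, drop_mask = drop_mask, self = is.null(mem))
  }
  list(out = out, A = A, cache = cache)
}

# Backward of attn_block_fwd. Returns list(dX, dmem, grads named list).
attn_block_bwd <- function(p, prefix, dOut, cache, heads) {
  g <- function(nm) p[[paste0(prefix, "_", nm)]]
  gr <- list()
  dm <- cache$drop_mask
  # FFN branch
  dF2 <- if (is.null(dm)) dOut else dOut * dm$ffn
  gr[[paste0(prefix, "_W2")]] <- gx_cube_linear_dW(cache$R, dF2)
  gr[[paste0(prefix, "_b2")]] <- as.numeric(gx_cube_colsums(dF2))
  dR <- lin(dF2, t(g("W2")))
  dH1 <- dR * (cache$H1 > 0)
  gr[[paste0(prefix, "_W1")]] <- gx_cube_linear_dW(cache$ln2$y, dH1)
  gr[[paste0(prefix, "_b1")]] <- as.numeric(gx_cube_colsums(dH1))
  dln2y <- lin(dH1, t(g("W1")))
  ln2b <- gx_layernorm_bwd(dln2y, cache$ln2$xhat, cache$ln2$rstd, g("ln2_g"))
  gr[[paste0(prefix, "_ln2_g")]] <- as.numeric(ln2b$dgamma)
  gr[[paste0(prefix, "_ln2_b")]] <- as.numeric(ln2b$dbeta)
  dX2 <- dOut + ln2b$dx
  # attention branch
  dO <- if (is.null(dm)) dX2 else dX2 * dm$attn
  gr[[paste0(prefix, "_Wo")]] <- gx_cube_linear_dW(cache$Cm, dO)
  gr[[paste0(prefix, "_bo")]] <- as.numeric(gx_cube_colsums(dO))
  dCm <- lin(dO, t(g("Wo")))
  dCtx <- gx_split_heads(dCm, heads)
  dA <- gx_bmm(dCtx, cache$Vh, FALSE, TRUE)
  dVh <- gx_bmm(cache$A, dCtx, TRUE, FALSE)
  dS <- gx_softmax_bwd(cache$A, dA) / sqrt(cache$dh)
  dQh <- gx_bmm(dS, cache$Kh)
  dKh <- gx_bmm(dS, cache$Qh, TRUE, FALSE)
  dQ <- gx_merge_heads(dQh, heads)
  dK <- gx_merge_heads(dKh, heads)
  dV <- gx_merge_heads(dVh, heads)
  gr[[paste0(prefix, "_Wq")]] <- gx_cube_linear_dW(cache$ln1$y, dQ)
  gr[[paste0(prefix, "_bq")]] <- as.numeric(gx_cube_colsums(dQ))
  gr[[paste0(prefix, "_Wk")]] <- gx_cube_linear_dW(cache$kv_in, dK)
  gr[[paste0(prefix, "_bk")]] <- as.numeric(gx_cube_colsums(dK))
  gr[[paste0(prefix, "_Wv")]] <- gx_cube_linear_dW(cache$kv_in, dV)
  gr[[paste0(prefix, "_bv")]] <- as.numeric(gx_cube_colsums(dV))
  dln1y <- lin(dQ, t(g("Wq")))
  dkv <- lin(dK, t(g("Wk"))) + lin(dV, t(g("Wv")))
  dmem <- NULL
  if (cache$self) dln1y <- dln1y + dkv else dmem <- dkv
  ln1b <- gx_layernorm_bwd(dln1y, cache$ln1$xhat, cache$ln1$rstd, g("ln1_g"))
  gr[[paste0(prefix, "_ln1_g")]] <- as.numeric(ln1b$dgamma)
  gr[[paste0(prefix, "_ln1_b")]] <- as.numeric(ln1b$dbeta)
  dX <- dX2 + ln1b$dx
  list(dX = dX, dmem = dmem, grads = gr)
}

# Full encoder pass. Returns encoder states (post final layer norm), caches,
# and per-layer attention cubes.
# Computation happens in packed space (observed weeks only); `states` is
# Lmax x H x n and `pack` maps packed positions back to weekly slots.
encoder_fwd <- function(params, cfg, values, observed, causal = TRUE,
                        keep_cache = FALSE, collect_attention = FALSE,
                        dropout_active = FALSE) {
  n <- nrow(values)
  if (n == 0L) stop("encoder: empty instance batch", call. = FALSE)
  if (any(rowSums(observed) == 0L)) {
    stop("encoder: no observed values in at least one series", call. = FALSE)
  }
  pack <- pack_instances(values, observed)
  Vc <- array(pack$pv, dim = c(pack$Lmax, 1L, n))
  X <- lin(Vc, params$emb_w, params$emb_b)
  X <- X + packed_pe(pack, cfg$hidden_size)
  amask <- packed_amask(pack, causal = causal)
  caches <- list(); attn <- list()
  for (l in seq_len(cfg$encoder_layers)) {
    dm <- NULL
    if (dropout_active && cfg$dropout > 0) {
      dm <- draw_drop_mask(cfg$dropout, dim(X))
    }
    blk <- attn_block_fwd(params, paste0("enc", l), X, NULL, amask,
                          cfg$heads, keep_cache, dm)
    X <- blk$out
    if (keep_cache) caches[[l]] <- blk$cache
    if (collect_attention) attn[[l]] <- blk$A
  }
  lnf <- gx_layernorm_fwd(X, params$enc_lnf_g, params$enc_lnf_b, 1e-5)
  list(states = lnf$y, pack = pack, lnf = if (keep_cache) lnf else NULL,
       caches = caches, attention = attn, Vc = if (keep_cache) Vc else NULL)
}

encoder_bwd <- function(params, cfg, dStates, fwd) {
  gr <- list()
  lnfb <- gx_layernorm_bwd(dStates, fwd$lnf$xhat, fwd$lnf$rstd,
                           params$enc_lnf_g)
  gr$enc_lnf_g <- as.numeric(lnfb$dgamma)
  gr$enc_lnf_b <- as.numeric(lnfb$dbeta)
  dX <- lnfb$dx
  for (l in rev(seq_len(cfg$encoder_layers))) {
    blk <- attn_block_bwd(params, paste0("enc", l), dX, fwd$caches[[l]],
                          cfg$heads)
    dX <- blk$dX
    gr <- c(gr, blk$grads)
  }
  gr$emb_w <- gx_cube_linear_dW(fwd$Vc, dX)
  gr$emb_b <- as.numeric(gx_cube_colsums(dX))
  gr
}

# Decoder pass over encoder memory. mem: Lk x H x n cube; key_real: n x Lk
# logical marking valid key positions (packed validity or the weekly
# observed mask, depending on the memory layout supplied).
decoder_fwd <- function(params, cfg, mem, key_real, keep_cache = FALSE,
                        collect_attention = FALSE, dropout_active = FALSE) {
  n <- dim(mem)[3]; H <- cfg$hidden_size
  Tq <- array(rep(params$dec_query, times = n), dim = c(1L, H, n))
  amask <- key_amask(key_real, n_query = 1L)
  caches <- list(); attn <- list()
  for (l in seq_len(cfg$decoder_layers)) {
    dm <- NULL
    if (dropout_active && cfg$dropout > 0) {
      dm <- draw_drop_mask(cfg$dropout, dim(Tq))
    }
    blk <- attn_block_fwd(params, paste0("dec", l), Tq, mem, amask,
                          cfg$heads, keep_cache, dm)
    Tq <- blk$out
    if (keep_cache) caches[[l]] <- blk$cache
    if (collect_attention) attn[[l]] <- blk$A
  }
  lnf <- gx_layernorm_fwd(Tq, params$dec_lnf_g, params$dec_lnf_b, 1e-5)
  tok <- matrix(lnf$y, nrow = H, ncol = n)          # 1 x H x n -> H x n
  logit <- as.numeric(crossprod(tok, params$cls_w)) + params$cls_b
  prob <- 1 / (1 + exp(-logit))
  list(prob = prob, logit = logit, tok = tok,
       lnf = if (keep_cache) lnf else NULL, caches = caches,
       attention = attn)
}

decoder_bwd <- function(params, cfg, dlogit, fwd, need_dmem = FALSE) {
  n <- length(dlogit); H <- cfg$hidden_size
  gr <- list()
  gr$cls_w <- matrix(fwd$tok %*% dlogit, ncol = 1L)
  gr$cls_b <- sum(dlogit)
  dtok <- params$cls_w %*% matrix(dlogit, nrow = 1L)   # H x n
  dlnf <- array(dtok, dim = c(1L, H, n))
  lnfb <- gx_layernorm_bwd(dlnf, fwd$lnf$xhat, fwd$lnf$rstd, params$dec_lnf_g)
  gr$dec_lnf_g <- as.numeric(lnfb$dgamma)
  gr$dec_lnf_b <- as.numeric(lnfb$dbeta)
  dT <- lnfb$dx
  dmem <- NULL
  for (l in rev(seq_len(cfg$decoder_layers))) {
    blk <- attn_block_bwd(params, paste0("dec", l), dT, fwd$caches[[l]],
                          cfg$heads)
    dT <- blk$dX
    gr <- c(gr, blk$grads)
    if (need_dmem) {
      dmem <- if (is.null(dmem)) blk$dmem else dmem + blk$dmem
    }
  }
  gr$dec_query <- rowSums(matrix(dT, nrow = H, ncol = dim(dT)[3]))
  list(grads = gr, dmem = dmem)
}

# ---- exported forward API ---------------------------------------------------

as_value_mask <- function(instances) {
  if (inherits(instances, "instance_set")) {
    list(values = instances$values, observed = instances$observed)
  } else if (inherits(instances, "weekly_series")) {
    list(values = matrix(instances$values, 1L),
         observed = matrix(instances$observed, 1L))
  } else {
    stop("expected an instance_set or weekly_series", call. = FALSE)
  }
}

#' Embed a weekly series into the token space
#'
#' Each observed weekly slot is mapped to a token: a linear projection of the
#' scalar HbA1c value plus the fixed sinusoidal positional encoding of the
#' week index. Missing slots are flagged in the key-padding mask; their
#' values are replaced by zero before the projection, so sentinel content
#' can never reach the model.
#'
#' @param series A `weekly_series` (see [quantize_weekly()]).
#' @param model A `glyc_transformer`.
#' @return List with `embeddings` (W x hidden matrix) and
#'   `key_padding_mask` (logical, `TRUE` = missing/ignored).
#' @export
embed_series <- function(series, model) {
  vm <- as_value_mask(series)
  if (!any(vm$observed)) {
    stop("embed_series: no observed values", call. = FALSE)
  }
  cfg <- model$config
  Vc <- values_cube(vm$values, vm$observed)
  X <- lin(Vc, model$params$emb_w, model$params$emb_b)
  W <- ncol(vm$values)
  E <- X[, , 1] + pos_encoding(W, cfg$hidden_size)
  list(embeddings = E, key_padding_mask = !vm$observed[1L, ])
}

#' Run the encoder over a batch of instances
#'
#' Applies the masked self-attention encoder. With `causal = TRUE` (the
#' default, used in both training stages) position `t` can attend only to
#' unmasked positions at weeks `<= t`; missing weeks receive self-attention
#' weight exactly 0 everywhere.
#'
#' @param model A `glyc_transformer`.
#' @param instances An `instance_set` (or single `weekly_series`).
#' @param causal Apply the causal mask (default `TRUE`).
#' @param collect_attention Also return per-layer attention cubes
#'   (`W x W x (n*heads)`; slice `(b-1)*heads + j` is instance `b`, head `j`).
#' @return List with `states` (`W x hidden x n` array) and, if requested,
#'   `attention` (list over layers).
#' @export
encoder_forward <- function(model, instances, causal = TRUE,
                            collect_attention = FALSE) {
  vm <- as_value_mask(instances)
  fwd <- encoder_fwd(model$params, model$config, vm$values, vm$observed,
                     causal = causal, collect_attention = collect_attention)
  attn <- NULL
  if (collect_attention) {
    attn <- lapply(fwd$attention, scatter_self_attention,
                   pack = fwd$pack, heads = model$config$heads)
  }
  list(states = scatter_states(fwd$states, fwd$pack), attention = attn)
}

# Scatter a packed self-attention cube (Lmax x Lmax x n*heads) onto the
# weekly grid (W x W x n*heads); masked rows/columns are exactly 0.
scatter_self_attention <- function(A, pack, heads) {
  out <- array(0, dim = c(pack$W, pack$W, pack$n * heads))
  for (b in seq_len(pack$n)) {
    obs <- pack$widx[seq_len(pack$L[b]), b]
    for (j in seq_len(heads)) {
      s <- (b - 1L) * heads + j
      out[obs, obs, s] <- A[seq_along(obs), seq_along(obs), s]
    }
  }
  out
}

# Scatter packed cross-attention (1 x Lmax x n*heads) onto the weekly grid.
scatter_cross_attention <- function(A, pack, heads) {
  out <- array(0, dim = c(1L, pack$W, pack$n * heads))
  for (b in seq_len(pack$n)) {
    obs <- pack$widx[seq_len(pack$L[b]), b]
    for (j in seq_len(heads)) {
      s <- (b - 1L) * heads + j
      out[1L, obs, s] <- A[1L, seq_along(obs), s]
    }
  }
  out
}

#' Run the classification decoder over encoder states
#'
#' A single learned classification query cross-attends to the encoder states
#' through the decoder blocks; a linear layer plus sigmoid yields the
#' probability of poor glycemic control. Missing weeks receive cross-attention
#' weight exactly 0.
#'
#' @param model A `glyc_transformer`.
#' @param encoder_states `W x hidden x n` array from [encoder_forward()].
#' @param observed `n x W` logical matrix of observed slots.
#' @param collect_attention Also return per-layer cross-attention cubes
#'   (`1 x W x (n*heads)`).
#' @return List with `prob` (length-n vector in `[0,1]`) and, if requested,
#'   `attention`.
#' @export
decoder_forward <- function(model, encoder_states, observed,
                            collect_attention = FALSE) {
  fwd <- decoder_fwd(model$params, model$config, encoder_states, observed,
                     collect_attention = collect_attention)
  list(prob = fwd$prob, attention = fwd$attention)
}

# Inverted-dropout mask pair for one block's residual branches.
draw_drop_mask <- function(rate, dims) {
  keep <- 1 - rate
  list(attn = array(stats::rbinom(prod(dims), 1L, keep) / keep, dim = dims),
       ffn = array(stats::rbinom(prod(dims), 1L, keep) / keep, dim = dims))
}

#' Next-value regression head
#'
#' Projects each encoder state to a scalar prediction of the next observed
#' HbA1c value after that week. Because the encoder is causal, the prediction
#' at week `t` uses only information from weeks `<= t`. This head is the
#' self-supervised pretraining target.
#'
#' @param model A `glyc_transformer`.
#' @param encoder_states `W x hidden x n` array from a causal
#'   [encoder_forward()].
#' @return `n x W` matrix of predicted HbA1c values.
#' @export
regression_head <- function(model, encoder_states) {
  Y <- lin(encoder_states, model$params$reg_w, model$params$reg_b)
  t(matrix(Y, nrow = dim(Y)[1], ncol = dim(Y)[3]))
}

#' Focal loss for binary classification
#'
#' `FL = -alpha * (1 - p_t)^gamma * log(p_t)` with `p_t = p` for positive
#' labels and `1 - p` for negative ones; `gamma = 0, alpha = 1` recovers
#' binary cross-entropy. Probabilities are clamped to `[1e-7, 1 - 1e-7]`.
#'
#' @param p Predicted probabilities.
#' @param y Binary labels (0/1 or logical).
#' @param gamma Focusing exponent (>= 0).
#' @param alpha Scale in (0, 1].
#' @param reduce `"mean"` (batch mean, default) or `"none"` (per-element).
#' @return Nonnegative loss value(s).
#' @examples
#' focal_loss(0.5, 1, gamma = 0, alpha = 1) # log(2)
#' @export
focal_loss <- function(p, y, gamma = 2.0, alpha = 0.25,
                       reduce = c("mean", "none")) {
  reduce <- match.arg(reduce)
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  y <- as.numeric(y)
  pt <- ifelse(y > 0.5, p, 1 - p)
  fl <- -alpha * (1 - pt)^gamma * log(pt)
  if (reduce == "mean") mean(fl) else fl
}

# d(mean focal loss)/d(logit), used by the supervised stage.
focal_loss_dlogit <- function(p, y, gamma, alpha) {
  eps <- 1e-7
  pc <- pmin(pmax(p, eps), 1 - eps)
  y <- as.numeric(y)
  pt <- ifelse(y > 0.5, pc, 1 - pc)
  # dFL/dpt = -alpha * ( -gamma (1-pt)^(gamma-1) log(pt) + (1-pt)^gamma / pt )
  # (1-pt >= eps by clamping, so the gamma < 1 exponent stays finite)
  dpt <- if (gamma == 0) {
    -alpha / pt
  } else {
    -alpha * (-gamma * (1 - pt)^(gamma - 1) * log(pt) + (1 - pt)^gamma / pt)
  }
  # dpt/dlogit = pt(1-pt) * (+1 for y=1, ... symmetric in pt)
  dlogit <- dpt * pt * (1 - pt) * ifelse(y > 0.5, 1, -1)
  dlogit / length(p)
}

#' Score instances with a trained model
#'
#' Runs the causal encoder and the cross-attention decoder in deterministic
#' inference mode (no dropout). With `type = "class"` the stored
#' F1-maximizing decision threshold is applied (`score >= threshold` is a
#' positive call).
#'
#' @param object A `glyc_transformer`.
#' @param instances An `instance_set`.
#' @param type `"prob"` (default) or `"class"`.
#' @param chunk_size Instances per forward chunk (memory control).
#' @param ... Unused.
#' @return Numeric probabilities, or 0/1 integer decisions for
#'   `type = "class"`.
#' @export
predict.glyc_transformer <- function(object, instances, type = "prob",
                                     chunk_size = 512L, ...) {
  vm <- as_value_mask(instances)
  n <- nrow(vm$values)
  probs <- numeric(n)
  for (start in seq(1L, n, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, n)
    enc <- encoder_fwd(object$params, object$config,
                       vm$values[idx, , drop = FALSE],
                       vm$observed[idx, , drop = FALSE], causal = TRUE)
    dec <- decoder_fwd(object$params, object$config, enc$states,
                       enc$pack$key_real)
    probs[idx] <- dec$prob
  }
  if (type == "class") {
    if (is.null(object$threshold)) {
      stop("model has no decision threshold; run select_threshold() first",
           call. = FALSE)
    }
    return(as.integer(probs >= object$threshold$value))
  }
  probs
}
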