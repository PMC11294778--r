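# Head- and layer-averaged attention summaries for a batch, computed in
# chunks so that raw per-head maps never accumulate across a large set.
attention_summaries <- function(model, instances, chunk_size = 256L) {
  vm <- as_value_mask(instances)
  n <- nrow(vm$values); W <- ncol(vm$values)
  heads <- model$config$heads
  self_sal <- matrix(0, n, W)
  cross <- matrix(0, n, W)
  for (start in seq(1L, n, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, n)
    enc <- encoder_fwd(model$params, model$config,
                       vm$values[idx, , drop = FALSE],
                       vm$observed[idx, , drop = FALSE], causal = TRUE,
                       collect_attention = TRUE)
    dec <- decoder_fwd(model$params, model$config, enc$states,
                       enc$pack$key_real, collect_attention = TRUE)
    pk <- enc$pack
    for (j in seq_along(idx)) {
      b <- idx[j]
      lb <- pk$L[j]
      obs <- pk$widx[seq_len(lb), j]
      slices <- (j - 1L) * heads + seq_len(heads)
      # self-attention: average map over heads and layers, then mean
      # attention received per key week over unmasked query rows
      M <- matrix(0, lb, lb)
      for (l in seq_along(enc$attention)) {
        for (s in slices) M <- M + enc$attention[[l]][seq_len(lb),
                                                      seq_len(lb), s]
      }
      M <- M / (length(enc$attention) * heads)
      self_sal[b, obs] <- colMeans(M)
      # cross-attention: head/layer mean of the classification query row
      cw <- numeric(lb)
      for (l in seq_along(dec$attention)) {
        for (s in slices) cw <- cw + dec$attention[[l]][1, seq_len(lb), s]
      }
      cross[b, obs] <- cw / (length(dec$attention) * heads)
    }
  }
  list(self_salience = self_sal, cross_attention = cross,
       observed = vm$observed, values = vm$values)
}

#' Extract per-instance attention weights
#'
#' Runs a trained model over instances and returns, per instance, the
#' aggregated attention summaries used for interpretation: a per-week
#' self-attention salience (attention received by each week, averaged over
#' heads, layers, and unmasked query rows) and the per-week cross-attention
#' of the classification query (averaged over heads and layers; a
#' probability vector over observed weeks). Raw per-layer, per-head maps are
#' retained when `keep_raw = TRUE`.
#'
#' @param model A trained `glyc_transformer`.
#' @param instances An `instance_set` (one or more rows).
#' @param keep_raw Retain raw per-layer/per-head attention maps (memory
#'   scales with `W^2 * heads * layers` per instance; default `FALSE`).
#' @return A list of `attention_record` objects, one per instance, each with
#'   `self_salience`, `cross_attention` (length-W vectors), `observed`,
#'   `values`, `weeks_before_ref` (W-1 .. 0), and optionally `raw_self`,
#'   `raw_cross`.
#' @export
extract_attention <- function(model, instances, keep_raw = FALSE) {
  sm <- attention_summaries(model, instances)
  n <- nrow(sm$observed); W <- ncol(sm$observed)
  heads <- model$config$heads
  raw <- NULL
  if (keep_raw) {
    vm <- as_value_mask(instances)
    enc <- encoder_fwd(model$params, model$config, vm$values, vm$observed,
                       causal = TRUE, collect_attention = TRUE)
    dec <- decoder_fwd(model$params, model$config, enc$states,
                       enc$pack$key_real, collect_attention = TRUE)
    raw <- list(
      self = lapply(enc$attention, scatter_self_attention,
                    pack = enc$pack, heads = heads),
      cross = lapply(dec$attention, scatter_cross_attention,
                     pack = enc$pack, heads = heads))
  }
  lapply(seq_len(n), function(b) {
    rec <- list(self_salience = sm$self_salience[b, ],
                cross_attention = sm$cross_attention[b, ],
                observed = sm$observed[b, ],
                values = sm$values[b, ],
                weeks_before_ref = rev(seq_len(W)) - 1L)
    if (keep_raw) {
      slices <- (b - 1L) * heads + seq_len(heads)
      rec$raw_self <- lapply(raw$self, function(A) A[, , slices, drop = FALSE])
      rec$raw_cross <- lapply(raw$cross, function(A) A[, , slices, drop = FALSE])
    }
    structure(rec, class = "attention_record")
  })
}

#' Assign instances to model/comparator concordance groups
#'
#' Partitions instances into the four groups used for attention comparison:
#' true positives under both models, true negatives under both, true
#' positives under the transformer that the comparator missed, and false
#' negatives of the transformer that the comparator caught. Instances
#' matching none of the four definitions (e.g. false positives) are left
#' unassigned.
#'
#' @param model_decisions 0/1 decisions of the attention model.
#' @param comparator_decisions 0/1 decisions of the comparator.
#' @param labels True binary outcomes.
#' @return A `concordance_groups` list of index vectors with elements
#'   `TP_both`, `TN_both`, `TP_model_FN_comparator`,
#'   `FN_model_TP_comparator`.
#' @export
assign_groups <- function(model_decisions, comparator_decisions, labels) {
  if (length(model_decisions) != length(labels) ||
      length(comparator_decisions) != length(labels)) {
    stop("assign_groups: decision and label vectors must have equal length",
         call. = FALSE)
  }
  m <- as.numeric(model_decisions) > 0.5
  c_ <- as.numeric(comparator_decisions) > 0.5
  y <- as.numeric(labels) > 0.5
  structure(list(
    TP_both = which(m & c_ & y),
    TN_both = which(!m & !c_ & !y),
    TP_model_FN_comparator = which(m & !c_ & y),
    FN_model_TP_comparator = which(!m & c_ & y)
  ), class = "concordance_groups")
}

#' Group-averaged attention profile
#'
#' Averages HbA1c levels, self-attention salience, and cross-attention
#' weights per weekly slot over the instances of one concordance group.
#' Means are taken only over instances where the slot is observed.
#'
#' @param records List of `attention_record` from [extract_attention()],
#'   parallel to `instances`.
#' @param instances The `instance_set` the records were extracted from.
#' @param group Integer index vector (e.g. one element of
#'   [assign_groups()]), or a group name plus `groups`.
#' @param groups Optional `concordance_groups` when `group` is a name.
#' @return An `attention_profile`: data.frame with columns
#'   `week_before_ref` (0 = most recent), `mean_hba1c`, `mean_self_attn`,
#'   `mean_cross_attn`, `n_observed`; attribute `n_instances`.
#' @export
group_attention_profile <- function(records, instances, group,
                                    groups = NULL) {
  if (is.character(group)) {
    if (is.null(groups)) {
      stop("group_attention_profile: supply `groups` when `group` is a name",
           call. = FALSE)
    }
    idx <- groups[[group]]
    gname <- group
  } else {
    idx <- group
    gname <- "group"
  }
  if (length(idx) == 0L) {
    stop("group_attention_profile: group `", gname, "` is empty",
         call. = FALSE)
  }
  W <- length(records[[1]]$self_salience)
  vals <- do.call(rbind, lapply(records[idx], `[[`, "values"))
  obs <- do.call(rbind, lapply(records[idx], `[[`, "observed"))
  sal <- do.call(rbind, lapply(records[idx], `[[`, "self_salience"))
  crs <- do.call(rbind, lapply(records[idx], `[[`, "cross_attention"))
  obs_mean <- function(M) {
    out <- colSums(ifelse(obs, M, 0)) / pmax(colSums(obs), 1L)
    out[colSums(obs) == 0L] <- NA_real_
    out
  }
  vals[!obs] <- 0
  prof <- data.frame(
    week_before_ref = rev(seq_len(W)) - 1L,
    mean_hba1c = obs_mean(vals),
    mean_self_attn = obs_mean(sal),
    mean_cross_attn = obs_mean(crs),
    n_observed = colSums(obs)
  )
  attr(prof, "n_instances") <- length(idx)
  class(prof) <- c("attention_profile", "data.frame")
  prof
}

#' Write an attention profile as tidy CSV
#'
#' @param profile An `attention_profile`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  df <- as.data.frame(profile)
  names(df) <- c("week_before_ref", "mean_hba1c", "mean_self_attn",
                 "mean_cross_attn", "n")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cross-attention mass on recent versus old observed weeks
#'
#' For one attention record, sums the cross-attention weight over the most
#' recent quarter and the oldest quarter of that instance's observed weeks.
#' Used to quantify whether the model prioritizes recent HbA1c levels.
#'
#' @param record An `attention_record`.
#' @return Named numeric `c(recent, oldest)`.
#' @export
cross_attention_recency <- function(record) {
  obs <- which(record$observed)
  q <- max(1L, length(obs) %/% 4L)
  recent <- sum(record$cross_attention[tail(obs, q)])
  oldest <- sum(record$cross_attention[head(obs, q)])
  c(recent = recent, oldest = oldest)
}

#' Plot an attention profile
#'
#' Three stacked panels: mean HbA1c level, mean self-attention salience, and
#' mean cross-attention weight against weeks before the reference date (time
#' flowing left to right toward the reference).
#'
#' @param x An `attention_profile`.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.attention_profile <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  wk <- -x$week_before_ref
  graphics::plot(wk, x$mean_hba1c, type = "b", pch = 16, cex = 0.5,
                 xlab = "", ylab = "mean HbA1c (%)", ...)
  graphics::abline(h = 8, lty = 2)
  graphics::plot(wk, x$mean_self_attn, type = "h",
                 xlab = "", ylab = "self-attention")
  graphics::plot(wk, x$mean_cross_attn, type = "h",
                 xlab = "weeks before reference", ylab = "cross-attention")
  invisible(x)
}
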