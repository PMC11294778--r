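#' Width of the weekly grid for an N-year history window
#'
#' An N-year history maps to `ceil(N * 365 / 7)` Monday-to-Sunday weekly
#' slots (53 for one year, 261 for five).
#'
#' @param history_years Number of years of history (positive integer).
#' @return Integer number of weekly slots.
#' @export
weekly_grid_width <- function(history_years) {
  stopifnot(history_years >= 1)
  as.integer(ceiling(history_years * 365 / 7))
}

# Monday of the ISO week containing `d` (vectorized).
week_monday <- function(d) {
  d <- as.Date(d)
  d - (as.integer(strftime(d, "%u")) - 1L)
}

#' Quantize one patient's measurements onto a weekly grid
#'
#' Maps irregularly dated measurements to a fixed-length Monday-to-Sunday
#' weekly grid ending at a reference date. Multiple measurements in one week
#' are averaged; weeks with no measurement stay missing. No interpolation,
#' normalization, or outlier handling is applied. The last slot is the week
#' containing the reference date; only measurements dated on or before the
#' reference date enter the grid (later measurements belong to the outcome
#' horizon).
#'
#' @param measurements A data.frame with columns `date` and `hba1c` for a
#'   single patient (rows in any order; measurements outside the window are
#'   ignored).
#' @param window_end Reference date closing the history window.
#' @param history_years Window length N in years; the grid has
#'   [weekly_grid_width()] slots.
#' @param include_reference_week If `FALSE`, measurements falling in the
#'   reference date's own week are excluded from the grid.
#' @return A `weekly_series` object: list with `values` (numeric, `NA` at
#'   missing slots), `observed` (logical), `reference_date`, `history_years`.
#' @examples
#' m <- data.frame(date = as.Date(c("2013-03-04", "2013-03-06")), hba1c = c(7, 8))
#' s <- quantize_weekly(m, window_end = as.Date("2013-03-06"), history_years = 1)
#' s$values[53] # 7.5, the within-week average
#' @export
quantize_weekly <- function(measurements, window_end, history_years = 1L,
                            include_reference_week = TRUE) {
  window_end <- as.Date(window_end)
  W <- weekly_grid_width(history_years)
  d <- as.Date(measurements$date)
  v <- measurements$hba1c
  bad <- which(is.na(d) | is.na(v) | !is.finite(v))
  if (length(bad) > 0L) {
    stop("quantize_weekly: undated or non-finite measurement at row ",
         bad[1L], call. = FALSE)
  }

  ref_monday <- week_monday(window_end)
  keep <- d <= window_end & d > window_end - history_years * 365L
  d <- d[keep]; v <- v[keep]

  values <- rep(NA_real_, W)
  observed <- rep(FALSE, W)
  if (length(d) > 0L) {
    slot <- W - as.integer(ref_monday - week_monday(d)) %/% 7L
    ok <- slot >= 1L & slot <= W
    if (!include_reference_week) ok <- ok & slot < W
    d <- d[ok]; v <- v[ok]; slot <- slot[ok]
    if (length(slot) > 0L) {
      agg <- tapply(v, slot, mean)
      idx <- as.integer(names(agg))
      values[idx] <- as.numeric(agg)
      observed[idx] <- TRUE
    }
  }
  structure(list(values = values, observed = observed,
                 reference_date = window_end,
                 history_years = as.integer(history_years)),
            class = "weekly_series")
}

#' Build labeled prediction instances for a reference year
#'
#' Every HbA1c test date of every patient inside `reference_year` becomes a
#' candidate reference date. Its input is the weekly-quantized history of the
#' preceding `history_years` years; its label is positive when any
#' measurement in the following `horizon_years` (exclusive of the reference
#' date, inclusive at the horizon end) is at or above `threshold` (the
#' comparison is inclusive: a future value of exactly 8.0 is poor control).
#' A patient contributes one instance per in-year test date.
#'
#' Instances whose outcome horizon extends beyond the last recorded date in
#' the data are dropped when `drop_truncated_horizon = TRUE` (their label
#' would be unverifiable), as are degenerate instances with no observed
#' history slot.
#'
#' @param measurements Measurement table for the whole cohort (columns
#'   `patient_id`, `date`, `hba1c`).
#' @param reference_year Calendar year of the reference dates.
#' @param history_years Input window length N (default 1).
#' @param horizon_years Outcome horizon (default 1 year = 365 days).
#' @param threshold Poor-control threshold in percent (default 8.0).
#' @param include_reference_week Passed to [quantize_weekly()].
#' @param drop_truncated_horizon Drop instances whose horizon passes the end
#'   of the data (default `TRUE`).
#' @return An `instance_set`: list with matrices `values` (n x W, `NA` at
#'   missing), `observed` (n x W logical), vectors `label` (logical),
#'   `reference_date`, `patient_id`, and scalars `history_years`,
#'   `horizon_years`, `threshold`.
#' @export
build_instances <- function(measurements, reference_year,
                            history_years = 1L, horizon_years = 1L,
                            threshold = 8.0, include_reference_week = TRUE,
                            drop_truncated_horizon = TRUE) {
  stopifnot(all(c("patient_id", "date", "hba1c") %in% names(measurements)))
  d <- as.Date(measurements$date)
  yrs <- as.integer(format(d, "%Y"))
  if (!(reference_year %in% yrs)) {
    warning("build_instances: reference_year ", reference_year,
            " has no measurements; returning an empty instance set")
    return(empty_instance_set(history_years, horizon_years, threshold))
  }
  last_date <- max(d)
  W <- weekly_grid_width(history_years)
  horizon_days <- as.integer(horizon_years * 365L)

  ord <- order(measurements$patient_id, d)
  pid <- measurements$patient_id[ord]
  dd <- d[ord]
  vv <- measurements$hba1c[ord]

  rows_v <- list(); rows_m <- list()
  lab <- logical(0); refs <- as.Date(character(0)); pids <- character(0)

  for (p in unique(pid)) {
    sel <- pid == p
    pd <- dd[sel]; pv <- vv[sel]
    ref_dates <- pd[as.integer(format(pd, "%Y")) == reference_year]
    ref_dates <- unique(ref_dates)
    for (ref in as.list(ref_dates)) {
      if (drop_truncated_horizon && (ref + horizon_days) > last_date) next
      fut <- pd > ref & pd <= ref + horizon_days
      label <- any(pv[fut] >= threshold)
      ser <- quantize_weekly(data.frame(date = pd, hba1c = pv), ref,
                             history_years, include_reference_week)
      if (!any(ser$observed)) next
      rows_v[[length(rows_v) + 1L]] <- ser$values
      rows_m[[length(rows_m) + 1L]] <- ser$observed
      lab <- c(lab, label)
      refs <- c(refs, ref)
      pids <- c(pids, p)
    }
  }
  if (length(rows_v) == 0L) {
    warning("build_instances: no usable instances in year ", reference_year)
    return(empty_instance_set(history_years, horizon_years, threshold))
  }
  structure(list(
    values = do.call(rbind, rows_v),
    observed = do.call(rbind, rows_m),
    label = lab,
    reference_date = refs,
    patient_id = pids,
    history_years = as.integer(history_years),
    horizon_years = horizon_years,
    threshold = threshold
  ), class = "instance_set")
}

empty_instance_set <- function(history_years, horizon_years, threshold) {
  W <- weekly_grid_width(history_years)
  structure(list(
    values = matrix(numeric(0), 0, W),
    observed = matrix(logical(0), 0, W),
    label = logical(0),
    reference_date = as.Date(character(0)),
    patient_id = character(0),
    history_years = as.integer(history_years),
    horizon_years = horizon_years,
    threshold = threshold
  ), class = "instance_set")
}

#' @export
print.instance_set <- function(x, ...) {
  cat(sprintf(
    "instance_set: %d instances, %d weekly slots (%d-year history), %.1f%% positive\n",
    nrow(x$values), ncol(x$values), x$history_years,
    if (nrow(x$values)) 100 * mean(x$label) else NA_real_))
  invisible(x)
}

#' Subset an instance set
#'
#' @param x An `instance_set`.
#' @param i Row index vector.
#' @param ... Unused.
#' @return The subsetted `instance_set`.
#' @export
`[.instance_set` <- function(x, i, ...) {
  structure(list(
    values = x$values[i, , drop = FALSE],
    observed = x$observed[i, , drop = FALSE],
    label = x$label[i],
    reference_date = x$reference_date[i],
    patient_id = x$patient_id[i],
    history_years = x$history_years,
    horizon_years = x$horizon_years,
    threshold = x$threshold
  ), class = "instance_set")
}

#' Rolling-origin train/test year pairs
#'
#' One split per test year: the model is trained on instances referenced in
#' the preceding calendar year and tested on instances referenced in the test
#' year, sliding both forward one year at a time.
#'
#' @param first_test_year,last_test_year First and last test calendar years.
#' @return A data.frame with columns `train_reference_year` and
#'   `test_reference_year`; empty when `first_test_year > last_test_year`.
#' @examples
#' make_rolling_splits(2008, 2014) # 7 splits
#' @export
make_rolling_splits <- function(first_test_year, last_test_year) {
  if (first_test_year > last_test_year) {
    return(data.frame(train_reference_year = integer(0),
                      test_reference_year = integer(0)))
  }
  test <- seq.int(first_test_year, last_test_year)
  data.frame(train_reference_year = test - 1L, test_reference_year = test)
}

#' Write or read an instance set as CSV
#'
#' Columns: `patient_id`, `reference_date`, `label`, then `value_1..value_W`
#' (empty at missing slots) and `mask_1..mask_W` (0/1). Window metadata is
#' kept in a leading comment line. Round-tripping reproduces values, masks,
#' and labels exactly.
#'
#' @param x An `instance_set`.
#' @param path File path.
#' @return `read_instances` returns the `instance_set`; `write_instances`
#'   returns `path` invisibly.
#' @export
write_instances <- function(x, path) {
  W <- ncol(x$values)
  hdr <- sprintf("# glycattn instances history_years=%d horizon_years=%g threshold=%g",
                 x$history_years, x$horizon_years, x$threshold)
  df <- data.frame(patient_id = x$patient_id,
                   reference_date = format(x$reference_date, "%Y-%m-%d"),
                   label = as.integer(x$label))
  vals <- as.data.frame(x$values)
  names(vals) <- paste0("value_", seq_len(W))
  msk <- as.data.frame(x$observed * 1L)
  names(msk) <- paste0("mask_", seq_len(W))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(cbind(df, vals, msk), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_instances
#' @export
read_instances <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- regmatches(hdr, gregexpr("[a-z_]+=[-0-9.]+", hdr))[[1]]
  kv <- strsplit(meta, "=")
  meta <- stats::setNames(vapply(kv, function(p) as.numeric(p[2]), 0),
                          vapply(kv, function(p) p[1], ""))
  df <- read.csv(path, skip = 1L, stringsAsFactors = FALSE)
  W <- sum(grepl("^value_", names(df)))
  vals <- as.matrix(df[, paste0("value_", seq_len(W))])
  dimnames(vals) <- NULL
  msk <- as.matrix(df[, paste0("mask_", seq_len(W))]) == 1L
  dimnames(msk) <- NULL
  structure(list(
    values = vals,
    observed = msk,
    label = df$label == 1L,
    reference_date = as.Date(df$reference_date),
    patient_id = df$patient_id,
    history_years = as.integer(meta[["history_years"]]),
    horizon_years = meta[["horizon_years"]],
    threshold = meta[["threshold"]]
  ), class = "instance_set")
}
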