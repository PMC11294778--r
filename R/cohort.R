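#' Configuration for the synthetic HbA1c cohort simulator
#'
#' Defines a seeded generative model for longitudinal HbA1c laboratory data
#' emulating a hospital diabetes-clinic regime: each patient carries a latent
#' weekly AR(1) process around an individual set point, with a seasonal
#' component, a slow linear drift, and measurement noise; visit dates follow a
#' gamma renewal process. Defaults reproduce the marginal statistics of a
#' large specialist-care cohort: about 7.7 HbA1c tests per patient-year
#' (SD 2.8), record-level mean 7.1% (SD 1.1).
#'
#' The between-patient spread of set points is derived internally so that the
#' marginal SD of generated records matches `hba1c_sd` given the within-patient
#' process SD, measurement noise, and seasonal amplitude; it is not a free
#' parameter.
#'
#' @param n_patients Number of patients (positive integer).
#' @param start_date,end_date Calendar bounds of the record span (coerced with
#'   [as.Date()]).
#' @param visits_per_year_mean Mean HbA1c tests per patient-year (> 0).
#' @param visits_per_year_sd Target SD of per-year test counts; sets the
#'   default gamma gap shape.
#' @param hba1c_mean Marginal mean HbA1c in percent.
#' @param hba1c_sd Target marginal SD of records in percent (>= 0).
#' @param ar_coefficient AR(1) coefficient of the weekly latent deviation,
#'   in `[0, 1)`.
#' @param process_noise_sd Innovation SD of the AR(1) recursion (% per week).
#' @param seasonal_amplitude Amplitude of the seasonal HbA1c component in
#'   percent (>= 0).
#' @param seasonal_phase Day-of-year at which the seasonal component peaks.
#' @param measurement_noise_sd Assay/reporting noise SD in percent.
#' @param drift_sd SD across patients of a linear drift slope, %/year.
#' @param mu_offset Constant added to every patient set point (steers outcome
#'   prevalence; default 0).
#' @param gap_shape Gamma shape of inter-visit gaps. Default
#'   `visits_per_year_mean / visits_per_year_sd^2` (about 1 at the default
#'   regime), which reproduces the target count SD for a renewal process.
#' @param seed Integer RNG seed; identical config + seed gives byte-identical
#'   cohorts.
#' @return An object of class `cohort_config` (a validated list).
#' @examples
#' cfg <- cohort_config(n_patients = 20, seed = 1)
#' coh <- generate_cohort(cfg)
#' head(coh)
#' @export
cohort_config <- function(n_patients,
                          start_date = "2006-01-01",
                          end_date = "2015-12-31",
                          visits_per_year_mean = 7.7,
                          visits_per_year_sd = 2.8,
                          hba1c_mean = 7.1,
                          hba1c_sd = 1.1,
                          ar_coefficient = 0.9,
                          process_noise_sd = 0.08,
                          seasonal_amplitude = 0.25,
                          seasonal_phase = 45,
                          measurement_noise_sd = 0.08,
                          drift_sd = 0.05,
                          mu_offset = 0,
                          gap_shape = NULL,
                          seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    start_date = as.Date(start_date),
    end_date = as.Date(end_date),
    visits_per_year_mean = visits_per_year_mean,
    visits_per_year_sd = visits_per_year_sd,
    hba1c_mean = hba1c_mean,
    hba1c_sd = hba1c_sd,
    ar_coefficient = ar_coefficient,
    process_noise_sd = process_noise_sd,
    seasonal_amplitude = seasonal_amplitude,
    seasonal_phase = seasonal_phase,
    measurement_noise_sd = measurement_noise_sd,
    drift_sd = drift_sd,
    mu_offset = mu_offset,
    gap_shape = if (is.null(gap_shape)) {
      visits_per_year_mean / visits_per_year_sd^2
    } else {
      gap_shape
    },
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid cohort config: field `", field, "` ", why, call. = FALSE)
  }
  if (is.na(cfg$n_patients) || cfg$n_patients < 1L) {
    fail("n_patients", "must be a positive integer")
  }
  if (is.na(cfg$start_date) || is.na(cfg$end_date) ||
      cfg$end_date <= cfg$start_date) {
    fail("end_date", "must be a date after start_date")
  }
  if (!is.finite(cfg$visits_per_year_mean) || cfg$visits_per_year_mean <= 0) {
    fail("visits_per_year_mean", "must be > 0")
  }
  if (!is.finite(cfg$hba1c_sd) || cfg$hba1c_sd < 0) {
    fail("hba1c_sd", "must be >= 0")
  }
  if (!is.finite(cfg$ar_coefficient) || cfg$ar_coefficient < 0 ||
      cfg$ar_coefficient >= 1) {
    fail("ar_coefficient", "must lie in [0, 1)")
  }
  for (f in c("process_noise_sd", "seasonal_amplitude",
              "measurement_noise_sd", "drift_sd")) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0) fail(f, "must be >= 0")
  }
  if (!is.finite(cfg$gap_shape) || cfg$gap_shape <= 0) {
    fail("gap_shape", "must be > 0")
  }
  # marginal variance budget: between-patient spread must be attainable
  if (between_patient_sd(cfg)^2 < 0) {
    fail("hba1c_sd", paste0(
      "is smaller than the variation implied by process_noise_sd, ",
      "measurement_noise_sd and seasonal_amplitude"))
  }
  invisible(cfg)
}

# Stationary within-patient SD of the AR(1) latent deviation.
within_patient_sd <- function(cfg) {
  cfg$process_noise_sd / sqrt(1 - cfg$ar_coefficient^2)
}

# Between-patient SD of set points, solved so that the marginal record SD
# matches hba1c_sd. Seasonal cosine contributes amplitude^2/2 variance.
between_patient_sd <- function(cfg) {
  v <- cfg$hba1c_sd^2 - within_patient_sd(cfg)^2 -
    cfg$measurement_noise_sd^2 - cfg$seasonal_amplitude^2 / 2
  if (v < 0) {
    stop("invalid cohort config: field `hba1c_sd` is smaller than the ",
         "variation implied by process_noise_sd, measurement_noise_sd and ",
         "seasonal_amplitude", call. = FALSE)
  }
  sqrt(v)
}

#' Generate a synthetic longitudinal HbA1c cohort
#'
#' Simulates one measurement table (`patient_id`, `date`, `hba1c`) under the
#' generative model described in [cohort_config()]: per patient a weekly
#' latent deviation `d_t = a * d_(t-1) + eta_t`, an observation
#' `mu_i + slope_i * years + seasonal(day of year) + d_t + noise`, and visit
#' dates from a gamma renewal process (at most one visit per calendar day;
#' several visits may fall in one Monday-Sunday week).
#'
#' @param config A [cohort_config()] object.
#' @return A `data.frame` with columns `patient_id` (character), `date`
#'   (`Date`), `hba1c` (percent), sorted by patient and date.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    config <- do.call(cohort_config, as.list(config))
  }
  validate_cohort_config(config)
  cfg <- config
  set.seed(cfg$seed)

  span_days <- as.integer(cfg$end_date - cfg$start_date)
  n_weeks <- ceiling(span_days / 7) + 1L
  sd_between <- between_patient_sd(cfg)
  sd_within <- within_patient_sd(cfg)
  mean_gap_days <- 365.25 / cfg$visits_per_year_mean

  out <- vector("list", cfg$n_patients)
  for (i in seq_len(cfg$n_patients)) {
    mu <- cfg$hba1c_mean + cfg$mu_offset + rnorm(1L, 0, sd_between)
    slope <- rnorm(1L, 0, cfg$drift_sd)

    # latent weekly AR(1) deviation, started at its stationary distribution
    innov <- rnorm(n_weeks, 0, cfg$process_noise_sd)
    d0 <- rnorm(1L, 0, sd_within)
    dev <- as.numeric(stats::filter(innov, cfg$ar_coefficient,
                                    method = "recursive", init = d0))

    # renewal visit process, rounded to whole days, at most one per day
    n_draw <- max(8L, ceiling(2 * span_days / mean_gap_days) + 8L)
    gaps <- rgamma(n_draw, shape = cfg$gap_shape,
                   scale = mean_gap_days / cfg$gap_shape)
    t_days <- cumsum(pmax(1, round(gaps)))
    # renewal draws rarely fall short of the span; extend if they do
    while (t_days[length(t_days)] <= span_days) {
      extra <- rgamma(n_draw, shape = cfg$gap_shape,
                      scale = mean_gap_days / cfg$gap_shape)
      t_days <- c(t_days, t_days[length(t_days)] +
                    cumsum(pmax(1, round(extra))))
    }
    t_days <- unique(t_days[t_days <= span_days])
    if (length(t_days) == 0L) next
    dates <- cfg$start_date + t_days

    week_idx <- pmin(n_weeks, t_days %/% 7 + 1L)
    doy <- as.integer(strftime(dates, "%j"))
    seasonal <- cfg$seasonal_amplitude *
      cos(2 * pi * (doy - cfg$seasonal_phase) / 365.25)
    years <- t_days / 365.25
    value <- mu + slope * years + seasonal + dev[week_idx] +
      rnorm(length(t_days), 0, cfg$measurement_noise_sd)
    value <- pmin(pmax(value, 0.1), 19.9)

    out[[i]] <- data.frame(
      patient_id = sprintf("P%05d", i),
      date = dates,
      hba1c = value,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize a measurement table
#'
#' Computes the record- and patient-level descriptive statistics used to
#' characterize an HbA1c cohort: counts, marginal mean/SD, the fraction of
#' records at or above 8% (the poor-control threshold), the fraction of
#' patients ever at or above 8%, and tests per patient-year.
#'
#' Tests per year are counted per patient over complete calendar years inside
#' the observed date span (zero-count years included); if the span contains
#' no complete year, the overall rate `records / span-in-years` is reported
#' and the SD is `NA`.
#'
#' @param measurements A data.frame with columns `patient_id`, `date`,
#'   `hba1c`.
#' @param threshold Poor-control threshold in percent (default 8; the
#'   comparison is inclusive, `>=`).
#' @return An object of class `cohort_summary`: a list with elements
#'   `n_patients`, `n_records`, `hba1c_mean`, `hba1c_sd`,
#'   `frac_records_ge_threshold`, `frac_patients_ever_ge_threshold`,
#'   `tests_per_year_mean`, `tests_per_year_sd`, `threshold`.
#' @export
cohort_summary <- function(measurements, threshold = 8.0) {
  if (is.null(measurements) || nrow(measurements) == 0L) {
    stop("cohort_summary: no measurements supplied", call. = FALSE)
  }
  stopifnot(all(c("patient_id", "date", "hba1c") %in% names(measurements)))
  v <- measurements$hba1c
  d <- as.Date(measurements$date)
  pid <- measurements$patient_id

  ge <- v >= threshold
  ever <- tapply(ge, pid, any)

  years <- as.integer(format(d, "%Y"))
  complete <- seq.int(min(years), max(years))
  complete <- complete[as.Date(sprintf("%d-01-01", complete)) >= min(d) &
                         as.Date(sprintf("%d-12-31", complete)) <= max(d)]
  if (length(complete) >= 1L) {
    tab <- table(factor(pid), factor(years, levels = complete))
    counts <- as.vector(tab)
    tpy_mean <- mean(counts)
    tpy_sd <- sd(counts)
  } else {
    span_years <- max(1L, as.integer(max(d) - min(d))) / 365.25
    tpy_mean <- length(v) / length(unique(pid)) / span_years
    tpy_sd <- NA_real_
  }

  structure(list(
    n_patients = length(unique(pid)),
    n_records = length(v),
    hba1c_mean = mean(v),
    hba1c_sd = sd(v),
    frac_records_ge_threshold = mean(ge),
    frac_patients_ever_ge_threshold = mean(ever),
    tests_per_year_mean = tpy_mean,
    tests_per_year_sd = tpy_sd,
    threshold = threshold
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("HbA1c cohort summary\n")
  cat(sprintf("  patients: %d   records: %d\n", x$n_patients, x$n_records))
  cat(sprintf("  HbA1c mean (SD): %.2f (%.2f) %%\n", x$hba1c_mean, x$hba1c_sd))
  cat(sprintf("  records >= %.1f%%: %.2f%%\n", x$threshold,
              100 * x$frac_records_ge_threshold))
  cat(sprintf("  patients ever >= %.1f%%: %.2f%%\n", x$threshold,
              100 * x$frac_patients_ever_ge_threshold))
  cat(sprintf("  tests per patient-year, mean (SD): %.1f (%.1f)\n",
              x$tests_per_year_mean, x$tests_per_year_sd))
  invisible(x)
}

#' Expected weekly-grid missingness at a given testing rate
#'
#' With `r` tests per patient-year spread over the `ceil(365/7) = 53` weekly
#' slots of a one-year grid, the expected fraction of empty (missing) slots is
#' `1 - r / 53` when each test occupies its own week.
#'
#' @param tests_per_year Tests per patient-year.
#' @return Expected missing fraction in `[0, 1]`.
#' @examples
#' expected_weekly_missingness(7.7) # ~0.855
#' @export
expected_weekly_missingness <- function(tests_per_year) {
  1 - tests_per_year / weekly_grid_width(1L)
}

#' Read or write a cohort measurement table as CSV
#'
#' The on-disk dialect is a plain CSV with header `patient_id,date,hba1c` and
#' ISO-8601 dates.
#'
#' @param measurements A cohort `data.frame` (see [generate_cohort()]).
#' @param path File path.
#' @return `read_cohort_csv` returns the measurement `data.frame`;
#'   `write_cohort_csv` returns `path` invisibly.
#' @export
write_cohort_csv <- function(measurements, path) {
  df <- data.frame(
    patient_id = measurements$patient_id,
    date = format(as.Date(measurements$date), "%Y-%m-%d"),
    hba1c = measurements$hba1c
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("patient_id", "date", "hba1c") %in% names(df)))
  df$date <- as.Date(df$date)
  df
}
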