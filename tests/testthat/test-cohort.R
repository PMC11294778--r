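test_that("invalid configs are rejected with the offending field named", {
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(10, visits_per_year_mean = 0),
               "visits_per_year_mean")
  expect_error(cohort_config(10, ar_coefficient = 1), "ar_coefficient")
  expect_error(cohort_config(10, ar_coefficient = -0.1), "ar_coefficient")
  expect_error(cohort_config(10, hba1c_sd = -1), "hba1c_sd")
  expect_error(cohort_config(10, start_date = "2010-01-01",
                             end_date = "2009-01-01"), "end_date")
  # variance budget: marginal SD too small for the noise components
  expect_error(cohort_config(10, hba1c_sd = 0.05), "hba1c_sd")
})

test_that("generation is reproducible under a seed and varies across seeds", {
  a <- small_cohort(n = 15, seed = 42)
  b <- small_cohort(n = 15, seed = 42)
  c <- small_cohort(n = 15, seed = 43)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("measurements respect date bounds, ordering, and value range", {
  coh <- small_cohort(n = 25, seed = 7)
  expect_true(all(coh$date >= as.Date("2009-01-01")))
  expect_true(all(coh$date <= as.Date("2012-12-31")))
  expect_true(all(coh$hba1c > 0 & coh$hba1c < 20))
  by_pat <- split(coh$date, coh$patient_id)
  expect_true(all(vapply(by_pat, function(d) !is.unsorted(d, strictly = TRUE),
                         TRUE)))
})

test_that("with all stochastic components off, values are set point plus drift", {
  coh <- generate_cohort(cohort_config(
    n_patients = 8, start_date = "2009-01-01", end_date = "2011-12-31",
    seasonal_amplitude = 0, measurement_noise_sd = 0, ar_coefficient = 0,
    process_noise_sd = 0, drift_sd = 0.4, seed = 5))
  # per patient the values must lie exactly on a line in time
  for (p in unique(coh$patient_id)) {
    sub <- coh[coh$patient_id == p, ]
    t <- as.numeric(sub$date)
    if (nrow(sub) < 3) next
    fit <- stats::lm(hba1c ~ t, data = sub)
    expect_lt(max(abs(stats::residuals(fit))), 1e-8)
  }
  # and with drift off too, constant at the set point
  coh0 <- generate_cohort(cohort_config(
    n_patients = 5, start_date = "2009-01-01", end_date = "2010-12-31",
    seasonal_amplitude = 0, measurement_noise_sd = 0, ar_coefficient = 0,
    process_noise_sd = 0, drift_sd = 0, seed = 6))
  spread <- tapply(coh0$hba1c, coh0$patient_id, function(v) diff(range(v)))
  expect_true(all(spread < 1e-10))
})

test_that("the seasonal component is exactly the configured cosine", {
  coh <- generate_cohort(cohort_config(
    n_patients = 12, start_date = "2009-01-01", end_date = "2010-12-31",
    measurement_noise_sd = 0, ar_coefficient = 0, process_noise_sd = 0,
    drift_sd = 0, seasonal_amplitude = 0.5, seasonal_phase = 45, seed = 9))
  # with every other component off, value - set point is the seasonal term;
  # remove the (unknown) set point per patient via the de-seasonalized mean
  doy <- as.integer(strftime(coh$date, "%j"))
  seas <- 0.5 * cos(2 * pi * (doy - 45) / 365.25)
  resid <- coh$hba1c - seas
  spread <- tapply(resid, coh$patient_id, function(v) diff(range(v)))
  expect_true(all(spread < 1e-10))
})

test_that("empirical visit rate and HbA1c mean match the configured regime", {
  coh <- small_cohort(n = 500, seed = 11, start = "2008-01-01",
                      end = "2012-12-31")
  s <- cohort_summary(coh)
  expect_gt(s$tests_per_year_mean, 7.4)
  expect_lt(s$tests_per_year_mean, 8.0)
  expect_gt(s$hba1c_mean, 7.0)
  expect_lt(s$hba1c_mean, 7.2)
  expect_gt(s$hba1c_sd, 0.95)
  expect_lt(s$hba1c_sd, 1.25)
})

test_that("weekly missingness after quantization is near the analytic rate", {
  coh <- small_cohort(n = 300, seed = 13, start = "2009-01-01",
                      end = "2012-12-31")
  inst <- build_instances(coh, 2011)
  expect_lt(abs(mean(!inst$observed) - expected_weekly_missingness(7.7)),
            0.02)
})

test_that("cohort_summary arithmetic on forced inputs", {
  one <- data.frame(patient_id = "A", date = as.Date("2010-05-03"),
                    hba1c = 8.0)
  s1 <- cohort_summary(one)
  expect_equal(s1$frac_records_ge_threshold, 1.0)  # >= is inclusive
  two <- data.frame(patient_id = c("A", "B"),
                    date = as.Date(c("2010-05-03", "2010-06-03")),
                    hba1c = c(7.0, 9.0))
  s2 <- cohort_summary(two)
  expect_equal(s2$hba1c_mean, 8.0)
  expect_equal(s2$frac_records_ge_threshold, 0.5)
  expect_equal(s2$frac_patients_ever_ge_threshold, 0.5)
  expect_error(cohort_summary(two[0, ]), "no measurements")
})

test_that("cohort CSV round-trips", {
  coh <- small_cohort(n = 5, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, path)
  back <- read_cohort_csv(path)
  expect_equal(back$patient_id, coh$patient_id)
  expect_equal(back$date, coh$date)
  expect_equal(back$hba1c, coh$hba1c, tolerance = 1e-12)
})
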