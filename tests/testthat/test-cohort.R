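test_that("cohort generation is seeded, sized and demographically calibrated", {
  expect_length(generate_cohort(cohort_spec(n_athletes = 0)), 0)

  c1 <- generate_cohort(cohort_spec(n_athletes = 5, seed = 11))
  c2 <- generate_cohort(cohort_spec(n_athletes = 5, seed = 11))
  expect_equal(profiles_to_table(c1), profiles_to_table(c2))

  big <- generate_cohort(cohort_spec(n_athletes = 10000, seed = 1))
  frac_male <- mean(vapply(big, function(p) p$sex == "M", logical(1)))
  expect_lt(abs(frac_male - 245 / 338), 0.02)
  ages <- vapply(big, `[[`, numeric(1), "age")
  expect_lt(abs(mean(ages) - 23.1), 0.2)

  expect_error(cohort_spec(sport_mix = c(soccer = 0.5, tennis = 0.4)),
               class = "loadctrl_config_error")
})

test_that("generated dynamics constants always satisfy the profile invariants", {
  for (s in seq_len(25)) {
    cohort <- generate_cohort(cohort_spec(n_athletes = 8, seed = s))
    for (p in cohort) {
      expect_gt(p$k_accum, 0)
      expect_gt(p$k_recover, 0)
      expect_gte(p$k_active, 0)
      expect_gt(p$adapt_coeff, 0)
      expect_gt(p$adapt_rate, 0)
      expect_gte(p$fatigue_sens, 0)
      for (cp in p$compartments) {
        expect_gt(cp$tau, 0)
        expect_gte(cp$r_max, 0)
      }
      expect_true(p$preferred_load >= 0 && p$preferred_load <= 1)
      expect_true(p$phenotype %in% phenotype_levels())
    }
  }
})

test_that("the sensor observation model degrades data as configured", {
  truth <- tibble::tibble(hrv = rnorm(1e5, 70, 8), rpe = runif(1e5, 0, 10))

  # all rates zero: identity
  ident <- sensor_observe(truth, noise_model(0, 0, 0), rng_stream(1))
  expect_identical(ident, truth)

  obs <- sensor_observe(truth, noise_model(sd_frac = 0.02,
                                           missing_rate = 0.032,
                                           outlier_rate = 0),
                        rng_stream(2))
  miss <- mean(is.na(obs$hrv))
  ci <- qbinom(c(0.0005, 0.9995), 1e5, 0.032) / 1e5
  expect_gt(miss, ci[1])
  expect_lt(miss, ci[2])
  # unbiased noise: observed mean approaches the true mean
  expect_lt(abs(mean(obs$hrv, na.rm = TRUE) - mean(truth$hrv)), 0.1)

  out <- sensor_observe(truth, noise_model(0, 0, outlier_rate = 0.01,
                                           outlier_scale = 6),
                        rng_stream(3))
  displaced <- abs(out$hrv - truth$hrv) > 3 * sd(truth$hrv)
  expect_gt(mean(displaced), 0.005)
})

test_that("the three-sigma rule flags exactly the right values", {
  expect_false(any(flag_outliers(c(5, 5, 5), athlete_mean = 5, athlete_sd = 1)))
  expect_true(flag_outliers(9, athlete_mean = 5, athlete_sd = 1))
  expect_identical(flag_outliers(c(5, 20, 5), 5, 0), rep(FALSE, 3))
  flags <- flag_outliers(c(5, 5 + 3.1, 5 - 3.1, NA), 5, 1)
  expect_identical(flags, c(FALSE, TRUE, TRUE, FALSE))
})

test_that("imputation fills gaps without touching observed values", {
  daily <- tidyr::expand_grid(athlete_id = c("a", "b"), day = 1:40) |>
    dplyr::mutate(hrv = 70 + day * 0.1 + (athlete_id == "b") * 5,
                  rpe = 5 + sin(day), sleep = 8)
  # no missing: unchanged, nobody excluded
  res0 <- impute_and_qc(daily)
  expect_equal(res0$completed, daily)
  expect_length(res0$excluded, 0)

  # athlete b: 15% missing hrv -> excluded; athlete a: one sleep gap imputed
  # to the constant
  holed <- daily
  holed$hrv[holed$athlete_id == "b"][1:6] <- NA
  holed$sleep[5] <- NA
  res <- impute_and_qc(holed)
  expect_identical(res$excluded, "b")
  expect_true(all(res$completed$athlete_id == "a"))
  expect_equal(res$completed$sleep[5], 8)
  # observed cells unaltered
  obs_idx <- which(!is.na(holed$sleep) & holed$athlete_id == "a")
  expect_identical(res$completed$sleep[obs_idx],
                   daily$sleep[daily$athlete_id == "a"][obs_idx])

  # exclusion is invariant to row order
  shuffled <- holed[rev(seq_len(nrow(holed))), ]
  expect_identical(impute_and_qc(shuffled)$excluded, "b")

  all_na <- daily
  all_na$rpe <- NA_real_
  expect_error(impute_and_qc(all_na), "rpe",
               class = "loadctrl_invalid_input")
})

test_that("regression imputation reconstructs correlated gaps", {
  set.seed(31)
  n <- 200
  x <- rnorm(n, 60, 5)
  daily <- tibble::tibble(athlete_id = "a", day = seq_len(n),
                          hrv = x, rec = 0.5 * x + rnorm(n, 0, 0.5))
  holed <- daily
  gap <- sample(n, 10)
  holed$rec[gap] <- NA
  res <- impute_and_qc(holed)
  # chained regression uses hrv to predict rec far better than the mean would
  err_model <- mean(abs(res$completed$rec[gap] - daily$rec[gap]))
  err_mean <- mean(abs(mean(daily$rec[-gap]) - daily$rec[gap]))
  expect_lt(err_model, err_mean / 2)
})

test_that("simulated daily logs have the athlete-day schema with missingness", {
  cohort <- fixture_cohort(2)
  logs <- simulate_daily_logs(cohort, seed = 5)
  expect_equal(nrow(logs), 2 * 112)
  expect_true(all(c("athlete_id", "day", "tl", "performance", "injured",
                    "hr_rest", "hrv", "rpe", "sleep", "soreness")
                  %in% names(logs)))
  miss <- mean(is.na(logs$hrv))
  expect_gt(miss, 0)
  logs2 <- simulate_daily_logs(cohort, seed = 5)
  expect_identical(logs, logs2)
})
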