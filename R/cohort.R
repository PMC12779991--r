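# Seeded synthetic-athlete cohort generator: demographics matching the study
# cohort structure, per-phenotype dynamics constants, a sensor observation
# model with noise / missingness / outliers, outlier flagging and the
# imputation + exclusion quality-control pipeline.

#' Cohort specification
#'
#' Defaults mirror the study cohort structure: 338 athletes across seven
#' sport disciplines (soccer 68/338, basketball 60/338, ...), age 23.1 +/-
#' 3.2 years, 245/338 male, training experience 7.3 +/- 2.5 years, and a
#' phenotype mix over the eight phenotype categories.
#'
#' @param n_athletes Number of athletes to generate.
#' @param sport_mix Named proportions over sports (must sum to 1).
#' @param age_mean,age_sd Age distribution (years).
#' @param sex_ratio_male Fraction male.
#' @param experience_mean,experience_sd Training experience (years).
#' @param phenotype_mix Named proportions over [phenotype_levels()].
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_athletes = 10L,
                        sport_mix = c(track_sprints = 45, track_distance = 52,
                                      swimming_sprint = 38, swimming_distance = 41,
                                      basketball = 60, soccer = 68,
                                      tennis = 34) / 338,
                        age_mean = 23.1, age_sd = 3.2,
                        sex_ratio_male = 245 / 338,
                        experience_mean = 7.3, experience_sd = 2.5,
                        phenotype_mix = c(Endurance = 0.20, Power = 0.10,
                                          Speed = 0.15, Strength = 0.10,
                                          Technical = 0.10, Mixed = 0.20,
                                          Novice = 0.05, Elite = 0.10),
                        seed = 1L) {
  if (n_athletes < 0) abort("n_athletes must be >= 0", class = "loadctrl_config_error")
  for (nm in c("sport_mix", "phenotype_mix")) {
    v <- get(nm)
    if (any(v < 0) || abs(sum(v) - 1) > 1e-9) {
      abort(sprintf("`%s` proportions must be nonnegative and sum to 1", nm),
            class = "loadctrl_config_error")
    }
  }
  structure(list(n_athletes = as.integer(n_athletes), sport_mix = sport_mix,
                 age_mean = age_mean, age_sd = age_sd,
                 sex_ratio_male = sex_ratio_male,
                 experience_mean = experience_mean,
                 experience_sd = experience_sd,
                 phenotype_mix = phenotype_mix, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Per-phenotype dynamics-constant ranges
#'
#' One editable block of plausible defaults: for each phenotype, uniform
#' sampling ranges for the adaptation coefficient/rate, fatigue sensitivity,
#' the fatigue ODE rates and the fast/slow recovery-compartment time
#' constants. These are modelling defaults, not physiologically validated
#' human constants.
#'
#' @return A tibble with one row per phenotype and `*_lo` / `*_hi` columns.
#' @export
phenotype_dynamics <- function() {
  base <- tibble(
    phenotype = phenotype_levels(),
    adapt_coeff_lo = c(1.0, 1.1, 1.1, 1.0, 0.9, 1.0, 0.8, 1.2),
    adapt_coeff_hi = c(1.3, 1.5, 1.5, 1.4, 1.2, 1.3, 1.1, 1.6),
    adapt_rate_lo  = c(1.8, 2.0, 2.2, 1.9, 1.6, 1.8, 1.4, 2.2),
    adapt_rate_hi  = c(2.4, 2.8, 3.0, 2.6, 2.2, 2.4, 2.0, 3.0),
    fatigue_sens_lo = c(0.03, 0.05, 0.05, 0.04, 0.03, 0.04, 0.05, 0.03),
    fatigue_sens_hi = c(0.06, 0.09, 0.09, 0.07, 0.06, 0.07, 0.09, 0.06),
    k_accum_lo = c(0.8, 1.0, 1.0, 0.9, 0.8, 0.9, 1.0, 0.8),
    k_accum_hi = c(1.1, 1.4, 1.4, 1.2, 1.1, 1.2, 1.4, 1.1),
    k_recover_lo = c(0.25, 0.20, 0.20, 0.22, 0.22, 0.22, 0.18, 0.28),
    k_recover_hi = c(0.35, 0.28, 0.28, 0.30, 0.30, 0.30, 0.25, 0.38),
    k_active_lo = c(0.25, 0.20, 0.20, 0.22, 0.22, 0.22, 0.18, 0.28),
    k_active_hi = c(0.40, 0.32, 0.32, 0.35, 0.35, 0.35, 0.28, 0.45),
    tau_fast_lo = c(1.0, 1.2, 1.2, 1.1, 1.1, 1.1, 1.4, 0.9),
    tau_fast_hi = c(1.8, 2.2, 2.2, 2.0, 2.0, 2.0, 2.6, 1.6),
    tau_slow_lo = c(3.0, 3.5, 3.5, 3.2, 3.2, 3.2, 4.0, 2.8),
    tau_slow_hi = c(5.0, 6.0, 6.0, 5.5, 5.5, 5.5, 7.0, 4.5)
  )
  base
}

#' Generate a seeded synthetic cohort
#'
#' Samples demographics from the specification's distributions, assigns
#' phenotypes, and draws each athlete's dynamics constants uniformly from the
#' per-phenotype ranges in [phenotype_dynamics()]. Deterministic per seed.
#'
#' @param spec A [cohort_spec()].
#' @return A list of [athlete_profile()] objects; each additionally carries
#'   `age`, `sex`, `sport`, `experience` fields.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_athletes = 3, seed = 7))
#' length(cohort)
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  if (spec$n_athletes == 0L) return(list())
  stream <- rng_stream(spec$seed)
  dyn <- phenotype_dynamics()
  with_stream(stream, {
    sports <- sample(names(spec$sport_mix), spec$n_athletes, replace = TRUE,
                     prob = spec$sport_mix)
    phenos <- sample(names(spec$phenotype_mix), spec$n_athletes, replace = TRUE,
                     prob = spec$phenotype_mix)
    ages <- pmax(16, rnorm(spec$n_athletes, spec$age_mean, spec$age_sd))
    male <- runif(spec$n_athletes) < spec$sex_ratio_male
    expr <- pmax(0.5, rnorm(spec$n_athletes, spec$experience_mean,
                            spec$experience_sd))
    purrr::map(seq_len(spec$n_athletes), function(i) {
      d <- dyn[dyn$phenotype == phenos[i], ]
      u <- function(lo, hi) runif(1, lo, hi)
      hist_feats <- clip01(rnorm(2, mean = min(expr[i] / 15, 0.9), sd = 0.1))
      p <- athlete_profile(
        genetic = runif(2, 0.2, 0.9),
        history = hist_feats,
        anthro = runif(2, 0.3, 0.8),
        baseline_fitness = runif(2, 0.3, 0.9),
        adapt_coeff = u(d$adapt_coeff_lo, d$adapt_coeff_hi),
        adapt_rate = u(d$adapt_rate_lo, d$adapt_rate_hi),
        fatigue_sens = u(d$fatigue_sens_lo, d$fatigue_sens_hi),
        k_accum = u(d$k_accum_lo, d$k_accum_hi),
        k_recover = u(d$k_recover_lo, d$k_recover_hi),
        k_active = u(d$k_active_lo, d$k_active_hi),
        compartments = list(
          list(r_max = u(0.5, 0.7), tau = u(d$tau_fast_lo, d$tau_fast_hi)),
          list(r_max = u(0.3, 0.5), tau = u(d$tau_slow_lo, d$tau_slow_hi))
        ),
        phenotype = phenos[i],
        baseline_performance = rnorm(1, 100, 5),
        preferred_load = 0.35 + 0.3 * mean(hist_feats),
        athlete_id = sprintf("athlete_%03d", i)
      )
      p$age <- ages[i]
      p$sex <- if (male[i]) "M" else "F"
      p$sport <- sports[i]
      p$experience <- expr[i]
      p
    })
  })
}

#' Sensor noise model
#'
#' @param sd_frac Gaussian noise SD as a fraction of each variable's observed
#'   range.
#' @param missing_rate Independent per-value missingness probability
#'   (default 0.032, the study-wide average missing fraction).
#' @param outlier_rate Per-value probability of an injected outlier.
#' @param outlier_scale Outlier displacement in units of the variable's SD.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(sd_frac = 0.05, missing_rate = 0.032,
                        outlier_rate = 0.005, outlier_scale = 6) {
  for (r in c(missing_rate, outlier_rate)) check_range(r, "rate", 0, 1)
  structure(list(sd_frac = sd_frac, missing_rate = missing_rate,
                 outlier_rate = outlier_rate, outlier_scale = outlier_scale),
            class = "noise_model")
}

#' Apply the sensor observation model to true daily features
#'
#' Adds independent Gaussian noise (SD a fraction of each variable's range),
#' injects outliers (displaced by `outlier_scale` SDs, random sign), and
#' masks values as missing. Identity when all rates are zero.
#'
#' @param true_features Tibble/data frame of numeric variables (one row per
#'   athlete-day); non-numeric columns pass through untouched.
#' @param noise A [noise_model()].
#' @param stream An [rng_stream()].
#' @return A tibble of the same shape with `NA` marking missing values.
#' @export
sensor_observe <- function(true_features, noise = noise_model(), stream) {
  out <- as_tibble(true_features)
  num_cols <- names(out)[vapply(out, is.numeric, logical(1))]
  for (nm in num_cols) {
    x <- out[[nm]]
    n <- length(x)
    rng <- diff(range(x))
    s <- sd(x)
    with_stream(stream, {
      if (noise$sd_frac > 0 && rng > 0) {
        x <- x + rnorm(n, 0, noise$sd_frac * rng)
      }
      if (noise$outlier_rate > 0 && s > 0) {
        hit <- runif(n) < noise$outlier_rate
        x[hit] <- x[hit] + sample(c(-1, 1), sum(hit), replace = TRUE) *
          noise$outlier_scale * s
      }
      if (noise$missing_rate > 0) {
        x[runif(n) < noise$missing_rate] <- NA_real_
      }
    })
    out[[nm]] <- x
  }
  out
}

#' Flag values beyond three athlete-level standard deviations
#'
#' @param series Numeric vector.
#' @param athlete_mean,athlete_sd The athlete's own mean and SD for the
#'   variable; `athlete_sd = 0` yields no flags (documented convention).
#' @return Logical flag vector (`NA` values are never flagged).
#' @export
flag_outliers <- function(series, athlete_mean, athlete_sd) {
  if (athlete_sd < 0) abort("athlete_sd must be >= 0", class = "loadctrl_invalid_input")
  if (athlete_sd == 0) return(rep(FALSE, length(series)))
  out <- abs(series - athlete_mean) > 3 * athlete_sd
  out[is.na(out)] <- FALSE
  out
}

#' Impute missing values and apply the exclusion rule
#'
#' Athletes with more than 10% missing values on any variable are excluded
#' (and listed). Remaining gaps are filled by single-pass chained linear
#' regression: each variable with gaps is regressed on the other variables
#' over originally observed rows (after an athlete-mean initialization) and
#' its missing entries replaced by predictions; isolated columns fall back to
#' the athlete mean. Observed cells are never altered.
#'
#' @param daily Tibble with `athlete_id`, `day` and numeric variable columns.
#' @param missing_cap Per-athlete, per-variable missingness threshold for
#'   exclusion.
#' @return A list with `completed` (imputed tibble of retained athletes) and
#'   `excluded` (character vector of excluded athlete ids).
#' @export
impute_and_qc <- function(daily, missing_cap = 0.10) {
  stopifnot(all(c("athlete_id", "day") %in% names(daily)))
  vars <- setdiff(names(daily)[vapply(daily, is.numeric, logical(1))], "day")
  for (nm in vars) {
    if (all(is.na(daily[[nm]]))) {
      abort(sprintf("variable '%s' is entirely missing", nm),
            class = "loadctrl_invalid_input")
    }
  }
  miss <- daily |>
    dplyr::group_by(athlete_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(vars), ~ mean(is.na(.x))),
                     .groups = "drop")
  worst <- apply(miss[vars], 1, max)
  excluded <- sort(miss$athlete_id[worst > missing_cap])
  kept <- daily[!daily$athlete_id %in% excluded, ]
  if (!nrow(kept)) return(list(completed = kept, excluded = excluded))

  obs_mask <- !is.na(kept[vars])
  # athlete-mean initialization (global mean fallback)
  filled <- kept |>
    dplyr::group_by(athlete_id) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(vars), function(x) {
      m <- mean(x, na.rm = TRUE)
      x[is.na(x)] <- m
      x
    })) |>
    dplyr::ungroup()
  for (nm in vars) {
    x <- filled[[nm]]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    filled[[nm]] <- x
  }
  # single chained pass of regression imputation
  for (nm in vars) {
    gaps <- !obs_mask[, nm]
    if (!any(gaps)) next
    others <- setdiff(vars, nm)
    if (length(others)) {
      df <- filled[vars]
      fit <- tryCatch(
        lm(stats::reformulate(others, response = nm), data = df[obs_mask[, nm], ]),
        error = function(e) NULL)
      if (!is.null(fit)) {
        pred <- predict(fit, newdata = df[gaps, , drop = FALSE])
        ok <- is.finite(pred)
        filled[[nm]][which(gaps)[ok]] <- pred[ok]
      }
    }
  }
  # restore observed cells verbatim
  for (nm in vars) {
    filled[[nm]][obs_mask[, nm]] <- kept[[nm]][obs_mask[, nm]]
  }
  list(completed = filled, excluded = excluded)
}

#' Simulate athlete-day monitoring logs for a cohort
#'
#' Runs each athlete's environment under a policy and passes the latent daily
#' variables through the sensor observation model, producing the athlete-day
#' table consumed by [impute_and_qc()] and the CSV round trip.
#'
#' @param cohort List of [athlete_profile()].
#' @param policy A `loadctrl_policy` (default: linear periodization).
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param env_cfg An [env_config()].
#' @return A tibble with one row per athlete-day: load, physiological
#'   markers (with missingness), performance and injury flags.
#' @export
simulate_daily_logs <- function(cohort, policy = policy_periodization(),
                                noise = noise_model(), seed = 1L,
                                env_cfg = env_config()) {
  stream <- rng_stream(derive_seed(seed, "sensors"))
  logs <- purrr::imap(cohort, function(p, i) {
    env <- training_env(p, config = env_cfg)
    policy_reset(policy, derive_seed(seed, paste0("pol", i)))
    run_episode(env, policy, seed = derive_seed(seed, paste0("log", i)))$log
  })
  latent <- dplyr::bind_rows(logs)
  sensors <- tibble(
    hr_rest = 55 + 3.0 * latent$fatigue,
    hrv = 75 - 8.0 * latent$fatigue,
    rpe = 8.0 * latent$tl + 0.3 * latent$fatigue,
    sleep = 8.0 - 0.25 * latent$fatigue,
    soreness = 1.2 * latent$fatigue + 2.0 * latent$tl
  )
  observed <- sensor_observe(sensors, noise, stream)
  dplyr::bind_cols(
    latent[c("athlete_id", "day", "tl", "performance", "injured")],
    observed
  )
}
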