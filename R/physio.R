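# Deterministic athlete-response mathematics: impulse-response performance
# update, first-order fatigue ODE (forward Euler), and multi-compartment
# exponential recovery.

#' Construct an athlete profile
#'
#' An athlete profile bundles the static characteristic vectors (genetic
#' markers, training-history features, anthropometrics, baseline fitness) with
#' the dynamics constants of the fitness-fatigue-recovery model: the adaptation
#' coefficient and rate of the saturating dose-response term, the fatigue
#' sensitivity of performance, the fatigue accumulation/recovery/active-recovery
#' rate constants, and the recovery compartments (capacity and time constant
#' per physiological system).
#'
#' @param genetic Numeric vector of unitless markers in \[0,1\].
#' @param history Numeric vector of training-history features in \[0,1\].
#' @param anthro Numeric vector of anthropometric features.
#' @param baseline_fitness Numeric vector of baseline fitness indicators in \[0,1\].
#' @param adapt_coeff Positive scalar: adaptation coefficient (performance
#'   units per unit saturated dose).
#' @param adapt_rate Positive scalar: adaptation rate constant per unit load;
#'   controls how quickly the dose-response saturates in training load.
#' @param fatigue_sens Nonnegative scalar: performance loss per unit fatigue.
#' @param k_accum Positive per-day fatigue accumulation rate constant.
#' @param k_recover Positive per-day natural recovery rate constant.
#' @param k_active Nonnegative per-day active-recovery coefficient.
#' @param compartments List of `list(r_max =, tau =)` recovery compartments;
#'   `r_max` nonnegative capacity, `tau` positive time constant in days.
#' @param phenotype Phenotype label (one of [phenotype_levels()]).
#' @param baseline_performance Initial performance in model units.
#' @param preferred_load Daily training load in \[0,1\] the athlete adheres to
#'   best.
#' @param athlete_id Identifier used in logs.
#' @return An object of class `athlete_profile`.
#' @examples
#' p <- athlete_profile()
#' p$k_recover
#' @export
athlete_profile <- function(genetic = c(0.5, 0.5),
                            history = c(0.5, 0.5),
                            anthro = c(0.5, 0.5),
                            baseline_fitness = c(0.5, 0.5),
                            adapt_coeff = 1.0,
                            adapt_rate = 2.0,
                            fatigue_sens = 0.05,
                            k_accum = 1.0,
                            k_recover = 0.25,
                            k_active = 0.30,
                            compartments = list(
                              list(r_max = 0.6, tau = 1.5),
                              list(r_max = 0.4, tau = 4.0)
                            ),
                            phenotype = "Mixed",
                            baseline_performance = 100,
                            preferred_load = 0.5,
                            athlete_id = "athlete_1") {
  for (v in list(genetic, history, anthro, baseline_fitness)) {
    if (!is.numeric(v) || any(!is.finite(v))) {
      abort("profile characteristic vectors must be finite numeric",
            class = "loadctrl_invalid_input")
    }
  }
  check_range(adapt_coeff, "adapt_coeff", lo = .Machine$double.eps)
  check_range(adapt_rate, "adapt_rate", lo = .Machine$double.eps)
  check_range(fatigue_sens, "fatigue_sens", lo = 0)
  check_range(k_accum, "k_accum", lo = .Machine$double.eps)
  check_range(k_recover, "k_recover", lo = .Machine$double.eps)
  check_range(k_active, "k_active", lo = 0)
  check_range(preferred_load, "preferred_load", lo = 0, hi = 1)
  for (cp in compartments) {
    check_range(cp$r_max, "r_max", lo = 0)
    check_range(cp$tau, "tau", lo = .Machine$double.eps)
  }
  structure(
    list(
      athlete_id = athlete_id,
      genetic = genetic, history = history, anthro = anthro,
      baseline_fitness = baseline_fitness,
      adapt_coeff = adapt_coeff, adapt_rate = adapt_rate,
      fatigue_sens = fatigue_sens,
      k_accum = k_accum, k_recover = k_recover, k_active = k_active,
      compartments = compartments,
      phenotype = phenotype,
      baseline_performance = baseline_performance,
      preferred_load = preferred_load
    ),
    class = "athlete_profile"
  )
}

#' @export
print.athlete_profile <- function(x, ...) {
  cat(sprintf(
    "<athlete_profile %s: %s, eta=%.3g lambda=%.3g delta=%.3g k=(%.3g, %.3g, %.3g), %d recovery compartments>\n",
    x$athlete_id, x$phenotype, x$adapt_coeff, x$adapt_rate, x$fatigue_sens,
    x$k_accum, x$k_recover, x$k_active, length(x$compartments)
  ))
  invisible(x)
}

#' Construct a daily physiological state
#'
#' @param performance Performance in model units.
#' @param fatigue Nonnegative fatigue level.
#' @param recovery_attained Attained recovery (bounded by the profile's total
#'   compartment capacity).
#' @param day Integer day index (0-based).
#' @param load_window Recent daily loads, most recent last, each in \[0,1\].
#' @return An object of class `physio_state`.
#' @export
physio_state <- function(performance = 100, fatigue = 0,
                         recovery_attained = 0, day = 0L,
                         load_window = numeric(0)) {
  check_scalar(performance, "performance")
  check_range(fatigue, "fatigue", lo = 0)
  check_range(recovery_attained, "recovery_attained", lo = 0)
  if (length(load_window) && (any(load_window < 0) || any(load_window > 1))) {
    abort("`load_window` values must lie in [0, 1]", class = "loadctrl_invalid_input")
  }
  structure(
    list(performance = performance, fatigue = fatigue,
         recovery_attained = recovery_attained, day = as.integer(day),
         load_window = as.numeric(load_window)),
    class = "physio_state"
  )
}

#' Profile-dependent gain of the dose-response term
#'
#' The dose-response term of the performance update is
#' `f(profile) * adapt_coeff * (1 - exp(-adapt_rate * load))`. The gain `f` is
#' load-independent: dose saturation is carried entirely by the exponential
#' factor. `f` is a weighted mean of the profile's genetic, history and
#' baseline-fitness summaries.
#'
#' @param profile An [athlete_profile()].
#' @param g0 Overall gain multiplier.
#' @param w Length-3 nonnegative weights over (genetic, history, baseline
#'   fitness) summaries; normalized internally.
#' @return Scalar gain.
#' @export
profile_gain <- function(profile, g0 = 1.0, w = c(1, 1, 1) / 3) {
  stopifnot(length(w) == 3, all(w >= 0), sum(w) > 0)
  w <- w / sum(w)
  g0 * sum(w * c(mean(profile$genetic), mean(profile$history),
                 mean(profile$baseline_fitness)))
}

#' One-day performance update
#'
#' Impulse-response update: the next performance equals the current one plus a
#' saturating training dose-response minus a fatigue penalty,
#' `P' = P + f * eta * (1 - exp(-lambda * TL)) - delta * F`,
#' with `f` the profile gain ([profile_gain()]), `eta` the adaptation
#' coefficient, `lambda` the adaptation rate and `delta` the fatigue
#' sensitivity.
#'
#' @param state A [physio_state()].
#' @param load Daily training load in \[0,1\].
#' @param profile An [athlete_profile()].
#' @param gain Optional precomputed profile gain; defaults to
#'   `profile_gain(profile)`.
#' @return Next-day performance (scalar).
#' @examples
#' performance_update(physio_state(performance = 100), load = 0.5, athlete_profile())
#' @export
performance_update <- function(state, load, profile, gain = NULL) {
  check_range(load, "load", lo = 0, hi = 1)
  check_scalar(state$performance, "state$performance")
  check_range(state$fatigue, "state$fatigue", lo = 0)
  f <- gain %||% profile_gain(profile)
  out <- state$performance +
    f * profile$adapt_coeff * (1 - exp(-profile$adapt_rate * load)) -
    profile$fatigue_sens * state$fatigue
  check_scalar(out, "performance_update result")
  out
}

#' One forward-Euler step of the fatigue ODE
#'
#' Fatigue follows `dF/dt = k1 * TL - k2 * F - k3 * R`, with `k1` the
#' accumulation rate, `k2` natural recovery, `k3` the active-recovery
#' coefficient and `R` the day's recovery intervention. The step is explicit
#' Euler with a nonnegativity clamp.
#'
#' @param fatigue Current fatigue (nonnegative scalar).
#' @param load Daily training load in \[0,1\].
#' @param recovery_input Recovery-intervention input for the day (nonnegative).
#' @param profile An [athlete_profile()] providing `k_accum`, `k_recover`,
#'   `k_active`.
#' @param dt Step size in days (> 0); the environment uses 1.
#' @return Next fatigue value (nonnegative scalar).
#' @examples
#' fatigue_step(2, load = 0, recovery_input = 0, athlete_profile(), dt = 1)
#' @export
fatigue_step <- function(fatigue, load, recovery_input, profile, dt = 1) {
  check_range(fatigue, "fatigue", lo = 0)
  check_scalar(load, "load")
  check_scalar(recovery_input, "recovery_input")
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0) {
    abort("`dt` must be a positive scalar", class = "loadctrl_invalid_input")
  }
  dF <- profile$k_accum * load - profile$k_recover * fatigue -
    profile$k_active * recovery_input
  max(0, fatigue + dt * dF)
}

#' Total attained recovery after an elapsed time
#'
#' Multi-compartment exponential recovery:
#' `R_total(t) = sum_j r_max_j * (1 - exp(-t / tau_j))`, monotone
#' nondecreasing in `t` and bounded by the total capacity `sum_j r_max_j`.
#'
#' @param elapsed Elapsed time in days (nonnegative; vectorized).
#' @param compartments List of `list(r_max =, tau =)` pairs.
#' @return Total recovery, same length as `elapsed`.
#' @examples
#' recovery_total(1.5, list(list(r_max = 1, tau = 1.5)))
#' @export
recovery_total <- function(elapsed, compartments) {
  if (!is.numeric(elapsed) || any(!is.finite(elapsed)) || any(elapsed < 0)) {
    abort("`elapsed` must be nonnegative and finite", class = "loadctrl_invalid_input")
  }
  out <- numeric(length(elapsed))
  for (cp in compartments) {
    out <- out + cp$r_max * (1 - exp(-elapsed / cp$tau))
  }
  out
}

#' Total recovery capacity of a profile
#' @param profile An [athlete_profile()].
#' @return Sum of compartment capacities.
#' @export
recovery_capacity <- function(profile) {
  sum(vapply(profile$compartments, function(cp) cp$r_max, numeric(1)))
}

#' Time-varying adaptive weighting function
#'
#' Linear combination of a profile summary, a response-history summary and an
#' environmental factor under time-varying weights:
#' `AF = w_profile * profile_summary + w_history * response_history +
#' w_env * env_factor`.
#'
#' @param profile_summary Scalar summary of the athlete profile.
#' @param weights A list or [adaptive_weights()] with fields `w_profile`,
#'   `w_history`, `w_env`, `response_history`, `env_factor`.
#' @return Scalar adaptive-function value.
#' @export
adaptive_function <- function(profile_summary, weights) {
  check_scalar(profile_summary, "profile_summary")
  for (f in c("w_profile", "w_history", "w_env", "response_history", "env_factor")) {
    check_scalar(weights[[f]], f)
  }
  weights$w_profile * profile_summary +
    weights$w_history * weights$response_history +
    weights$w_env * weights$env_factor
}

#' Construct adaptive weights
#'
#' @param w_profile,w_history,w_env Finite scalars: weights on the profile
#'   summary, the response-history summary and the environmental factor.
#' @param response_history Scalar response-history summary.
#' @param env_factor Scalar environmental factor.
#' @return A list of class `adaptive_weights`.
#' @export
adaptive_weights <- function(w_profile = 1, w_history = 0, w_env = 0,
                             response_history = 0, env_factor = 0) {
  out <- list(w_profile = w_profile, w_history = w_history, w_env = w_env,
              response_history = response_history, env_factor = env_factor)
  for (f in names(out)) check_scalar(out[[f]], f)
  structure(out, class = "adaptive_weights")
}

# ---- profile <-> table serialization ----------------------------------------

#' Flatten athlete profiles to a tibble
#'
#' Vector fields are spread into indexed columns (`genetic_1`, ...);
#' compartments into `comp<j>_r_max` / `comp<j>_tau` columns. The inverse is
#' [profiles_from_table()].
#'
#' @param profiles A list of [athlete_profile()] objects (or a single one).
#' @return A tibble with one row per athlete.
#' @export
profiles_to_table <- function(profiles) {
  if (inherits(profiles, "athlete_profile")) profiles <- list(profiles)
  purrr::map_dfr(profiles, function(p) {
    row <- tibble(
      athlete_id = p$athlete_id, phenotype = p$phenotype,
      adapt_coeff = p$adapt_coeff, adapt_rate = p$adapt_rate,
      fatigue_sens = p$fatigue_sens,
      k_accum = p$k_accum, k_recover = p$k_recover, k_active = p$k_active,
      baseline_performance = p$baseline_performance,
      preferred_load = p$preferred_load
    )
    for (v in c("genetic", "history", "anthro", "baseline_fitness")) {
      vals <- p[[v]]
      for (i in seq_along(vals)) row[[paste0(v, "_", i)]] <- vals[i]
    }
    for (j in seq_along(p$compartments)) {
      row[[paste0("comp", j, "_r_max")]] <- p$compartments[[j]]$r_max
      row[[paste0("comp", j, "_tau")]] <- p$compartments[[j]]$tau
    }
    row
  })
}

#' Rebuild athlete profiles from a flat table
#'
#' @param tbl A tibble as produced by [profiles_to_table()].
#' @return A list of [athlete_profile()] objects.
#' @export
profiles_from_table <- function(tbl) {
  gather_vec <- function(row, prefix) {
    cols <- grep(paste0("^", prefix, "_[0-9]+$"), names(row), value = TRUE)
    cols <- cols[order(as.integer(sub(paste0(prefix, "_"), "", cols)))]
    as.numeric(row[cols])
  }
  purrr::map(seq_len(nrow(tbl)), function(i) {
    row <- tbl[i, ]
    comp_cols <- grep("^comp[0-9]+_r_max$", names(row), value = TRUE)
    js <- sort(as.integer(sub("comp([0-9]+)_r_max", "\\1", comp_cols)))
    comps <- purrr::map(js, function(j) {
      list(r_max = row[[paste0("comp", j, "_r_max")]],
           tau = row[[paste0("comp", j, "_tau")]])
    })
    athlete_profile(
      genetic = gather_vec(row, "genetic"),
      history = gather_vec(row, "history"),
      anthro = gather_vec(row, "anthro"),
      baseline_fitness = gather_vec(row, "baseline_fitness"),
      adapt_coeff = row$adapt_coeff, adapt_rate = row$adapt_rate,
      fatigue_sens = row$fatigue_sens, k_accum = row$k_accum,
      k_recover = row$k_recover, k_active = row$k_active,
      compartments = comps, phenotype = row$phenotype,
      baseline_performance = row$baseline_performance,
      preferred_load = row$preferred_load,
      athlete_id = row$athlete_id
    )
  })
}
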