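# Training-load Markov decision process: factored daily actions, min-max
# scaled state features, injury hazard, four-component reward, 16-week
# (112-day) episodes.

#' Default environment configuration
#'
#' Returns the configuration block of the training-load MDP: the factored
#' action space and its load mapping, feature scaling bounds, injury-hazard
#' parameters, reward shaping constants, sensor noise levels and episode
#' length. All values are plain numbers; override any field via `...`.
#'
#' @param ... Named overrides merged over the defaults.
#' @return A list of class `env_config`.
#' @export
env_config <- function(...) {
  cfg <- list(
    episode_days = 112L,            # 16-week macrocycle, one decision per day
    window_acute = 7L,
    window_chronic = 28L,
    acwr_floor = 0.1,               # floor on the chronic mean
    # factored action space
    intensity_levels = -2:2,
    volume_levels = -1:1,
    session_types = c("work", "active_recovery"),
    recovery_protocols = c("none", "extended"),
    tl_base = 0.5,
    tl_per_intensity = 0.10,
    tl_per_volume = 0.10,
    recovery_base = 0.2,
    recovery_active_session = 0.4,
    recovery_extended = 0.4,
    # injury hazard (daily probability)
    hazard_scale = 0.05,
    hazard_fatigue_slope = 1.5,
    hazard_fatigue_ref = 2.5,
    hazard_acwr_slope = 2.0,
    hazard_acwr_ref = 1.3,
    injury_block_days = 7L,
    injury_penalty = 1.0,
    injury_block_recovery = 0.6,
    # reward shaping
    perf_gain_scale = 0.5,
    adherence_slope = 1.0,
    high_load_threshold = 0.5,      # a day counts as "hard" above this TL
    # latent fatigue baseline at reset
    fatigue_baseline = 1.0,
    # sensor observation model (mean structure is in env_sensors())
    sensor_noise_sd = c(hr_rest = 2.0, hrv = 4.0, rpe = 0.5,
                        sleep = 0.4, soreness = 0.5),
    # min-max scaling bounds per state feature
    feature_bounds = list(
      performance  = c(70, 140),
      fatigue      = c(0, 8),
      recovery_quality = c(0, 1),
      day          = c(0, 112),
      load_lag1 = c(0, 1), load_lag2 = c(0, 1), load_lag3 = c(0, 1),
      load_lag4 = c(0, 1), load_lag5 = c(0, 1), load_lag6 = c(0, 1),
      load_lag7 = c(0, 1),
      acwr         = c(0, 3),
      preferred_load = c(0, 1),
      hr_rest      = c(40, 90),
      hrv          = c(20, 120),
      rpe          = c(0, 10),
      sleep        = c(4, 10),
      soreness     = c(0, 10),
      injury_block = c(0, 7)
    )
  )
  modifyList(structure(cfg, class = "env_config"), list(...))
}

#' Enumerate the factored action space
#'
#' Every combination of intensity modification, volume adjustment, session
#' type and recovery protocol is one discrete action. The mapping to a daily
#' training load is `TL = clip01(tl_base + tl_per_intensity * intensity +
#' tl_per_volume * volume)` for work sessions and `TL = 0` for
#' active-recovery sessions; the recovery input sums the base, session and
#' protocol contributions (capped at 1).
#'
#' @param config An [env_config()].
#' @return A tibble with columns `action_id`, the four factors, `tl` and
#'   `recovery_input`; `action_id` is a bijective index over factor tuples.
#' @examples
#' nrow(action_table())  # 5 * 3 * 2 * 2 = 60
#' @export
action_table <- function(config = env_config()) {
  grid <- tidyr::expand_grid(
    intensity_mod = config$intensity_levels,
    volume_adj = config$volume_levels,
    session_type = config$session_types,
    recovery_protocol = config$recovery_protocols
  )
  grid |>
    dplyr::mutate(
      action_id = dplyr::row_number(),
      tl = ifelse(
        session_type == "active_recovery", 0,
        clip01(config$tl_base + config$tl_per_intensity * intensity_mod +
                 config$tl_per_volume * volume_adj)
      ),
      recovery_input = pmin(
        1,
        config$recovery_base +
          config$recovery_active_session * (session_type == "active_recovery") +
          config$recovery_extended * (recovery_protocol == "extended")
      )
    ) |>
    dplyr::select(action_id, dplyr::everything())
}

#' Reward weighting coefficients
#'
#' Four nonnegative coefficients over (performance gain, injury safety,
#' adherence, recovery quality) that must sum to one. Defaults are the
#' calibrated optimum (0.4, 0.3, 0.2, 0.1).
#'
#' @param w_perf,w_injury,w_adherence,w_recovery Nonnegative weights.
#' @return A list of class `reward_weights`.
#' @export
reward_weights <- function(w_perf = 0.4, w_injury = 0.3,
                           w_adherence = 0.2, w_recovery = 0.1) {
  w <- c(w_perf = w_perf, w_injury = w_injury,
         w_adherence = w_adherence, w_recovery = w_recovery)
  if (any(!is.finite(w)) || any(w < 0)) {
    abort("reward weights must be finite and nonnegative",
          class = "loadctrl_config_error")
  }
  if (abs(sum(w) - 1) > 1e-9) {
    abort(sprintf("reward weights must sum to 1 (got %.12f)", sum(w)),
          class = "loadctrl_config_error")
  }
  structure(as.list(w), class = "reward_weights")
}

#' Combine reward components into the scalar reward
#'
#' `R = w_perf * perf_gain + w_injury * injury_safety +
#' w_adherence * adherence + w_recovery * recovery_quality`. Injury safety is
#' the bounded stand-in `1 - risk` for inverse injury risk, which keeps the
#' reward bounded (required for stable Q-learning).
#'
#' @param components Named list with `perf_gain` in \[-1,1\] and
#'   `injury_safety`, `adherence`, `recovery_quality` in \[0,1\].
#' @param weights A [reward_weights()].
#' @return Scalar reward in `[-w_perf, 1]`.
#' @export
compute_reward <- function(components, weights) {
  if (!inherits(weights, "reward_weights")) {
    abort("`weights` must be a reward_weights object", class = "loadctrl_config_error")
  }
  weights$w_perf * components$perf_gain +
    weights$w_injury * components$injury_safety +
    weights$w_adherence * components$adherence +
    weights$w_recovery * components$recovery_quality
}

#' Acute:chronic workload ratio
#'
#' Mean of the last 7 daily loads over the mean of the last 28, with the
#' chronic mean floored to avoid division blow-ups. An empty history gives the
#' neutral ratio 1.
#'
#' @param load_history Numeric vector of daily loads, oldest first.
#' @param config An [env_config()].
#' @return Scalar ratio.
#' @export
acwr <- function(load_history, config = env_config()) {
  if (!length(load_history)) return(1)
  acute <- mean(tail(load_history, config$window_acute))
  chronic <- max(mean(tail(load_history, config$window_chronic)), config$acwr_floor)
  acute / chronic
}

#' Daily injury risk
#'
#' Logistic hazard in fatigue and the acute:chronic workload ratio:
#' `risk = plogis(a * (F - F_ref) + b * (ACWR - ACWR_ref)) * h_scale`,
#' strictly increasing in both drivers and bounded by `h_scale`.
#'
#' @param fatigue Nonnegative fatigue level.
#' @param load_window Recent daily loads, oldest first (empty gives ACWR 1).
#' @param config An [env_config()].
#' @return Daily injury probability in `(0, h_scale)`.
#' @examples
#' injury_risk(2.5, rep(0.5, 28))
#' @export
injury_risk <- function(fatigue, load_window = numeric(0), config = env_config()) {
  check_range(fatigue, "fatigue", lo = 0)
  ratio <- acwr(load_window, config)
  plogis(config$hazard_fatigue_slope * (fatigue - config$hazard_fatigue_ref) +
           config$hazard_acwr_slope * (ratio - config$hazard_acwr_ref)) *
    config$hazard_scale
}

# Latent-state -> expected sensor readings. Noise is added by the environment
# from its own stream; the cohort module reuses these mean structures.
env_sensor_means <- function(fatigue, load_yesterday) {
  c(
    hr_rest = 55 + 3.0 * fatigue,
    hrv = 75 - 8.0 * fatigue,
    rpe = 8.0 * load_yesterday + 0.3 * fatigue,
    sleep = 8.0 - 0.25 * fatigue,
    soreness = 1.2 * fatigue + 2.0 * load_yesterday
  )
}

#' Build the agent-visible state vector
#'
#' Assembles the named raw features (latent performance/fatigue/recovery,
#' calendar day, 7-day load window, acute:chronic ratio, preferred load,
#' sensor readings, remaining injury-block days) and min-max scales each into
#' \[0,1\] using the configured bounds; raw values outside their bounds are
#' clipped.
#'
#' @param physio A [physio_state()].
#' @param profile An [athlete_profile()].
#' @param observed Named numeric vector of observed (sensor) features.
#' @param config An [env_config()].
#' @param extras Named numeric vector of additional raw features
#'   (e.g. `recovery_quality`, `injury_block`).
#' @return An `env_state`: list with `features` (named, scaled), `day`, `done`.
#' @export
build_state <- function(physio, profile, observed, config = env_config(),
                        extras = c(recovery_quality = 0, injury_block = 0)) {
  lw <- physio$load_window
  lags <- rev(tail(c(rep(0, 7), lw), 7))  # lag1 = yesterday
  raw <- c(
    performance = as.numeric(physio$performance),
    fatigue = as.numeric(physio$fatigue),
    recovery_quality = as.numeric(extras[["recovery_quality"]]),
    day = as.numeric(physio$day),
    setNames(lags, paste0("load_lag", 1:7)),
    acwr = acwr(lw, config),
    preferred_load = as.numeric(profile$preferred_load),
    observed,
    injury_block = as.numeric(extras[["injury_block"]])
  )
  bounds <- config$feature_bounds
  unknown <- setdiff(names(raw), names(bounds))
  if (length(unknown)) {
    abort(paste0("no scaling bounds configured for feature(s): ",
                 paste(unknown, collapse = ", ")),
          class = "loadctrl_config_error")
  }
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  feats <- clip01((raw[names(bounds)] - lo) / (hi - lo))
  names(feats) <- names(bounds)
  structure(list(features = feats, day = physio$day, done = FALSE),
            class = "env_state")
}

#' Create a training-load environment for one athlete
#'
#' The environment is a mutable object (an R environment) holding the hidden
#' physiological state, the load history, the injury-block counter and its own
#' random stream. Use [env_reset()] and [env_step()] to interact with it.
#'
#' @param profile An [athlete_profile()].
#' @param config An [env_config()].
#' @param weights A [reward_weights()].
#' @return An object of class `loadctrl_env`.
#' @export
training_env <- function(profile, config = env_config(),
                         weights = reward_weights()) {
  e <- new.env(parent = emptyenv())
  e$profile <- profile
  e$config <- config
  e$weights <- weights
  e$actions <- action_table(config)
  e$tl_of <- e$actions$tl               # fast per-action lookups
  e$rin_of <- e$actions$recovery_input
  e$capacity <- recovery_capacity(profile)
  e$profile_gain <- profile_gain(profile)
  b <- config$feature_bounds
  e$feat_lo <- vapply(b, `[`, numeric(1), 1)
  e$feat_hi <- vapply(b, `[`, numeric(1), 2)
  class(e) <- "loadctrl_env"
  e
}

#' @export
print.loadctrl_env <- function(x, ...) {
  cat(sprintf("<loadctrl_env athlete=%s |A|=%d episode=%d days>\n",
              x$profile$athlete_id, nrow(x$actions), x$config$episode_days))
  invisible(x)
}

#' Reset an environment to day zero
#'
#' @param env A [training_env()].
#' @param seed Integer seed for the environment's private stream; episode
#'   dynamics are deterministic given `(profile, seed, action sequence)`.
#' @return The initial `env_state`.
#' @export
env_reset <- function(env, seed = 0L) {
  env$stream <- rng_stream(seed)
  env$physio <- physio_state(
    performance = env$profile$baseline_performance,
    fatigue = env$config$fatigue_baseline,
    day = 0L, load_window = numeric(0)
  )
  env$load_history <- numeric(0)
  env$days_since_high <- 14          # enters the macrocycle rested
  env$injury_block <- 0L
  env$injury_count <- 0L
  env$done <- FALSE
  env$state <- env_observe(env)
  env$state
}

# Build the current observed state (draws sensor noise from the env stream).
# Fast inline equivalent of build_state() for the training hot path.
env_observe <- function(env) {
  lh <- env$load_history
  ly <- if (length(lh)) lh[length(lh)] else 0
  mu <- env_sensor_means(env$physio$fatigue, ly)
  noise_sd <- env$config$sensor_noise_sd
  obs <- with_stream(env$stream, mu + rnorm(length(mu), 0, noise_sd[names(mu)]))
  rq <- recovery_total(env$days_since_high, env$profile$compartments) / env$capacity
  lags <- rev(tail(c(0, 0, 0, 0, 0, 0, 0, lh), 7))
  raw <- c(env$physio$performance, env$physio$fatigue, rq, env$physio$day,
           lags, acwr(lh, env$config), env$profile$preferred_load,
           obs, env$injury_block)
  feats <- clip01((raw - env$feat_lo) / (env$feat_hi - env$feat_lo))
  names(feats) <- names(env$config$feature_bounds)
  structure(list(features = feats, day = env$physio$day, done = env$done),
            class = "env_state")
}

#' Advance the environment by one day
#'
#' Maps the action to a daily load and recovery input (overridden to a
#' zero-load recovery block while an injury block is active), advances the
#' fitness-fatigue dynamics, samples an injury as a Bernoulli draw from the
#' current hazard, computes the four reward components and the scalar reward
#' (minus a one-time penalty on the day an injury occurs), and returns the
#' next observed state. The episode ends after `episode_days` days; injuries
#' do not terminate it.
#'
#' @param env A [training_env()] that has been [env_reset()].
#' @param action_id Integer action index into [action_table()].
#' @return A list `(state, reward, done, info)`; `info` is a one-row tibble
#'   with the latent trajectory record.
#' @export
env_step <- function(env, action_id) {
  if (isTRUE(env$done)) {
    abort("env_step() called on a finished episode; env_reset() first",
          class = "loadctrl_state_error")
  }
  cfg <- env$config
  if (!is.numeric(action_id) || length(action_id) != 1 ||
      is.na(action_id) || action_id < 1 || action_id > length(env$tl_of)) {
    abort(sprintf("unknown action_id %s", action_id), class = "loadctrl_config_error")
  }

  blocked <- env$injury_block > 0L
  tl <- if (blocked) 0 else env$tl_of[action_id]
  rin <- if (blocked) cfg$injury_block_recovery else env$rin_of[action_id]

  # hazard uses the pre-step fatigue and the window including today's load
  risk <- injury_risk(env$physio$fatigue, c(env$load_history, tl), cfg)
  injured <- !blocked && with_stream(env$stream, runif(1)) < risk
  if (injured) {
    env$injury_block <- cfg$injury_block_days
    env$injury_count <- env$injury_count + 1L
    blocked_today <- TRUE
  }

  p_next <- performance_update(env$physio, tl, env$profile,
                               gain = env$profile_gain)
  f_next <- fatigue_step(env$physio$fatigue, tl, rin, env$profile, dt = 1)

  env$load_history <- c(env$load_history, tl)
  env$days_since_high <- if (tl >= cfg$high_load_threshold) 0 else env$days_since_high + 1
  rq <- recovery_total(env$days_since_high, env$profile$compartments) / env$capacity

  components <- list(
    perf_gain = pmin(1, pmax(-1, (p_next - env$physio$performance) / cfg$perf_gain_scale)),
    injury_safety = 1 - risk,
    adherence = clip01(1 - cfg$adherence_slope * abs(tl - env$profile$preferred_load)),
    recovery_quality = rq
  )
  reward <- compute_reward(components, env$weights) -
    if (injured) cfg$injury_penalty else 0

  if (env$injury_block > 0L) env$injury_block <- env$injury_block - 1L

  env$physio <- structure(
    list(performance = p_next, fatigue = f_next,
         recovery_attained = rq * env$capacity,
         day = env$physio$day + 1L,
         load_window = tail(env$load_history, cfg$window_chronic)),
    class = "physio_state")
  env$done <- env$physio$day >= cfg$episode_days
  env$state <- env_observe(env)

  info <- list(
    athlete_id = env$profile$athlete_id, day = env$physio$day,
    action_id = as.integer(action_id), tl = tl, performance = p_next,
    fatigue = f_next, risk = risk, injured = injured, reward = reward,
    perf_gain = components$perf_gain, injury_safety = components$injury_safety,
    adherence = components$adherence, recovery_quality = components$recovery_quality
  )
  list(state = env$state, reward = reward, done = env$done, info = info)
}

#' Run one full episode under a policy
#'
#' @param env A [training_env()].
#' @param policy A function `(state, env) -> action_id` (see `policy_*`
#'   constructors) or a `loadctrl_policy` object.
#' @param seed Environment seed for [env_reset()].
#' @return A list with `log` (one row per day), `return` (summed reward),
#'   `injuries`, `perf_start`, `perf_end`.
#' @export
run_episode <- function(env, policy, seed = 0L) {
  state <- env_reset(env, seed)
  p0 <- env$physio$performance
  rows <- vector("list", env$config$episode_days)
  total <- 0
  for (d in seq_len(env$config$episode_days)) {
    a <- policy_action(policy, state, env)
    out <- env_step(env, a)
    rows[[d]] <- out$info
    total <- total + out$reward
    state <- out$state
  }
  list(log = dplyr::bind_rows(rows), return = total,
       injuries = env$injury_count,
       perf_start = p0, perf_end = env$physio$performance)
}
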