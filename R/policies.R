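# Policy interface and baseline policies: uniform random, constant load,
# linear periodization, physiological-threshold rules, and regression-based
# prescription. A policy is a mutable object with a `select(state, env)`
# method and an optional `reset(seed)` used by the paired comparison harness.

new_policy <- function(name, select, reset = NULL) {
  p <- new.env(parent = emptyenv())
  p$name <- name
  p$select <- select
  p$reset <- reset
  class(p) <- "loadctrl_policy"
  p
}

#' @export
print.loadctrl_policy <- function(x, ...) {
  cat(sprintf("<loadctrl_policy: %s>\n", x$name)); invisible(x)
}

#' Ask a policy for an action
#'
#' @param policy A `loadctrl_policy` or a bare function `(state, env)`.
#' @param state Current `env_state`.
#' @param env The [training_env()] being acted in.
#' @return Integer action index.
#' @export
policy_action <- function(policy, state, env) {
  if (is.function(policy)) return(policy(state, env))
  policy$select(state, env)
}

#' Reset a policy's internal state/stream before an episode
#'
#' @param policy A `loadctrl_policy`.
#' @param seed Seed for the policy's private stream.
#' @return The policy, invisibly.
#' @export
policy_reset <- function(policy, seed) {
  if (!is.function(policy) && !is.null(policy$reset)) policy$reset(seed)
  invisible(policy)
}

# Locate an action id by its factor tuple.
find_action <- function(actions, intensity_mod = 0, volume_adj = 0,
                        session_type = "work", recovery_protocol = "none") {
  hit <- actions[actions$intensity_mod == intensity_mod &
                   actions$volume_adj == volume_adj &
                   actions$session_type == session_type &
                   actions$recovery_protocol == recovery_protocol, ]
  stopifnot(nrow(hit) == 1)
  hit$action_id
}

# Invert min-max scaling for one named state feature.
feature_raw <- function(state, name, config) {
  b <- config$feature_bounds[[name]]
  b[1] + state$features[[name]] * (b[2] - b[1])
}

#' Greedy policy of a trained agent
#'
#' @param agent A `loadctrl_agent` (or any list with `spec` and `params`).
#' @return A `loadctrl_policy` selecting `argmax_a Q(s, a)`.
#' @export
policy_agent <- function(agent) {
  new_policy("dqn", function(state, env) {
    q_forward(agent$spec, agent$params, state)$greedy
  })
}

#' Uniform-random policy
#'
#' @param seed Seed of the policy's private stream.
#' @return A `loadctrl_policy`.
#' @export
policy_random <- function(seed = 0L) {
  stream <- rng_stream(seed)
  p <- new_policy("random", function(state, env) {
    with_stream(stream, sample.int(nrow(env$actions), 1))
  })
  p$reset <- function(s) stream <<- rng_stream(s)
  p
}

#' Constant-action policy
#'
#' Defaults to the moderate work session (no intensity or volume adjustment,
#' no extra recovery), i.e. a constant daily load of `tl_base`.
#'
#' @param intensity_mod,volume_adj,session_type,recovery_protocol Factor
#'   levels identifying the repeated action.
#' @return A `loadctrl_policy`.
#' @export
policy_constant <- function(intensity_mod = 0, volume_adj = 0,
                            session_type = "work",
                            recovery_protocol = "none") {
  new_policy("constant", function(state, env) {
    find_action(env$actions, intensity_mod, volume_adj, session_type,
                recovery_protocol)
  })
}

# ---- linear periodization ---------------------------------------------------

#' Default linear-periodization plan
#'
#' Four 4-week mesocycle blocks: intensity ramps up across blocks while
#' volume ramps down; the fourth week of each block is a deload week (reduced
#' intensity and volume plus extended recovery); the last day of every week
#' is an active-recovery rest day.
#'
#' @return A list describing the plan.
#' @export
periodization_plan <- function() {
  list(block_days = 28L, week_days = 7L,
       block_intensity = c(-1L, 0L, 1L, 2L),
       block_volume = c(1L, 1L, 0L, -1L),
       deload_week = 4L,
       deload_intensity = -2L, deload_volume = -1L)
}

#' Linear-periodization action for a given day
#'
#' Deterministic schedule over the 112-day macrocycle (see
#' [periodization_plan()]).
#'
#' @param day Day index in `[0, 112)`.
#' @param plan A [periodization_plan()].
#' @param actions An [action_table()].
#' @return Integer action id.
#' @export
periodization_policy <- function(day, plan = periodization_plan(),
                                 actions = action_table()) {
  stopifnot(day >= 0, day < 4L * plan$block_days)
  block <- (day %/% plan$block_days) + 1L
  week_in_block <- ((day %% plan$block_days) %/% plan$week_days) + 1L
  day_in_week <- day %% plan$week_days
  if (day_in_week == plan$week_days - 1L) {     # weekly rest day
    return(find_action(actions, 0, 0, "active_recovery", "extended"))
  }
  if (week_in_block == plan$deload_week) {
    return(find_action(actions, plan$deload_intensity, plan$deload_volume,
                       "work", "extended"))
  }
  find_action(actions, plan$block_intensity[block], plan$block_volume[block],
              "work", "none")
}

#' Periodization policy object
#' @param plan A [periodization_plan()].
#' @return A `loadctrl_policy`.
#' @export
policy_periodization <- function(plan = periodization_plan()) {
  new_policy("periodization", function(state, env) {
    periodization_policy(state$day, plan, env$actions)
  })
}

# ---- rule-based thresholds --------------------------------------------------

#' Physiological-marker thresholds for the rule-based policy
#'
#' Defaults: reduce load when morning HRV drops below 60 ms, or session RPE
#' exceeds 7/10, or muscle soreness exceeds 6/10.
#'
#' @param hrv_floor HRV floor in milliseconds.
#' @param rpe_ceiling RPE ceiling on the 0-10 scale.
#' @param soreness_ceiling Soreness ceiling on the 0-10 scale.
#' @return A list of class `rule_thresholds`.
#' @export
rule_thresholds <- function(hrv_floor = 60, rpe_ceiling = 7,
                            soreness_ceiling = 6) {
  stopifnot(hrv_floor > 0, rpe_ceiling > 0, soreness_ceiling > 0)
  structure(list(hrv_floor = hrv_floor, rpe_ceiling = rpe_ceiling,
                 soreness_ceiling = soreness_ceiling),
            class = "rule_thresholds")
}

#' Threshold-rule action from observed markers
#'
#' When any marker breaches its threshold the policy steps intensity and
#' volume down (with extended recovery); otherwise it maintains the planned
#' moderate progression. Missing markers fall back to maintain, with a
#' warning.
#'
#' @param observed Named vector/list with `hrv`, `rpe`, `soreness` (raw units).
#' @param thresholds A [rule_thresholds()].
#' @param actions An [action_table()].
#' @return Integer action id.
#' @export
rule_based_policy <- function(observed, thresholds = rule_thresholds(),
                              actions = action_table()) {
  need <- c("hrv", "rpe", "soreness")
  vals <- vapply(need, function(nm) {
    v <- if (is.list(observed)) observed[[nm]] else unname(observed[nm])
    if (is.null(v) || !length(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  if (any(is.na(vals))) {
    warn(paste0("missing marker(s): ", paste(need[is.na(vals)], collapse = ", "),
                "; maintaining planned load"))
    return(find_action(actions, 0, 0, "work", "none"))
  }
  breach <- vals["hrv"] < thresholds$hrv_floor ||
    vals["rpe"] > thresholds$rpe_ceiling ||
    vals["soreness"] > thresholds$soreness_ceiling
  if (breach) {
    find_action(actions, -2, -1, "work", "extended")
  } else {
    find_action(actions, 0, 0, "work", "none")
  }
}

#' Rule-based policy object
#'
#' Reads HRV, RPE and soreness back from the scaled state features using the
#' environment's scaling bounds.
#'
#' @param thresholds A [rule_thresholds()].
#' @return A `loadctrl_policy`.
#' @export
policy_rule_based <- function(thresholds = rule_thresholds()) {
  new_policy("rule_based", function(state, env) {
    obs <- c(hrv = feature_raw(state, "hrv", env$config),
             rpe = feature_raw(state, "rpe", env$config),
             soreness = feature_raw(state, "soreness", env$config))
    rule_based_policy(obs, thresholds, env$actions)
  })
}

# ---- regression-based prescription ------------------------------------------

#' Regression prescription from a training history
#'
#' Fits ordinary least squares of the next-day performance change on the
#' daily load (linear and quadratic terms) and a fatigue proxy, then selects
#' the candidate action whose load maximizes the predicted gain at the
#' current fatigue, subject to a fatigue-guard cap; predicted-gain ties break
#' to the lowest load. A rank-deficient design falls back to ridge regression
#' with a small documented penalty.
#'
#' @param history Tibble with columns `tl`, `dperf`, `fatigue` (one row per
#'   observed day).
#' @param fatigue_now Current fatigue (raw units).
#' @param actions An [action_table()].
#' @param min_rows Minimum history length before the model is used.
#' @param fatigue_cap Above this fatigue, candidate loads are capped at
#'   `guard_tl`.
#' @param guard_tl Load cap applied under the fatigue guard.
#' @param ridge_penalty Ridge fallback penalty.
#' @return Integer action id, or `NULL` (not-ready signal) when `history`
#'   has fewer than `min_rows` rows.
#' @export
regression_policy <- function(history, fatigue_now = 0,
                              actions = action_table(),
                              min_rows = 14L, fatigue_cap = 3.5,
                              guard_tl = 0.45, ridge_penalty = 1e-6) {
  if (nrow(history) < min_rows) return(NULL)
  y <- history$dperf
  cand_all <- actions[order(actions$tl, actions$action_id), ]
  if (sd(y) < 1e-12) {
    # flat response: every action ties; break to the lowest load
    return(cand_all$action_id[1])
  }
  X <- cbind(1, history$tl, history$tl^2, history$fatigue)
  fit <- lm.fit(X, y)
  beta <- fit$coefficients
  if (any(is.na(beta))) {
    beta <- solve(crossprod(X) + ridge_penalty * diag(ncol(X)), crossprod(X, y))
  }
  cand <- actions
  if (fatigue_now > fatigue_cap) cand <- cand[cand$tl <= guard_tl, ]
  pred <- beta[1] + beta[2] * cand$tl + beta[3] * cand$tl^2 +
    beta[4] * fatigue_now
  ord <- order(cand$tl, cand$action_id)
  cand <- cand[ord, ]
  pred <- pred[ord]
  cand$action_id[which(pred >= max(pred) - 1e-9)[1]]
}

#' Regression-prescription policy object
#'
#' Accumulates its own history of (load, observed performance change, fatigue
#' proxy) from the scaled state features during the episode; before
#' `min_rows` days it maintains the moderate planned action.
#'
#' @param min_rows,fatigue_cap,guard_tl See [regression_policy()].
#' @return A `loadctrl_policy`.
#' @export
policy_regression <- function(min_rows = 14L, fatigue_cap = 3.5,
                              guard_tl = 0.45) {
  mem <- new.env(parent = emptyenv())
  mem$rows <- list()
  mem$prev <- NULL
  p <- new_policy("regression", function(state, env) {
    perf <- feature_raw(state, "performance", env$config)
    fat <- feature_raw(state, "fatigue", env$config)
    if (!is.null(mem$prev)) {
      mem$rows[[length(mem$rows) + 1L]] <-
        list(tl = mem$prev$tl, dperf = perf - mem$prev$perf,
             fatigue = mem$prev$fatigue)
    }
    hist <- dplyr::bind_rows(mem$rows)
    a <- if (nrow(hist) >= min_rows) {
      regression_policy(hist, fat, env$actions, min_rows, fatigue_cap, guard_tl)
    } else NULL
    a <- a %||% find_action(env$actions, 0, 0, "work", "none")
    mem$prev <- list(tl = env$actions$tl[env$actions$action_id == a],
                     perf = perf, fatigue = fat)
    a
  })
  p$reset <- function(s) { mem$rows <- list(); mem$prev <- NULL }
  p
}
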