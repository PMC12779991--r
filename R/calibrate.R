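# Reward-weight calibration: constrained grid search with athlete-level
# cross-validation, composite scoring, and a +/-20% sensitivity analysis of
# the calibrated weights.

#' Feasible reward-weight grid
#'
#' Enumerates the 0.05-step grid over the admissible coefficient ranges
#' (performance 0.30-0.50, injury 0.20-0.40, adherence 0.10-0.30, recovery
#' 0.05-0.15) and keeps the combinations lying on the unit simplex (sum 1
#' within 1e-9). Candidates violating any constraint are filtered out before
#' scoring.
#'
#' @param step Grid step per coefficient.
#' @return A tibble of feasible weight candidates.
#' @export
weight_grid <- function(step = 0.05) {
  rng <- list(w_perf = c(0.30, 0.50), w_injury = c(0.20, 0.40),
              w_adherence = c(0.10, 0.30), w_recovery = c(0.05, 0.15))
  grid <- tidyr::expand_grid(
    w_perf = round(seq(rng$w_perf[1], rng$w_perf[2], by = step), 6),
    w_injury = round(seq(rng$w_injury[1], rng$w_injury[2], by = step), 6),
    w_adherence = round(seq(rng$w_adherence[1], rng$w_adherence[2], by = step), 6),
    w_recovery = round(seq(rng$w_recovery[1], rng$w_recovery[2], by = step), 6)
  )
  keep <- abs(grid$w_perf + grid$w_injury + grid$w_adherence +
                grid$w_recovery - 1) < 1e-9
  grid[keep, ]
}

#' Desk-scale training budget for calibration runs
#'
#' Short-budget agent settings used inside the grid search: a tiny Q-network
#' and a handful of episodes per fold, enough to rank weight candidates on a
#' single CPU.
#'
#' @param episodes Training episodes per fold.
#' @param eval_episodes Greedy evaluation episodes per fold.
#' @param hidden_dims Hidden widths of the short-budget network.
#' @param ... Overrides forwarded to [reduced_agent_config()].
#' @return A list of class `calib_budget`.
#' @export
calib_budget <- function(episodes = 3L, eval_episodes = 1L,
                         hidden_dims = c(32L, 16L), ...) {
  structure(list(
    episodes = as.integer(episodes),
    eval_episodes = as.integer(eval_episodes),
    hidden_dims = as.integer(hidden_dims),
    config = reduced_agent_config(batch_size = 32L, eval_every = 100000L,
                                  eps_decay_episodes = max(episodes, 2L), ...)
  ), class = "calib_budget")
}

# Train a short-budget agent under given weights and evaluate it on held-out
# athletes; returns mean performance gain (%), injuries per episode and mean
# adherence over the evaluation episodes.
calib_evaluate <- function(weights, train_profiles, test_profiles, budget,
                           seed, env_cfg = env_config()) {
  train_envs <- purrr::map(train_profiles, training_env,
                           config = env_cfg, weights = weights)
  spec <- network_spec(input_dim = 32L, hidden_dims = budget$hidden_dims,
                       dropout_rates = rep(0, length(budget$hidden_dims)),
                       output_dim = nrow(train_envs[[1]]$actions))
  agent <- train_agent(train_envs, budget$episodes, budget$config,
                       spec = spec, seed = seed)
  pol <- policy_agent(agent)
  runs <- purrr::map(test_profiles, function(p) {
    env <- training_env(p, config = env_cfg, weights = weights)
    purrr::map(seq_len(budget$eval_episodes), function(k) {
      run_episode(env, pol, seed = derive_seed(seed, paste0(p$athlete_id, "-", k)))
    })
  }) |> purrr::flatten()
  tibble(
    perf_gain = mean(vapply(runs, function(r)
      100 * (r$perf_end - r$perf_start) / r$perf_start, numeric(1))),
    injuries = mean(vapply(runs, function(r) as.numeric(r$injuries), numeric(1))),
    adherence = mean(vapply(runs, function(r) mean(r$log$adherence), numeric(1)))
  )
}

#' Composite calibration score
#'
#' `score = 10 * (0.5 * norm(perf gain) + 0.3 * (1 - norm(injuries)) +
#' 0.2 * mean adherence)`, where `norm()` min-max normalizes across the
#' candidate set (a degenerate spread normalizes to 0.5).
#'
#' @param metrics Tibble with columns `perf_gain`, `injuries`, `adherence`
#'   (one row per candidate).
#' @return Numeric vector of composite scores on the 0-10 scale.
#' @export
composite_score <- function(metrics) {
  norm01 <- function(x) {
    r <- range(x)
    if (diff(r) < 1e-12) return(rep(0.5, length(x)))
    (x - r[1]) / diff(r)
  }
  10 * (0.5 * norm01(metrics$perf_gain) +
          0.3 * (1 - norm01(metrics$injuries)) +
          0.2 * metrics$adherence)
}

#' Grid search over reward-weight candidates
#'
#' For each feasible candidate, trains a short-budget agent per
#' cross-validation fold (folds split the cohort at the athlete level) and
#' evaluates it greedily on the held-out athletes; candidate-level metrics
#' average over folds, the composite score normalizes across the candidate
#' set, and candidates are ranked by descending score. Deterministic given
#' `seed`.
#'
#' @param profiles List of [athlete_profile()] (the calibration cohort).
#' @param grid Tibble of weight candidates (default [weight_grid()]);
#'   infeasible rows (negative weights, off-simplex, out of range) are
#'   filtered out before scoring.
#' @param folds Number of athlete-level CV folds.
#' @param budget A [calib_budget()].
#' @param seed Integer seed.
#' @param env_cfg An [env_config()].
#' @return A tibble ranked by `composite` with per-fold performance scores in
#'   a list column `cv_fold_scores`.
#' @export
grid_search_weights <- function(profiles, grid = weight_grid(), folds = 5L,
                                budget = calib_budget(), seed = 1L,
                                env_cfg = env_config()) {
  ok <- grid$w_perf >= 0.30 - 1e-9 & grid$w_perf <= 0.50 + 1e-9 &
    grid$w_injury >= 0.20 - 1e-9 & grid$w_injury <= 0.40 + 1e-9 &
    grid$w_adherence >= 0.10 - 1e-9 & grid$w_adherence <= 0.30 + 1e-9 &
    grid$w_recovery >= 0.05 - 1e-9 & grid$w_recovery <= 0.15 + 1e-9 &
    grid$w_perf >= 0 & grid$w_injury >= 0 & grid$w_adherence >= 0 &
    grid$w_recovery >= 0 &
    abs(grid$w_perf + grid$w_injury + grid$w_adherence + grid$w_recovery - 1) < 1e-9
  grid <- grid[ok, ]
  if (!nrow(grid)) {
    abort(paste("no feasible weight candidates: each must be nonnegative,",
                "lie within its admissible range, and sum to 1"),
          class = "loadctrl_config_error")
  }
  n <- length(profiles)
  stopifnot(n >= folds)
  fold_id <- rep(seq_len(folds), length.out = n)   # athlete-level folds

  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    w <- reward_weights(grid$w_perf[i], grid$w_injury[i],
                        grid$w_adherence[i], grid$w_recovery[i])
    per_fold <- purrr::map(seq_len(folds), function(f) {
      calib_evaluate(w, profiles[fold_id != f], profiles[fold_id == f],
                     budget, seed = derive_seed(seed, sprintf("cand%d-fold%d", i, f)),
                     env_cfg = env_cfg)
    })
    fold_tbl <- dplyr::bind_rows(per_fold)
    tibble(
      w_perf = grid$w_perf[i], w_injury = grid$w_injury[i],
      w_adherence = grid$w_adherence[i], w_recovery = grid$w_recovery[i],
      perf_gain = mean(fold_tbl$perf_gain),
      injuries = mean(fold_tbl$injuries),
      adherence = mean(fold_tbl$adherence),
      cv_fold_scores = list(fold_tbl$perf_gain)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$composite <- composite_score(out)
  out <- out[order(-out$composite), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Sensitivity of system outcomes to reward-weight perturbations
#'
#' Each coefficient is perturbed by +/- `perturbation` (relative) and
#' renormalized to the simplex, giving eight perturbed weight vectors; the
#' reported statistic is the maximum absolute relative change in the mean
#' episode performance gain over the same seeded evaluation episodes,
#' against the unperturbed reference.
#'
#' Two modes are offered. In `"fixed"` mode (the default) one agent is
#' trained once with the reference weights and then evaluated greedily under
#' each perturbed reward configuration. Because a fixed greedy policy's
#' trajectories do not depend on the reward weights, this isolates the
#' policy-side effect of the perturbation and is stable at desk scale. In
#' `"retrain"` mode a fresh short-budget agent is retrained per perturbed
#' weight vector under an identical seed and budget; at small training
#' budgets this measures mostly training-run variance rather than weight
#' sensitivity (see the package vignette for the discussion), so it is the
#' non-default mode.
#'
#' @param weights A [reward_weights()] (the calibrated reference).
#' @param perturbation Relative perturbation (default 0.20).
#' @param profiles List of [athlete_profile()].
#' @param seed Integer seed (shared by all runs).
#' @param episodes Training episodes (per run in `"retrain"` mode).
#' @param eval_episodes Evaluation episodes per athlete.
#' @param mode `"fixed"` (one agent, re-evaluated) or `"retrain"` (one agent
#'   per weight vector).
#' @param spec Optional [network_spec()] (defaults to the reduced network).
#' @param config An [agent_config()].
#' @param env_cfg An [env_config()].
#' @return A list with `max_rel_change` (in %, of the mean performance gain),
#'   `baseline_outcome` and a `table` of the 2x4 perturbed runs.
#' @export
sensitivity_analysis <- function(weights, perturbation = 0.20, profiles,
                                 seed = 1L, episodes = 120L,
                                 eval_episodes = 1L,
                                 mode = c("fixed", "retrain"), spec = NULL,
                                 config = reduced_agent_config(),
                                 env_cfg = env_config()) {
  stopifnot(perturbation >= 0)
  mode <- match.arg(mode)
  fit <- function(w) {
    envs <- purrr::map(profiles, training_env, config = env_cfg, weights = w)
    train_agent(envs, episodes, config, spec = spec, seed = seed)
  }
  evaluate <- function(agent, w) {
    pol <- policy_agent(agent)
    gains <- purrr::map(profiles, function(p) {
      env <- training_env(p, config = env_cfg, weights = w)
      vapply(seq_len(eval_episodes), function(k) {
        r <- run_episode(env, pol,
                         seed = derive_seed(seed, paste0("sens-", p$athlete_id, "-", k)))
        100 * (r$perf_end - r$perf_start) / r$perf_start
      }, numeric(1))
    })
    mean(unlist(gains))
  }
  base_agent <- fit(weights)
  base_out <- evaluate(base_agent, weights)
  outcome <- function(w) {
    agent <- if (mode == "retrain") fit(w) else base_agent
    evaluate(agent, w)
  }
  coefs <- c("w_perf", "w_injury", "w_adherence", "w_recovery")
  runs <- tidyr::expand_grid(coef = coefs, direction = c(-1, 1))
  if (perturbation == 0) runs <- runs[0, ]
  results <- purrr::pmap_dfr(runs, function(coef, direction) {
    w <- unlist(weights[coefs])
    w[coef] <- w[coef] * (1 + direction * perturbation)
    w <- w / sum(w)
    wobj <- reward_weights(w["w_perf"], w["w_injury"], w["w_adherence"],
                           w["w_recovery"])
    out <- outcome(wobj)
    tibble(coef = coef, direction = direction, outcome = out,
           rel_change = abs(out - base_out) / abs(base_out))
  })
  list(
    max_rel_change = if (nrow(results)) 100 * max(results$rel_change) else 0,
    baseline_outcome = base_out,
    table = results,
    mode = mode
  )
}
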