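test_that("the factored action space enumerates bijectively with valid loads", {
  acts <- action_table()
  expect_equal(nrow(acts), 5 * 3 * 2 * 2)
  expect_equal(acts$action_id, seq_len(nrow(acts)))
  # round trip: every (tuple) maps to exactly one id and back
  key <- paste(acts$intensity_mod, acts$volume_adj, acts$session_type,
               acts$recovery_protocol)
  expect_equal(anyDuplicated(key), 0L)
  expect_true(all(acts$tl >= 0 & acts$tl <= 1))
  expect_true(all(acts$tl[acts$session_type == "active_recovery"] == 0))
})

test_that("reward combination is the weighted sum with bounded components", {
  comps <- list(perf_gain = 0.5, injury_safety = 0.8, adherence = 1.0,
                recovery_quality = 0.25)
  expect_equal(compute_reward(comps, reward_weights()),
               0.4 * 0.5 + 0.3 * 0.8 + 0.2 * 1.0 + 0.1 * 0.25)
  ones <- list(perf_gain = 1, injury_safety = 1, adherence = 1,
               recovery_quality = 1)
  expect_equal(compute_reward(ones, reward_weights(0.35, 0.35, 0.2, 0.1)), 1.0)
  expect_equal(compute_reward(list(perf_gain = 0.37, injury_safety = 0,
                                   adherence = 0, recovery_quality = 0),
                              reward_weights(1, 0, 0, 0)), 0.37)
  expect_error(reward_weights(0.5, 0.5, 0.2, 0.1), class = "loadctrl_config_error")
  expect_error(reward_weights(-0.1, 0.6, 0.4, 0.1), class = "loadctrl_config_error")
})

test_that("reward is invariant under a matched permutation of components and weights", {
  comps <- c(perf_gain = 0.3, injury_safety = 0.9, adherence = 0.6,
             recovery_quality = 0.2)
  w <- c(0.4, 0.3, 0.2, 0.1)
  base <- sum(w * comps)
  for (k in 1:5) {
    perm <- sample(4)
    expect_equal(sum(w[perm] * comps[perm]), base)
  }
})

test_that("injury hazard is a bounded logistic, increasing in its drivers", {
  cfg <- env_config(hazard_acwr_ref = 1)  # empty window gives neutral ACWR 1
  expect_equal(injury_risk(cfg$hazard_fatigue_ref, numeric(0), cfg),
               0.5 * cfg$hazard_scale)
  expect_lt(injury_risk(0, rep(0.05, 28)), 1e-3)
  risks <- vapply(seq(0, 8, by = 0.5), injury_risk,
                  numeric(1), load_window = rep(0.5, 28))
  expect_true(all(diff(risks) > 0))
  # increasing in the acute:chronic ratio at fixed fatigue
  low <- injury_risk(2, c(rep(0.6, 21), rep(0.2, 7)))
  high <- injury_risk(2, c(rep(0.2, 21), rep(0.6, 7)))
  expect_gt(high, low)
  expect_true(all(risks > 0 & risks < env_config()$hazard_scale))
})

test_that("state features are min-max scaled with clipping", {
  cfg <- env_config()
  prof <- fixture_profile(preferred_load = 0)
  bounds <- cfg$feature_bounds
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)

  obs_names <- c("hr_rest", "hrv", "rpe", "sleep", "soreness")
  # all raw features at configured minima -> all-zero vector
  st_min <- build_state(
    physio_state(performance = lo["performance"], fatigue = 0, day = 0,
                 load_window = rep(0, 28)),
    prof, setNames(lo[obs_names], obs_names), cfg,
    extras = c(recovery_quality = 0, injury_block = 0))
  expect_true(all(st_min$features[setdiff(names(st_min$features), "acwr")] == 0))

  # raw values above the maximum clip to one
  st_over <- build_state(
    physio_state(performance = 1e5, fatigue = 50, day = 112,
                 load_window = rep(1, 28)),
    athlete_profile(preferred_load = 1),
    setNames(hi[obs_names] + 100, obs_names), cfg,
    extras = c(recovery_quality = 2, injury_block = 10))
  expect_true(all(st_over$features >= 0 & st_over$features <= 1))
  expect_equal(unname(st_over$features["fatigue"]), 1)
  expect_equal(unname(st_over$features["hrv"]), 1)

  expect_error(
    build_state(physio_state(), prof, c(unknown_marker = 1), cfg),
    class = "loadctrl_config_error")
})

test_that("episodes are deterministic, 112 days long, and guard their lifecycle", {
  prof <- fixture_profile()
  env <- training_env(prof)
  s0 <- env_reset(env, 7)
  expect_equal(s0$day, 0)
  expect_false(s0$done)
  expect_true(all(s0$features >= 0 & s0$features <= 1))
  s0b <- env_reset(env, 7)
  expect_identical(s0$features, s0b$features)

  r1 <- run_episode(env, policy_constant(), seed = 11)
  r2 <- run_episode(env, policy_constant(), seed = 11)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$return, r2$return)
  expect_equal(nrow(r1$log), 112)
  expect_true(env$done)
  expect_error(env_step(env, 1), class = "loadctrl_state_error")
})

test_that("rest lowers fatigue and the pure-performance reward equals the gain", {
  prof <- fixture_profile()
  env <- training_env(prof, weights = reward_weights(1, 0, 0, 0))
  env_reset(env, 3)
  rest <- find_rest <- env$actions$action_id[
    env$actions$session_type == "active_recovery" &
      env$actions$recovery_protocol == "extended"][1]
  f_before <- env$physio$fatigue
  out <- env_step(env, rest)
  expect_lt(env$physio$fatigue, f_before)
  # with weights (1,0,0,0) the reward is exactly the normalized gain
  expect_equal(out$reward + as.numeric(out$info$injured) *
                 env$config$injury_penalty, out$info$perf_gain)
})

test_that("sustained maximal load causes more injuries than rest", {
  prof <- fixture_profile()
  env <- training_env(prof)
  hard <- env$actions$action_id[which.max(env$actions$tl)]
  inj <- function(action, seeds) {
    vapply(seeds, function(s) {
      run_episode(env, function(state, env) action, seed = s)$injuries
    }, integer(1))
  }
  rest <- env$actions$action_id[env$actions$tl == 0][1]
  seeds <- 1:15
  expect_gt(mean(inj(hard, seeds)), mean(inj(rest, seeds)))
})
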