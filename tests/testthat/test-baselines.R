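test_that("the periodization schedule is deterministic with a real deload", {
  acts <- action_table()
  ids <- vapply(0:111, periodization_policy, integer(1), actions = acts)
  ids2 <- vapply(0:111, periodization_policy, integer(1), actions = acts)
  expect_identical(ids, ids2)

  tl <- acts$tl[ids]
  # deload days (week 4 of block 1, excluding the weekly rest day) carry less
  # load than the preceding weeks
  deload_days <- 21:26
  build_days <- 0:20
  build_days <- build_days[build_days %% 7 != 6]
  expect_lt(max(tl[deload_days + 1]), min(tl[build_days + 1]))
  expect_gt(mean(tl[1:28]), mean(tl[22:28]))
  # intensity ramps across blocks
  expect_gt(mean(tl[85:105]), mean(tl[1:21]))
})

test_that("threshold rules step load down and never up", {
  acts <- action_table()
  maintain_tl <- acts$tl[rule_based_policy(
    c(hrv = 70, rpe = 4, soreness = 2), actions = acts)]
  expect_equal(maintain_tl, 0.5)

  reduce_hrv <- rule_based_policy(c(hrv = 55, rpe = 4, soreness = 2),
                                  actions = acts)
  reduce_rpe <- rule_based_policy(c(hrv = 70, rpe = 8, soreness = 2),
                                  actions = acts)
  reduce_sore <- rule_based_policy(c(hrv = 70, rpe = 4, soreness = 7),
                                   actions = acts)
  for (a in c(reduce_hrv, reduce_rpe, reduce_sore)) {
    expect_lt(acts$tl[a], maintain_tl)
  }

  # exhaustive grid: whenever any rule fires, the prescribed load never
  # exceeds the maintain load
  grid <- expand.grid(hrv = c(40, 55, 59, 60, 75), rpe = c(2, 7, 7.5, 9),
                      soreness = c(1, 6, 6.5, 9))
  for (i in seq_len(nrow(grid))) {
    obs <- c(hrv = grid$hrv[i], rpe = grid$rpe[i], soreness = grid$soreness[i])
    fired <- obs["hrv"] < 60 || obs["rpe"] > 7 || obs["soreness"] > 6
    tl_i <- acts$tl[rule_based_policy(obs, actions = acts)]
    if (fired) expect_lte(tl_i, maintain_tl) else expect_equal(tl_i, maintain_tl)
  }

  expect_warning(a <- rule_based_policy(c(rpe = 3), actions = acts),
                 "missing marker")
  expect_equal(acts$tl[a], 0.5)
})

test_that("regression prescription finds a constructed optimum", {
  acts <- action_table()
  # synthetic quadratic response peaked at TL* = 0.6
  tls <- rep(seq(0, 1, by = 0.1), 4)
  hist <- tibble::tibble(
    tl = tls,
    dperf = 1 - 8 * (tls - 0.6)^2,
    fatigue = 1
  )
  a <- regression_policy(hist, fatigue_now = 1, actions = acts)
  expect_lte(abs(acts$tl[a] - 0.6), 0.1)

  # constant performance: ties break to the lowest load
  hist0 <- tibble::tibble(tl = tls, dperf = 0.3, fatigue = 1)
  a0 <- regression_policy(hist0, fatigue_now = 1, actions = acts)
  expect_equal(acts$tl[a0], min(acts$tl))

  # not ready below the minimum history
  expect_null(regression_policy(hist[1:5, ], 1, acts))

  # fatigue guard caps the candidate load
  a_guard <- regression_policy(hist, fatigue_now = 10, actions = acts)
  expect_lte(acts$tl[a_guard], 0.45)
})

test_that("the feasible weight grid satisfies simplex and range constraints", {
  g <- weight_grid()
  expect_equal(nrow(g), 55)
  expect_true(all(abs(g$w_perf + g$w_injury + g$w_adherence + g$w_recovery - 1)
                  < 1e-9))
  expect_true(all(g$w_perf >= 0.3 & g$w_perf <= 0.5))
  expect_true(all(g$w_injury >= 0.2 & g$w_injury <= 0.4))
  expect_true(all(g$w_adherence >= 0.1 & g$w_adherence <= 0.3))
  expect_true(all(g$w_recovery >= 0.05 & g$w_recovery <= 0.15))
  # the published optimum is on the grid
  expect_true(any(g$w_perf == 0.4 & g$w_injury == 0.3 &
                    g$w_adherence == 0.2 & g$w_recovery == 0.1))
})

test_that("grid search filters infeasible candidates and ranks by score", {
  cohort <- fixture_cohort(4)
  budget <- calib_budget(episodes = 2L, eval_episodes = 1L)

  single <- tibble::tibble(w_perf = 0.4, w_injury = 0.3, w_adherence = 0.2,
                           w_recovery = 0.1)
  out <- grid_search_weights(cohort, grid = single, folds = 2L,
                             budget = budget, seed = 2)
  expect_equal(nrow(out), 1)
  expect_equal(out$rank, 1L)

  bad <- tibble::tibble(w_perf = c(0.4, 0.9), w_injury = c(0.3, -0.2),
                        w_adherence = c(0.2, 0.2), w_recovery = c(0.1, 0.1))
  out_bad <- grid_search_weights(cohort, grid = bad, folds = 2L,
                                 budget = budget, seed = 2)
  expect_equal(nrow(out_bad), 1)   # negative-weight row filtered pre-scoring

  all_bad <- tibble::tibble(w_perf = 0.9, w_injury = -0.2, w_adherence = 0.2,
                            w_recovery = 0.1)
  expect_error(grid_search_weights(cohort, grid = all_bad, folds = 2L,
                                   budget = budget, seed = 2),
               class = "loadctrl_config_error")
})

test_that("zero perturbation yields zero sensitivity", {
  cohort <- fixture_cohort(2)
  sens <- sensitivity_analysis(reward_weights(), perturbation = 0,
                               profiles = cohort, seed = 1, episodes = 2L,
                               config = reduced_agent_config(eval_every = 1e6L))
  expect_identical(sens$max_rel_change, 0)
  expect_equal(nrow(sens$table), 0)
})

test_that("phenotype clustering separates constructed groups", {
  slow <- lapply(1:6, function(i) {
    fixture_profile(k_accum = 0.5 + 0.01 * i, k_recover = 0.15,
                    adapt_coeff = 0.8, athlete_id = paste0("s", i))
  })
  fast <- lapply(1:6, function(i) {
    fixture_profile(k_accum = 1.8 + 0.01 * i, k_recover = 0.45,
                    adapt_coeff = 1.8, athlete_id = paste0("f", i))
  })
  res <- cluster_phenotypes(c(slow, fast), k = 2, seed = 9)
  truth <- rep(c(1, 2), each = 6)
  expect_equal(adjusted_rand(res$labels, truth), 1.0)

  res1 <- cluster_phenotypes(c(slow, fast), k = 1, seed = 9)
  expect_true(all(res1$labels == res1$labels[1]))

  dup <- c(slow[1], slow[1], slow[1])
  res_dup <- cluster_phenotypes(dup, k = 1, seed = 3)
  expect_true(all(res_dup$labels == res_dup$labels[1]))

  expect_error(cluster_phenotypes(slow, k = 10),
               class = "loadctrl_invalid_input")
})

test_that("phenotype hyperparameter table matches the published operating points", {
  expect_equal(phenotype_config("Endurance")$learning_rate, 0.0008)
  expect_equal(phenotype_config("Endurance")$discount, 0.95)
  expect_equal(phenotype_config("Speed")$learning_rate, 0.0015)
  expect_equal(phenotype_config("Speed")$discount, 0.88)
  expect_equal(phenotype_config("Novice")$learning_rate, 0.0005)
  expect_equal(phenotype_config("Novice")$discount, 0.98)
  expect_equal(phenotype_config("Elite")$learning_rate, 0.0014)
  expect_warning(cfg <- phenotype_config("Cyborg"), "unknown phenotype")
  expect_equal(cfg$learning_rate, agent_config()$learning_rate)
})

test_that("fatigue constants are recovered from noiseless trajectories", {
  prof <- fixture_profile(k_accum = 0.9, k_recover = 0.28, k_active = 0.22)
  traj <- simulate_fatigue_traj(prof, 200)
  fit <- fit_fatigue_params(traj)
  truth <- c(k1 = 0.9, k2 = 0.28, k3 = 0.22)
  expect_true(all(abs(fit$estimates - truth) / truth < 1e-3))
  expect_length(fit$flags, 0)
  expect_true(glance(fit)$converged)
})

test_that("pure decay identifies only the natural recovery rate", {
  prof <- fixture_profile(k_recover = 0.31)
  n <- 40
  f <- numeric(n)
  f[1] <- 4
  for (t in seq_len(n - 1)) f[t + 1] <- fatigue_step(f[t], 0, 0, prof)
  traj <- tibble::tibble(tl = 0, recovery = 0, fatigue = f)
  fit <- fit_fatigue_params(traj)
  expect_setequal(fit$flags, c("k1", "k3"))
  expect_equal(unname(fit$estimates["k2"]), 0.31, tolerance = 1e-6)
  expect_true(all(is.na(fit$estimates[c("k1", "k3")])))
})

test_that("estimation bias shrinks as noise shrinks", {
  prof <- fixture_profile(k_accum = 0.9, k_recover = 0.28, k_active = 0.22)
  truth <- c(0.9, 0.28, 0.22)
  err_at <- function(noise_frac, reps = 5) {
    median(vapply(seq_len(reps), function(r) {
      traj <- simulate_fatigue_traj(prof, 200, seed = 100 + r,
                                    noise_frac = noise_frac)
      fit <- fit_fatigue_params(traj)
      max(abs(fit$estimates - truth) / truth)
    }, numeric(1)))
  }
  errs <- c(err_at(0), err_at(0.01), err_at(0.05))
  expect_true(all(diff(errs) > 0))
  expect_lt(errs[1], 1e-3)
})
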