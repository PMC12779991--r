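test_that("epsilon decays linearly from 0.3 to 0.05 over the schedule", {
  cfg <- agent_config()
  expect_equal(epsilon_schedule(0, cfg), 0.3)
  expect_equal(epsilon_schedule(5000, cfg), 0.175)
  expect_equal(epsilon_schedule(10000, cfg), 0.05)
  expect_equal(epsilon_schedule(50000, cfg), 0.05)
})

test_that("action selection is greedy at epsilon zero and explores at one", {
  cfg0 <- agent_config(eps_start = 0, eps_end = 0)
  stream <- rng_stream(1)
  qv <- c(0.1, 0.9, 0.9, 0.2)
  # lowest-index tie break
  expect_identical(select_action(qv, 0, cfg0, stream), 2L)

  cfg1 <- agent_config(eps_start = 1, eps_end = 1)
  picks <- vapply(1:2000, function(i) select_action(qv, 0, cfg1, stream),
                  integer(1))
  expect_gt(chisq.test(tabulate(picks, 4))$p.value, 0.01)
})

test_that("TD loss obeys its limiting cases", {
  spec <- network_spec(input_dim = 4, hidden_dims = 5, dropout_rates = 0,
                       output_dim = 3)
  params <- network_init(spec, rng_stream(7))
  s <- matrix(runif(8), 2, 4)
  q <- q_forward(spec, params, s)$q

  # terminal transitions: td = r - Q(s, a); rewards set to Q give zero loss
  batch <- list(states = s, next_states = s, actions = c(1L, 2L),
                rewards = q[cbind(1:2, 1:2)], dones = c(TRUE, TRUE),
                weights = c(1, 1))
  cfg0 <- agent_config(l2_coeff = 0)
  res <- td_loss(batch, spec, params, params, cfg0)
  expect_equal(res$td, c(0, 0), tolerance = 1e-12)
  expect_equal(res$loss, 0, tolerance = 1e-12)

  batch$rewards <- c(2, -1)
  res2 <- td_loss(batch, spec, params, params, cfg0)
  expect_equal(res2$td, batch$rewards - q[cbind(1:2, 1:2)])

  # zero-TD batch with l2 > 0: loss is exactly the ridge penalty
  cfgl2 <- agent_config(l2_coeff = 0.02)
  batch$rewards <- q[cbind(1:2, 1:2)]
  res3 <- td_loss(batch, spec, params, params, cfgl2)
  sqn <- sum(vapply(params, function(l) sum(l$W^2) + sum(l$b^2), numeric(1)))
  expect_equal(res3$loss, 0.02 * sqn, tolerance = 1e-12)
})

test_that("training is bit-for-bit reproducible given a seed", {
  cohort <- fixture_cohort(2)
  envs1 <- lapply(cohort, training_env)
  envs2 <- lapply(cohort, training_env)
  cfg <- reduced_agent_config(eval_every = 5L, eval_episodes = 1L)
  a1 <- train_agent(envs1, 8, cfg, seed = 5)
  a2 <- train_agent(envs2, 8, cfg, seed = 5)
  expect_identical(a1$log, a2$log)
  expect_equal(a1$params, a2$params, tolerance = 1e-15)
  expect_equal(nrow(a1$log), 8)
  expect_true(all(is.finite(unlist(lapply(a1$params, `[[`, "W")))))
})

test_that("a one-day dose-response episode is solved by short training", {
  # degenerate single-decision environment with a pure performance reward:
  # the optimal action is any action attaining the maximal daily load
  cfg_env <- env_config(episode_days = 1L, hazard_scale = 0)
  prof <- fixture_profile()
  envs <- list(training_env(prof, cfg_env, reward_weights(1, 0, 0, 0)))
  cfg <- reduced_agent_config(eps_decay_episodes = 300L, batch_size = 32L,
                              eval_every = 10000L, train_every_steps = 1L)
  agent <- train_agent(envs, 500, cfg,
                       spec = network_spec(32, c(32, 16), c(0, 0),
                                           nrow(envs[[1]]$actions)),
                       seed = 3)
  st <- env_reset(envs[[1]], 1)
  a <- q_forward(agent$spec, agent$params, st)$greedy
  expect_equal(envs[[1]]$actions$tl[a], max(envs[[1]]$actions$tl))
})

test_that("the divergence guard aborts on a sustained exploding loss", {
  cohort <- fixture_cohort(1)
  envs <- lapply(cohort, training_env)
  cfg <- reduced_agent_config(loss_ceiling = 1e-9, divergence_steps = 2L)
  expect_error(train_agent(envs, 3, cfg, seed = 1),
               class = "loadctrl_divergence")
})

test_that("the Bellman-residual monitor summarizes and flags decay", {
  log_const <- tibble::tibble(episode = 1:20, mean_td = rep(0.5, 20))
  mon <- bellman_residual_monitor(log_const, window = 5)
  expect_false(mon$improving)
  expect_true(all(abs(mon$series$moving_mean - 0.5) < 1e-12))

  log_decay <- tibble::tibble(episode = 1:40,
                              mean_td = 2 * exp(-0.2 * (1:40)))
  expect_true(bellman_residual_monitor(log_decay, window = 5)$improving)

  mon_full <- bellman_residual_monitor(log_decay, window = 40)
  expect_equal(mon_full$series$moving_mean, mean(log_decay$mean_td))

  expect_error(bellman_residual_monitor(log_decay, window = 41),
               class = "loadctrl_invalid_input")
})
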