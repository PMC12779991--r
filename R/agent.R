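# DQN agent: epsilon-greedy control, prioritized replay, regularized TD loss
# with importance weighting, soft target updates, gradient clipping,
# plateau learning-rate scheduling and a divergence guard.

#' Agent hyperparameter configuration
#'
#' Defaults follow the published operating point: learning rate 0.001,
#' discount 0.95, epsilon decaying linearly from 0.3 to 0.05 over 10,000
#' episodes, soft-update coefficient 0.001, L2 coefficient 1e-4, batch size
#' 64, replay capacity 100,000, prioritization exponent 0.6 with importance
#' correction annealing 0.4 to 1, one optimization step per 4 environment
#' steps, gradient clip norm 10 and plateau LR halving.
#'
#' @param ... Named overrides merged over the defaults.
#' @return A list of class `agent_config`.
#' @export
agent_config <- function(...) {
  cfg <- list(
    learning_rate = 0.001,
    discount = 0.95,
    eps_start = 0.3, eps_end = 0.05, eps_decay_episodes = 10000L,
    tau = 0.001,
    target_update_every = NULL,    # NULL: soft update every optimization step
    l2_coeff = 1e-4,
    batch_size = 64L,
    replay_capacity = 100000L,
    per_alpha = 0.6,
    per_beta_start = 0.4, per_beta_end = 1.0,
    beta_anneal_episodes = 10000L,
    train_every_steps = 4L,
    grad_clip_norm = 10,
    eps_priority = 1e-3,
    lr_plateau_factor = 0.5, lr_plateau_patience = 20L,
    eval_every = 100L, eval_episodes = 4L,
    loss_ceiling = 1e4, divergence_steps = 200L
  )
  cfg <- modifyList(structure(cfg, class = "agent_config"), list(...))
  stopifnot(cfg$discount > 0, cfg$discount < 1,
            cfg$eps_end >= 0, cfg$eps_end <= cfg$eps_start, cfg$eps_start <= 1,
            cfg$tau > 0, cfg$tau <= 1,
            cfg$replay_capacity >= cfg$batch_size)
  cfg
}

#' Reduced desk-scale agent configuration
#'
#' Scaled-down counterpart of [agent_config()] for single-CPU experiments:
#' smaller replay buffer, epsilon and importance-correction schedules
#' compressed to a 1,500-episode horizon, more frequent evaluation.
#'
#' @param ... Named overrides.
#' @return An `agent_config`.
#' @export
reduced_agent_config <- function(...) {
  agent_config(
    replay_capacity = 20000L,
    eps_decay_episodes = 1500L,
    beta_anneal_episodes = 1500L,
    eval_every = 100L, eval_episodes = 3L,
    lr_plateau_patience = 8L,
    ...
  )
}

#' Exploration rate at a given episode
#'
#' Linear decay: `eps(e) = eps_start - (eps_start - eps_end) *
#' min(e / eps_decay_episodes, 1)`.
#'
#' @param episode Episode index (0-based).
#' @param config An [agent_config()].
#' @return Epsilon in \[eps_end, eps_start\].
#' @export
epsilon_schedule <- function(episode, config = agent_config()) {
  stopifnot(episode >= 0)
  config$eps_start - (config$eps_start - config$eps_end) *
    pmin(episode / config$eps_decay_episodes, 1)
}

per_beta_schedule <- function(episode, config) {
  config$per_beta_start + (config$per_beta_end - config$per_beta_start) *
    pmin(episode / config$beta_anneal_episodes, 1)
}

#' Epsilon-greedy action selection
#'
#' With probability `eps(episode)` a uniform random action, otherwise the
#' greedy argmax of the Q-values (lowest index on ties).
#'
#' @param q_values Numeric vector of per-action value estimates.
#' @param episode Episode index for the epsilon schedule.
#' @param config An [agent_config()].
#' @param stream [rng_stream()] supplying the exploration draws.
#' @return Integer action index.
#' @export
select_action <- function(q_values, episode, config, stream) {
  eps <- epsilon_schedule(episode, config)
  if (with_stream(stream, runif(1)) < eps) {
    with_stream(stream, sample.int(length(q_values), 1))
  } else {
    which.max(q_values)
  }
}

#' Regularized temporal-difference loss on a batch
#'
#' Importance-weighted mean squared TD error plus an L2 penalty:
#' `L = mean(w_i * (r_i + gamma * max_a Q(s'_i, a; theta^-) - Q(s_i, a_i))^2)
#' + l2_coeff * ||theta||^2`. Terminal transitions bootstrap to `r` alone.
#'
#' @param batch A batch from [sample_batch()].
#' @param spec A [network_spec()].
#' @param params,target_params Main and target `network_params`.
#' @param config An [agent_config()].
#' @param stream Optional [rng_stream()] for dropout (training mode); when
#'   `NULL` the forward pass is deterministic.
#' @return List with `loss`, `td` (per-transition signed TD errors) and
#'   `grads` (parameter gradients of the loss).
#' @export
td_loss <- function(batch, spec, params, target_params, config,
                    stream = NULL) {
  n <- length(batch$actions)
  X <- states_to_matrix(batch$states, spec$input_dim)
  X2 <- states_to_matrix(batch$next_states, spec$input_dim)
  q_next <- mlp_forward(spec, target_params, X2, mode = "eval")$out
  q_next_max <- q_next[cbind(seq_len(n), max.col(q_next, ties.method = "first"))]
  target <- batch$rewards +
    config$discount * q_next_max * (1 - as.numeric(batch$dones))
  mode <- if (is.null(stream)) "eval" else "train"
  fw <- mlp_forward(spec, params, X, mode = mode, stream = stream)
  sel <- cbind(seq_len(n), batch$actions)
  q_sa <- fw$out[sel]
  td <- target - q_sa
  w <- batch$weights %||% rep(1, n)
  loss <- mean(w * td^2) + config$l2_coeff * params_sqnorm(params)
  dOut <- matrix(0, n, spec$output_dim)
  dOut[sel] <- -2 * w * td / n
  grads <- mlp_backward(spec, params, fw, dOut)
  grads <- params_map2(grads, params, function(g, p) g + 2 * config$l2_coeff * p)
  list(loss = loss, td = td, grads = grads)
}

#' Train a DQN agent on a cohort of environments
#'
#' Runs epsilon-greedy episodes over the athlete environments (cycled in
#' order), storing transitions in a prioritized replay buffer. Every
#' `train_every_steps` environment steps one optimization step is taken:
#' sample a prioritized batch, descend the regularized TD loss (Adam,
#' gradient clipped to `grad_clip_norm`), refresh the sampled priorities from
#' the new TD errors, and soft-update the target network (or hard-copy every
#' `target_update_every` steps if configured). Greedy evaluations every
#' `eval_every` episodes drive plateau LR halving. All randomness flows from
#' three child streams (environment, agent, replay) derived from `seed`, so
#' runs are exactly reproducible.
#'
#' @param envs List of [training_env()] objects (one per athlete).
#' @param episodes Number of training episodes.
#' @param config An [agent_config()].
#' @param spec A [network_spec()]; defaults to the reduced desk-scale network
#'   sized to the environments' action space.
#' @param seed Master seed.
#' @param verbose Print evaluation progress.
#' @return An object of class `loadctrl_agent` with fields `spec`, `params`,
#'   `target_params`, `config`, `log` (per-episode tibble: return, mean
#'   absolute TD residual, epsilon, learning rate, injuries), `evals`.
#' @export
train_agent <- function(envs, episodes, config = reduced_agent_config(),
                        spec = NULL, seed = 1L, verbose = FALSE) {
  stopifnot(episodes >= 1, length(envs) >= 1)
  n_actions <- nrow(envs[[1]]$actions)
  spec <- spec %||% reduced_network_spec(output_dim = n_actions)
  if (spec$output_dim != n_actions) {
    abort("network output_dim must equal the action-space size",
          class = "loadctrl_config_error")
  }
  agent_stream <- rng_stream(derive_seed(seed, "agent"))
  replay_stream <- rng_stream(derive_seed(seed, "replay"))
  params <- network_init(spec, agent_stream)
  target_params <- params
  opt <- adam_init(params)
  feat_dim <- length(env_reset(envs[[1]], derive_seed(seed, "probe"))$features)
  buffer <- replay_buffer(config$replay_capacity, feat_dim)

  lr <- config$learning_rate
  best_eval <- -Inf
  evals_since_best <- 0L
  step_count <- 0L
  opt_steps <- 0L
  diverged_run <- 0L
  evals <- list()
  log_rows <- vector("list", episodes)

  for (ep in seq_len(episodes)) {
    env <- envs[[((ep - 1L) %% length(envs)) + 1L]]
    state <- env_reset(env, derive_seed(seed, paste0("episode", ep)))
    ep_return <- 0
    ep_td <- numeric(0)
    beta <- per_beta_schedule(ep - 1L, config)
    repeat {
      qv <- q_forward(spec, params, state)$q[1, ]
      a <- select_action(qv, ep - 1L, config, agent_stream)
      out <- env_step(env, a)
      replay_add(buffer, state$features, a, out$reward, out$state$features,
                 out$done)
      ep_return <- ep_return + out$reward
      state <- out$state
      step_count <- step_count + 1L

      if (step_count %% config$train_every_steps == 0L) {
        batch <- sample_batch(buffer, config$batch_size, config$per_alpha,
                              beta, replay_stream)
        if (!is.null(batch)) {
          res <- td_loss(batch, spec, params, target_params, config,
                         stream = agent_stream)
          if (!is.finite(res$loss) || res$loss > config$loss_ceiling) {
            diverged_run <- diverged_run + 1L
            if (diverged_run >= config$divergence_steps) {
              abort(sprintf(
                "divergence guard: loss above %.3g for %d consecutive steps",
                config$loss_ceiling, diverged_run),
                class = "loadctrl_divergence")
            }
          } else diverged_run <- 0L
          gn <- grad_global_norm(res$grads)
          grads <- if (gn > config$grad_clip_norm) {
            params_map(res$grads, function(g) g * (config$grad_clip_norm / gn))
          } else res$grads
          st <- adam_step(params, grads, opt, lr)
          params <- st$params
          opt <- st$opt
          opt_steps <- opt_steps + 1L
          update_priorities(buffer, batch$indices, res$td,
                            config$eps_priority)
          if (is.null(config$target_update_every)) {
            target_params <- soft_update(params, target_params, config$tau)
          } else if (opt_steps %% config$target_update_every == 0L) {
            target_params <- params
          }
          ep_td <- c(ep_td, mean(abs(res$td)))
        }
      }
      if (out$done) break
    }

    if (ep %% config$eval_every == 0L) {
      agent_now <- structure(list(spec = spec, params = params), class = "loadctrl_agent")
      ev <- mean(vapply(seq_len(config$eval_episodes), function(k) {
        e <- envs[[((k - 1L) %% length(envs)) + 1L]]
        run_episode(e, policy_agent(agent_now),
                    seed = derive_seed(seed, paste0("eval", k)))$return
      }, numeric(1)))
      evals[[length(evals) + 1L]] <- tibble(episode = ep, mean_return = ev, lr = lr)
      if (ev > best_eval + 1e-9) {
        best_eval <- ev
        evals_since_best <- 0L
      } else {
        evals_since_best <- evals_since_best + 1L
        if (evals_since_best >= config$lr_plateau_patience) {
          lr <- lr * config$lr_plateau_factor
          evals_since_best <- 0L
        }
      }
      if (verbose) {
        message(sprintf("episode %d: eval return %.3f (lr %.2g)", ep, ev, lr))
      }
    }

    log_rows[[ep]] <- tibble(
      episode = ep, return = ep_return,
      mean_td = if (length(ep_td)) mean(ep_td) else NA_real_,
      epsilon = epsilon_schedule(ep - 1L, config), lr = lr,
      injuries = env$injury_count
    )
  }

  structure(
    list(spec = spec, params = params, target_params = target_params,
         config = config, log = dplyr::bind_rows(log_rows),
         evals = dplyr::bind_rows(evals), opt_steps = opt_steps, seed = seed),
    class = "loadctrl_agent"
  )
}

#' @export
print.loadctrl_agent <- function(x, ...) {
  cat(sprintf(
    "<loadctrl_agent: %d-%s-%d network, %d episodes trained, %d optimization steps>\n",
    x$spec$input_dim, paste(x$spec$hidden_dims, collapse = "-"),
    x$spec$output_dim, if (!is.null(x$log)) nrow(x$log) else 0L,
    x$opt_steps %||% 0L))
  invisible(x)
}

#' Empirical Bellman-residual monitor
#'
#' Moving-window mean of the per-episode absolute TD residuals from a
#' training log, plus a convergence-trend flag: `TRUE` when the mean over the
#' final window is at most `fraction` times the mean over the initial window.
#' This is an empirical stability diagnostic, not a formal convergence bound.
#'
#' @param log Training log tibble with a `mean_td` column (NA rows, from
#'   episodes before learning started, are dropped).
#' @param window Window length in episodes.
#' @param fraction Decay fraction defining the trend flag.
#' @return A list with `series` (tibble: episode, residual, moving mean) and
#'   `improving` flag.
#' @export
bellman_residual_monitor <- function(log, window, fraction = 0.5) {
  res <- log$mean_td[!is.na(log$mean_td)]
  eps <- log$episode[!is.na(log$mean_td)]
  if (window > length(res)) {
    abort("window exceeds the number of logged residuals",
          class = "loadctrl_invalid_input")
  }
  mv <- vapply(seq_len(length(res) - window + 1L),
               function(i) mean(res[i:(i + window - 1L)]), numeric(1))
  flag <- tail(mv, 1) <= fraction * mv[1]
  list(
    series = tibble(episode = eps[seq_along(mv) + window - 1L],
                    residual = res[seq_along(mv) + window - 1L],
                    moving_mean = mv),
    improving = flag
  )
}
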