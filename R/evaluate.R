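# Evaluation statistics and the paired policy-comparison harness:
# sport-weighted performance improvement, discounted long-term effectiveness,
# the multi-athlete objective, injury rate per 100 training hours, training
# efficiency, and bootstrap/Cohen's-d paired inference.

#' Sport-weighted performance improvement (percent)
#'
#' `PI = (p_post - p_base) / p_base * 100 * w_sport`. Scale-invariant in the
#' performance units.
#'
#' @param p_post Post-intervention performance (> 0 scale shared with
#'   `p_base`).
#' @param p_base Baseline performance (> 0).
#' @param w_sport Sport-specific weighting factor (default 1).
#' @return Improvement in percent.
#' @examples
#' performance_improvement(110, 100)        # 10
#' performance_improvement(110, 100, 1.2)   # 12
#' @export
performance_improvement <- function(p_post, p_base, w_sport = 1) {
  if (any(!is.finite(p_base)) || any(p_base <= 0)) {
    abort("`p_base` must be positive and finite", class = "loadctrl_invalid_input")
  }
  (p_post - p_base) / p_base * 100 * w_sport
}

#' Discounted long-term effectiveness
#'
#' `E = (1/T) * sum_t alpha^t * PI_t * (1 - beta * sigma_t)`, with the
#' variability factor clamped at zero so a very volatile period cannot
#' contribute negatively through the penalty alone.
#'
#' @param pi_series Performance improvements per period (length T >= 1).
#' @param sigma_series Within-period variability per period (same length).
#' @param temporal_alpha Temporal weight base (default 0.95).
#' @param beta_penalty Variability penalty coefficient (default 0.1).
#' @return Scalar effectiveness.
#' @examples
#' long_term_effectiveness(c(10, 10), c(0, 1), temporal_alpha = 0.9, beta_penalty = 0.1)
#' @export
long_term_effectiveness <- function(pi_series, sigma_series,
                                    temporal_alpha = 0.95,
                                    beta_penalty = 0.1) {
  if (length(pi_series) != length(sigma_series) || !length(pi_series)) {
    abort("pi_series and sigma_series must be equal nonzero length",
          class = "loadctrl_invalid_input")
  }
  t <- seq_along(pi_series)
  mean(temporal_alpha^t * pi_series * pmax(0, 1 - beta_penalty * sigma_series))
}

#' Multi-athlete collaborative objective
#'
#' `J = sum_i w_i * J_i + lambda * J_collective + mu * C_resource`.
#'
#' @param w Nonnegative athlete weights.
#' @param J Individual objective values (same length as `w`).
#' @param J_collective Collective performance term.
#' @param C_resource Resource-constraint penalty term.
#' @param lambda,mu Regularization coefficients.
#' @return Scalar objective.
#' @export
multi_objective <- function(w, J, J_collective = 0, C_resource = 0,
                            lambda = 0, mu = 0) {
  if (length(w) != length(J)) {
    abort("w and J must have equal length", class = "loadctrl_invalid_input")
  }
  if (any(w < 0)) abort("athlete weights must be >= 0", class = "loadctrl_invalid_input")
  sum(w * J) + lambda * J_collective + mu * C_resource
}

#' Cohen's d for paired differences
#' @param diffs Numeric vector of paired differences.
#' @return Standardized mean difference `mean(d) / sd(d)`.
#' @export
cohens_d_paired <- function(diffs) mean(diffs) / sd(diffs)

#' Percentile bootstrap CI of a mean
#'
#' @param x Numeric vector.
#' @param reps Bootstrap replicates.
#' @param stream An [rng_stream()].
#' @param conf Confidence level.
#' @return Named vector `c(lower, upper)`.
#' @export
bootstrap_mean_ci <- function(x, reps = 2000L, stream, conf = 0.95) {
  n <- length(x)
  means <- with_stream(stream, {
    idx <- matrix(sample.int(n, n * reps, replace = TRUE), nrow = reps)
    rowMeans(matrix(x[idx], nrow = reps))
  })
  a <- (1 - conf) / 2
  setNames(quantile(means, c(a, 1 - a), names = FALSE), c("lower", "upper"))
}

#' Compare policies on a common seeded cohort (paired design)
#'
#' Every policy runs the same athlete-episodes under identical environment
#' seeds, so per-athlete outcomes are paired across policies. Reports
#' per-policy mean performance improvement, injuries per 100 simulated
#' training hours (daily load is converted to hours with a nominal
#' `hours_per_load` scaling), and training efficiency (improvement per unit
#' cumulative load); plus, against the first (reference) policy,
#' paired-difference means, percentile bootstrap CIs and Cohen's d.
#'
#' @param policies Named list of `loadctrl_policy` objects (>= 2); the first
#'   is the comparison reference.
#' @param cohort List of [athlete_profile()].
#' @param episodes_per_athlete Episodes per athlete per policy.
#' @param seed Integer seed; drives the shared per-episode environment seeds
#'   and the bootstrap.
#' @param bootstrap_reps Percentile-bootstrap replicates.
#' @param weights A [reward_weights()] used by every environment.
#' @param env_cfg An [env_config()].
#' @param w_sport Named sport weights applied to PI (default all 1).
#' @param hours_per_load Nominal hours of training per unit daily load.
#' @return An object of class `eval_report`: list with `per_athlete`,
#'   `summary`, `comparisons` tibbles and the call settings.
#' @export
compare_policies <- function(policies, cohort, episodes_per_athlete = 1L,
                             seed = 1L, bootstrap_reps = 2000L,
                             weights = reward_weights(),
                             env_cfg = env_config(),
                             w_sport = NULL, hours_per_load = 2) {
  if (length(policies) < 2) {
    abort("need at least two policies to compare", class = "loadctrl_invalid_input")
  }
  if (!length(cohort)) abort("empty cohort", class = "loadctrl_invalid_input")
  if (is.null(names(policies)) || any(names(policies) == "")) {
    names(policies) <- paste0("policy_", seq_along(policies))
  }

  per <- purrr::imap(policies, function(pol, pname) {
    purrr::imap(cohort, function(p, i) {
      env <- training_env(p, config = env_cfg, weights = weights)
      purrr::map(seq_len(episodes_per_athlete), function(k) {
        # identical seed across policies -> paired episodes
        ep_seed <- derive_seed(seed, sprintf("athlete%s-rep%d", i, k))
        policy_reset(pol, derive_seed(ep_seed, pname))
        r <- run_episode(env, pol, seed = ep_seed)
        ws <- if (!is.null(w_sport) && !is.null(p$sport)) {
          w_sport[[p$sport]] %||% 1
        } else 1
        cum_tl <- sum(r$log$tl)
        tibble(
          policy = pname, athlete_id = p$athlete_id, rep = k,
          env_seed = ep_seed,
          pi = performance_improvement(r$perf_end, r$perf_start, ws),
          injuries = r$injuries,
          training_hours = cum_tl * hours_per_load,
          cum_tl = cum_tl,
          efficiency = if (cum_tl > 0)
            performance_improvement(r$perf_end, r$perf_start, ws) / cum_tl
          else NA_real_,
          return = r$return
        )
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  summary <- per |>
    dplyr::group_by(policy) |>
    dplyr::summarise(
      mean_pi = mean(pi),
      injury_rate_per_100h = 100 * sum(injuries) / sum(training_hours),
      mean_efficiency = mean(efficiency, na.rm = TRUE),
      mean_return = mean(return),
      .groups = "drop"
    )

  ref <- names(policies)[1]
  boot_stream <- rng_stream(derive_seed(seed, "bootstrap"))
  comparisons <- purrr::map(setdiff(names(policies), ref), function(pname) {
    a <- per[per$policy == pname, ]
    b <- per[per$policy == ref, ]
    key <- paste(a$athlete_id, a$rep)
    stopifnot(identical(key, paste(b$athlete_id, b$rep)),
              identical(a$env_seed, b$env_seed))   # paired-design assertion
    d <- a$pi - b$pi
    ci <- bootstrap_mean_ci(d, bootstrap_reps, boot_stream)
    tibble(policy = pname, reference = ref, mean_diff_pi = mean(d),
           ci_lower = ci["lower"], ci_upper = ci["upper"],
           cohens_d = if (sd(d) > 0) cohens_d_paired(d) else 0,
           n_pairs = length(d))
  }) |> dplyr::bind_rows()

  structure(
    list(per_athlete = per, summary = summary, comparisons = comparisons,
         reference = ref, seed = seed, bootstrap_reps = bootstrap_reps,
         hours_per_load = hours_per_load),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(x$summary)
  if (nrow(x$comparisons)) {
    cat(sprintf("paired comparisons vs '%s':\n", x$reference))
    print(x$comparisons)
  }
  invisible(x)
}

#' @rdname compare_policies
#' @param x An `eval_report`.
#' @param ... Unused.
#' @export
tidy.eval_report <- function(x, ...) x$per_athlete

#' @rdname compare_policies
#' @export
glance.eval_report <- function(x, ...) x$summary

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
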