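# Shared fixtures: small deterministic profiles and cohorts built in code.

fixture_profile <- function(k_accum = 1.0, k_recover = 0.25, k_active = 0.3,
                            adapt_coeff = 1.0, adapt_rate = 2.0,
                            fatigue_sens = 0.05, ...) {
  athlete_profile(k_accum = k_accum, k_recover = k_recover,
                  k_active = k_active, adapt_coeff = adapt_coeff,
                  adapt_rate = adapt_rate, fatigue_sens = fatigue_sens, ...)
}

fixture_cohort <- function(n = 4, seed = 42) {
  generate_cohort(cohort_spec(n_athletes = n, seed = seed))
}

# adjusted Rand index, computed from the contingency table (independent of
# any clustering code in the package)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maximum <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maximum - expected)
}

# Simulate a daily (load, recovery, fatigue) trajectory from known constants;
# Gaussian observation noise is scaled to the clean fatigue range.
simulate_fatigue_traj <- function(profile, n_days, seed = NULL,
                                  noise_frac = 0) {
  if (!is.null(seed)) set.seed(seed)
  tl <- rep(c(0.9, 0.5, 0, 0.7, 0.2, 0.8, 0), length.out = n_days)
  rec <- rep(c(0.2, 0.6, 1, 0.2), length.out = n_days)
  f <- numeric(n_days)
  f[1] <- 2
  for (t in seq_len(n_days - 1)) {
    f[t + 1] <- fatigue_step(f[t], tl[t], rec[t], profile)
  }
  obs <- f + if (noise_frac > 0) rnorm(n_days, 0, noise_frac * diff(range(f))) else 0
  tibble::tibble(tl = tl, recovery = rec, fatigue = obs)
}
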