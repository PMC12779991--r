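# Estimation of the fatigue-dynamics rate constants (k1, k2, k3) from a
# daily (load, recovery, fatigue) trajectory by nonlinear least squares on
# the Euler-discretized fatigue ODE.

#' Fit fatigue rate constants from a daily trajectory
#'
#' Minimizes the one-step-ahead residuals of the Euler-discretized fatigue
#' dynamics, `F[t+1] - (F[t] + dt * (k1 * TL[t] - k2 * F[t] - k3 * R[t]))`,
#' by bounded Levenberg-Marquardt least squares (all rates constrained
#' nonnegative). Structurally unidentifiable constants — `k1` when the load
#' column has zero variance, `k3` when the recovery column does — are fixed
#' at zero and flagged rather than estimated.
#'
#' @param trajectory Tibble/data frame with columns `tl`, `recovery`,
#'   `fatigue` (one row per day, at least 30 days).
#' @param dt Time step in days.
#' @param start Named starting values for `(k1, k2, k3)`.
#' @return An object of class `fatigue_fit`: list with `estimates` (named
#'   k1/k2/k3, `NA` where unidentifiable), `flags` (character vector of
#'   unidentifiable constants), `residual_norm`, `n_days` and the `nls.lm`
#'   convergence info.
#' @examples
#' prof <- athlete_profile(k_accum = 0.9, k_recover = 0.3, k_active = 0.2)
#' tl <- rep(c(0.8, 0.5, 0, 0.6), length.out = 60)
#' rec <- rep(c(0.2, 0.6), length.out = 60)
#' f <- numeric(61); for (t in 1:60) f[t + 1] <- fatigue_step(f[t], tl[t], rec[t], prof)
#' fit <- fit_fatigue_params(tibble::tibble(tl = tl, recovery = rec, fatigue = f[1:60]))
#' fit$estimates
#' @export
fit_fatigue_params <- function(trajectory, dt = 1,
                               start = c(k1 = 0.5, k2 = 0.5, k3 = 0.5)) {
  need <- c("tl", "recovery", "fatigue")
  if (!all(need %in% names(trajectory))) {
    abort("trajectory needs columns tl, recovery, fatigue",
          class = "loadctrl_invalid_input")
  }
  n <- nrow(trajectory)
  if (n < 30) {
    abort("at least 30 days of trajectory are required",
          class = "loadctrl_invalid_input")
  }
  tl <- trajectory$tl[-n]
  rec <- trajectory$recovery[-n]
  f0 <- trajectory$fatigue[-n]
  f1 <- trajectory$fatigue[-1]

  flags <- character(0)
  free <- c(k1 = TRUE, k2 = TRUE, k3 = TRUE)
  if (sd(tl) < 1e-12 && all(tl == 0)) { flags <- c(flags, "k1"); free["k1"] <- FALSE }
  else if (sd(tl) < 1e-12) flags <- c(flags, "k1")   # constant nonzero load: k1 confounded with k3/k2 scale
  if (sd(rec) < 1e-12 && all(rec == 0)) { flags <- c(flags, "k3"); free["k3"] <- FALSE }
  else if (sd(rec) < 1e-12) flags <- c(flags, "k3")
  if (sd(f0) < 1e-12) flags <- unique(c(flags, "k2"))

  resid_fn <- function(par) {
    k <- c(k1 = 0, k2 = 0, k3 = 0)
    k[names(par)] <- par
    pred <- f0 + dt * (k["k1"] * tl - k["k2"] * f0 - k["k3"] * rec)
    f1 - pmax(pred, 0)
  }
  par0 <- start[names(free)[free]]
  fit <- minpack.lm::nls.lm(
    par = par0, fn = resid_fn,
    lower = rep(0, length(par0)),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- c(k1 = NA_real_, k2 = NA_real_, k3 = NA_real_)
  est[names(fit$par)] <- fit$par
  est[intersect(names(est), flags)] <- NA_real_
  structure(
    list(estimates = est, flags = unique(flags),
         residual_norm = sqrt(sum(resid_fn(fit$par)^2)),
         n_days = n, info = fit$info, message = fit$message),
    class = "fatigue_fit"
  )
}

#' @export
print.fatigue_fit <- function(x, ...) {
  cat("<fatigue_fit>\n  estimates:",
      paste(sprintf("%s=%.4g", names(x$estimates), x$estimates), collapse = ", "),
      sprintf("\n  residual norm %.4g over %d days", x$residual_norm, x$n_days), "\n")
  if (length(x$flags)) cat("  unidentifiable:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname fit_fatigue_params
#' @param x A `fatigue_fit`.
#' @param ... Unused.
#' @export
tidy.fatigue_fit <- function(x, ...) {
  tibble(term = names(x$estimates), estimate = unname(x$estimates),
         identifiable = !names(x$estimates) %in% x$flags)
}

#' @rdname fit_fatigue_params
#' @export
glance.fatigue_fit <- function(x, ...) {
  tibble(residual_norm = x$residual_norm, n_days = x$n_days,
         n_flagged = length(x$flags), converged = x$info %in% 1:4)
}
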