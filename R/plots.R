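# ggplot2 visualisations for training logs, episode trajectories and policy
# comparisons.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col geom_errorbar
#'   facet_wrap labs theme_minimal autoplot
NULL

#' Plot a training log
#'
#' Per-episode return and mean absolute TD residual over training.
#'
#' @param object A `loadctrl_agent`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.loadctrl_agent <- function(object, ...) {
  df <- object$log |>
    tidyr::pivot_longer(c("return", "mean_td"), names_to = "metric")
  ggplot(df, aes(x = .data$episode, y = .data$value)) +
    geom_line(na.rm = TRUE, colour = "steelblue") +
    facet_wrap(~metric, scales = "free_y", ncol = 1) +
    labs(x = "episode", y = NULL,
         title = "DQN training: episode return and Bellman residual") +
    theme_minimal()
}

#' Plot a policy-comparison report
#'
#' Mean performance improvement per policy with paired-difference context.
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot(object$per_athlete,
         aes(x = .data$policy, y = .data$pi)) +
    geom_point(alpha = 0.5, position = ggplot2::position_jitter(width = 0.08)) +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 3,
                          colour = "firebrick") +
    labs(x = NULL, y = "performance improvement (%)",
         title = "Per-athlete performance improvement by policy",
         subtitle = "red points: policy means; paired across identical seeds") +
    theme_minimal()
}

#' Plot one episode trajectory
#'
#' Daily load, latent performance, fatigue and injury hazard over the
#' macrocycle.
#'
#' @param log Episode log tibble from [run_episode()].
#' @return A ggplot object.
#' @export
plot_trajectory <- function(log) {
  df <- log |>
    dplyr::select("day", "tl", "performance", "fatigue", "risk") |>
    tidyr::pivot_longer(-"day", names_to = "series")
  ggplot(df, aes(x = .data$day, y = .data$value)) +
    geom_line(colour = "steelblue") +
    facet_wrap(~series, scales = "free_y", ncol = 1) +
    labs(x = "day of macrocycle", y = NULL,
         title = "Simulated athlete trajectory") +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
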