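#' Plot the time evolution of strategy frequencies
#'
#' Domain-growth style plot: one line per strategy, log time axis. Requires a
#' simulation run with `record = "log"`.
#'
#' @param object a `sim_result` from [run_simulation()].
#' @param smooth apply [smooth_trajectory()] first?
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.sim_result <- function(object, smooth = TRUE, ...) {
  traj <- object$trajectory
  if (!nrow(traj)) stop("no trajectory recorded; rerun with record = 'log'",
                        call. = FALSE)
  if (smooth) traj <- smooth_trajectory(traj)
  long <- tidyr::pivot_longer(traj, dplyr::starts_with("rho_"),
                              names_to = "strategy", names_prefix = "rho_",
                              values_to = "rho")
  ggplot2::ggplot(long, ggplot2::aes(.data$t_mcs, .data$rho,
                                     colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "t (MCS)", y = expression(rho[i]), colour = "strategy")
}

#' Plot a power-law fit on log-log axes
#'
#' Order parameter against the reduced noise `(K_c - K) / K_c` with the
#' fitted power law overlaid.
#'
#' @param object a [fit_power_law()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.power_law_fit <- function(object, ...) {
  co <- setNames(object$estimate$estimate, object$estimate$term)
  d <- dplyr::mutate(object$data, tau = (co["K_c"] - .data$K) / co["K_c"],
                     in_window = .data$K >= object$window[1])
  ggplot2::ggplot(d, ggplot2::aes(.data$tau, .data$m)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$in_window)) +
    ggplot2::geom_line(ggplot2::aes(y = co["B"] * .data$tau^co["beta"]),
                       linetype = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression((K[c] - K) / K[c]), y = "order parameter",
                  shape = "in fit window")
}

#' Plot mean-field or pair-approximation branches
#'
#' Strategy frequencies of every tracked branch against the noise level, the
#' standard phase-diagram companion plot. Stable states are drawn with solid,
#' unstable with dashed lines.
#'
#' @param branches tibble from [mf_branches()].
#' @return A ggplot object.
#' @export
plot_branches <- function(branches) {
  long <- tidyr::pivot_longer(branches, dplyr::starts_with("rho_"),
                              names_to = "strategy", names_prefix = "rho_",
                              values_to = "rho")
  ggplot2::ggplot(long, ggplot2::aes(.data$K, .data$rho,
                                     colour = .data$strategy,
                                     linetype = .data$stable,
                                     group = interaction(.data$branch,
                                                         .data$strategy))) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid",
                                              `FALSE` = "dashed")) +
    ggplot2::labs(x = "K", y = expression(rho[i]))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
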