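#' Plot a triggered average
#'
#' Lag on the x axis (trigger at 0, dashed line), mean stimulus derivative
#' with a +/-1 se ribbon.
#'
#' @param object A [triggered_average()] result.
#' @param smooth_sd Optional Gaussian display smoothing in seconds (the
#'   underlying estimate is never smoothed); 0 disables.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tta <- function(object, smooth_sd = 0, ...) {
  df <- as_tibble(object)
  if (smooth_sd > 0) {
    bw <- attr(object, "bin") %||% 0.1
    df$mean <- gauss_smooth(df$mean, smooth_sd / bw)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag_s, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::labs(x = "lag (s)", y = "mean stimulus derivative",
                  title = sprintf("%s-triggered average (%d triggers)",
                                  attr(object, "trigger"),
                                  attr(object, "n_triggers")))
}

#' Plot a binned nonlinearity estimate
#'
#' Turn rate versus filtered-signal value with counting-statistics error
#' bars; optionally overlays a ratio-of-Gaussians curve.
#'
#' @param object A [binned_turn_rate()] result.
#' @param nl Optional [rog_nl()] to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nl_estimate <- function(object, nl = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$x, y = .data$rate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$rate - .data$se,
                                          ymax = .data$rate + .data$se)) +
    ggplot2::labs(x = "filtered signal", y = "turn rate (1/s)")
  if (!is.null(nl)) {
    xs <- seq(min(object$x), max(object$x), length.out = 200)
    p <- p + ggplot2::geom_line(
      data = tibble(x = xs, rate = rog_rate(xs, nl)),
      colour = "black")
  }
  p
}

#' Plot the turn-triggered ensemble
#'
#' 2D density of the turn-triggered `(x_O, x_L)` pairs, with the rotated
#' axes overlaid when an angle is given.
#'
#' @param ens A [build_ensemble()] result.
#' @param theta_deg Optional combination angle to draw the (u, v) axes.
#' @param bins 2D bin width (default 0.25, matching the nonlinearity bins).
#' @return A ggplot.
#' @export
plot_ensemble <- function(ens, theta_deg = NULL, bins = 0.25) {
  rng <- range(c(ens$turn$x_O, ens$turn$x_L))
  p <- ggplot2::ggplot(ens$turn, ggplot2::aes(.data$x_O, .data$x_L)) +
    ggplot2::geom_bin2d(binwidth = c(bins, bins)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x_O (filtered odor)", y = "x_L (filtered light)")
  if (!is.null(theta_deg)) {
    th <- deg2rad(theta_deg)
    r <- max(abs(rng))
    ax <- tibble(x = c(-r * cos(th), -r * -sin(th)),
                 y = c(-r * sin(th), -r * cos(th)),
                 xend = c(r * cos(th), r * -sin(th)),
                 yend = c(r * sin(th), r * cos(th)),
                 axis = c("u", "v"))
    p <- p + ggplot2::geom_segment(
      data = ax,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend,
                   linetype = .data$axis),
      inherit.aes = FALSE, colour = "red")
  }
  p
}

#' Plot predicted versus observed step response
#'
#' @param predicted [predict_step_response()] output.
#' @param observed [observed_step_response()] output.
#' @return A ggplot.
#' @export
plot_step_response <- function(predicted, observed) {
  ggplot2::ggplot(observed, ggplot2::aes(x = .data$cycle_t_s, y = .data$rate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$rate - .data$se,
                                      ymax = .data$rate + .data$se),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_line(data = predicted, colour = "cyan3") +
    ggplot2::labs(x = "time in cycle (s)", y = "turn rate (1/s)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
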