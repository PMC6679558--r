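#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the main result objects: simulated
#' walks (foot sagittal gyro with event markers), orientation fits
#' (per-segment angles), step tables (per-step lengths by method) and
#' strapdown fits (horizontal foot trajectory per stride).
#'
#' @name gaitkin-plots
NULL

#' @rdname gaitkin-plots
#' @param object object to plot.
#' @param site which sensor trace to show for a simulated walk.
#' @param ... unused.
#' @export
autoplot.gait_sim <- function(object, site = "foot_R", ...) {
  tr <- site_trace(object$log, site)
  ft <- if (site == "foot_L") "left" else "right"
  ev <- object$truth$events
  ev <- ev[ev$foot == ft, ]
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$t, y = .data$wy)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_vline(data = ev,
                        ggplot2::aes(xintercept = .data$t,
                                     colour = .data$event),
                        linetype = "dashed", alpha = 0.7) +
    ggplot2::labs(x = "time (s)", y = "sagittal angular rate (rad/s)",
                  colour = "event",
                  title = sprintf("Simulated %s trace", site))
}

#' @rdname gaitkin-plots
#' @export
autoplot.orientation_fit <- function(object, ...) {
  ang <- tidyr::pivot_longer(object$angles,
                             cols = c("roll", "pitch", "yaw"),
                             names_to = "angle", values_to = "value")
  ggplot2::ggplot(ang, ggplot2::aes(x = .data$t,
                                    y = .data$value * 180 / pi,
                                    colour = .data$segment)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~angle, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "angle (deg)",
                  title = "Estimated lower-limb segment orientation")
}

#' @rdname gaitkin-plots
#' @export
autoplot.gait_report <- function(object, ...) {
  st <- object$steps
  st <- st[!st$excluded & st$kind %in% c("step_length_feet",
                                         "stride_length"), ]
  ggplot2::ggplot(st, ggplot2::aes(x = .data$t_heel_strike,
                                   y = .data$value,
                                   colour = .data$method,
                                   shape = .data$kind)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "heel-strike time (s)", y = "length (m)",
                  title = "Step and stride lengths by method")
}

#' @rdname gaitkin-plots
#' @export
autoplot.strapdown_fit <- function(object, ...) {
  tr <- object$trajectories
  if (is.null(tr)) abort("no trajectories recorded",
                         class = "gaitkin_invalid_argument")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$stride,
                                   colour = factor(.data$stride))) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "forward (m)", y = "across (m)", colour = "stride",
                  title = "Strapdown foot trajectory per stride")
}
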