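#' Plot a neural trace with detected or ground-truth spikes
#'
#' @param object A `neural_trace`.
#' @param spikes Optional `spike_train` to overlay; defaults to the
#'   ground-truth spike times.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.neural_trace <- function(object, spikes = NULL, ...) {
  df <- tidy(object)
  st <- if (!is.null(spikes)) spikes$times else object$truth$spike_times
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$voltage)) +
    ggplot2::geom_line(linewidth = 0.2, colour = "grey30") +
    ggplot2::labs(x = "time (s)", y = "voltage (µV)")
  if (length(st) > 0) {
    p <- p + ggplot2::geom_rug(
      data = tibble(time = st), ggplot2::aes(x = .data$time),
      inherit.aes = FALSE, colour = "firebrick", sides = "t")
  }
  if (nrow(object$epochs) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$epochs,
      ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.08, fill = "steelblue")
  }
  p
}

#' Plot a tracked OCT surface
#'
#' @param object A `surface_track`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.surface_track <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$depth)) +
    ggplot2::geom_line(na.rm = TRUE, colour = "grey20") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "time (s)", y = "surface depth (µm)")
}

#' Plot per-condition displacement means with confidence intervals
#'
#' @param object A `condition_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.condition_comparison <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(.data$condition, .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lwr,
                                          ymax = .data$ci_upr)) +
    ggplot2::labs(x = NULL, y = "displacement (µm)")
}

#' Quiver-style plot of a cumulative displacement field
#'
#' @param object A `cumulative_flow`.
#' @param stride Vector sampling stride in px.
#' @param calibration px/cm (for the magnitude legend).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cumulative_flow <- function(object, stride = 16,
                                     calibration = 465, ...) {
  s <- summarize_flow(object, calibration = calibration, stride = stride)
  ggplot2::ggplot(s$vectors,
                  ggplot2::aes(.data$x, .data$y,
                               xend = .data$x + .data$dx,
                               yend = .data$y + .data$dy,
                               colour = .data$magnitude)) +
    ggplot2::geom_segment(arrow = ggplot2::arrow(
      length = ggplot2::unit(0.1, "cm"))) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_viridis_c(name = "|d| (px)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}

#' Plot raw and smoothed tip speed over time
#'
#' @param object A `tip_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tip_trajectory <- function(object, ...) {
  df <- object$data |> filter(!is.na(.data$raw_speed))
  ggplot2::ggplot(df, ggplot2::aes(.data$frame)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$raw_speed),
                       colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed_speed),
                       colour = "black", linetype = "dashed") +
    ggplot2::labs(x = "frame", y = "tip speed (cm/s)")
}
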