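#' Plot per-cell volume growth curves
#'
#' Raw volumes as points, smoothed series as lines, one colour per cell.
#'
#' @param tracks A tracks tibble with `volume_um3` (and, if available,
#'   `volume_um3_smoothed`).
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(tracks) {
  stopifnot(is.data.frame(tracks))
  p <- ggplot2::ggplot(tracks,
                       ggplot2::aes(x = .data$frame_t_min,
                                    y = .data$volume_um3,
                                    colour = factor(.data$cell_id))) +
    ggplot2::geom_point(alpha = 0.35, size = 0.8)
  if ("volume_um3_smoothed" %in% names(tracks)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$volume_um3_smoothed))
  }
  p + ggplot2::labs(x = "Time (min)", y = expression(Volume~(mu*m^3)),
                    colour = "Cell")
}

#' Box plot of growth periods by flow rate
#'
#' @param divisions A divisions tibble carrying a `flow_rate` column (e.g.
#'   from [run_shear_cohort()]).
#' @return A ggplot object.
#' @export
plot_growth_periods <- function(divisions) {
  stopifnot(is.data.frame(divisions), "flow_rate" %in% names(divisions))
  ggplot2::ggplot(divisions,
                  ggplot2::aes(x = factor(.data$flow_rate),
                               y = .data$growth_period_min / 1440)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = expression(Flow~rate~(mu*L~min^-1)),
                  y = "Growth period (d)")
}

#' @rdname fit_cubic
#' @export
autoplot.growth_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t_min)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$volume_um3),
                        alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "Time (min)", y = expression(Volume~(mu*m^3)),
                  subtitle = sprintf("R² = %.4f", object$r_squared))
}
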