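#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

.map_df <- function(m, value = "value") {
  df <- expand.grid(x = seq_len(nrow(m)), z = seq_len(ncol(m)))
  df[[value]] <- as.vector(m)
  df
}

#' Plot a velocity map
#'
#' Cross-sectional velocity image on a log color scale (velocities span
#' orders of magnitude across the class grid).
#'
#' @param object A `velocity_map` from [filter_likelihood()].
#' @param mask Optional logical matrix restricting the display to the lumen.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.velocity_map <- function(object, mask = NULL, ...) {
  v <- object$v_mm_s
  if (!is.null(mask)) v[!mask] <- NA
  df <- .map_df(v, "v_mm_s")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z,
                                   fill = .data$v_mm_s)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(trans = "log10", na.value = "grey20",
                                  name = "v (mm/s)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral location", y = "depth (pixels)",
                  title = "Network velocimetry") +
    ggplot2::theme_minimal()
}

#' Plot a Doppler velocity map
#'
#' @param object A `doppler_velocity_map`.
#' @param mask Optional lumen mask for display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.doppler_velocity_map <- function(object, mask = NULL, ...) {
  v <- object$v_mm_s
  if (!is.null(mask)) v[!mask] <- NA
  df <- .map_df(v, "v_mm_s")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z,
                                   fill = .data$v_mm_s)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(name = "v (mm/s)", na.value = "grey20") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral location", y = "depth (pixels)",
                  title = sprintf("Doppler velocimetry (alpha = %.1f deg)",
                                  object$alpha_deg)) +
    ggplot2::theme_minimal()
}

#' Plot an angle-dependence fit
#'
#' Flow-rate observations against Doppler angle with the fitted parabola.
#'
#' @param object An `angle_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.angle_fit <- function(object, ...) {
  mf <- object$fit$model
  df <- data.frame(alpha = mf$a + 90, rate = mf$rates)
  aa <- seq(min(df$alpha), max(df$alpha), length.out = 100) - 90
  pred <- data.frame(alpha = aa + 90,
                     rate = object$C0 + object$C1 * aa + object$C2 * aa^2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alpha, y = .data$rate)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = pred, color = "red") +
    ggplot2::labs(x = "Doppler angle (deg)", y = "flow rate (uL/min)",
                  subtitle = sprintf("C2/C0 = %.3g", object$ratio)) +
    ggplot2::theme_minimal()
}

#' Plot a power-law fit
#'
#' Log-log scatter of rate against diameter with the fitted line.
#'
#' @param object A `power_law_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_law_fit <- function(object, ...) {
  mf <- object$fit$model
  df <- data.frame(d = exp(mf[[2]]), q = exp(mf[[1]]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d, y = .data$q)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "red") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "vessel diameter (um)", y = "flow rate (uL/min)",
                  subtitle = sprintf("slope %.2f, R^2 %.2f",
                                     object$slope, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a likelihood curve
#'
#' Velocity likelihood for a single pixel or record on the log-spaced grid.
#'
#' @param probs Likelihood vector (length = grid size).
#' @param grid The [velocity_grid()].
#' @return A ggplot object.
#' @export
plot_likelihood <- function(probs, grid) {
  df <- data.frame(v = as.numeric(grid), p = as.numeric(probs))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$v, y = .data$p)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "velocity (mm/s)", y = "likelihood") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
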