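# 1 um^2 * mm/s = 1e-9 mL/s = 1e-6 uL/s = 6e-5 uL/min
.UL_MIN_PER_UM2_MM_S <- 6e-5

#' Cross-sectional pixel geometry
#'
#' The cross-sectional area of one B-scan pixel: lateral step size times the
#' axial pixel size scaled for the refractive index of blood.
#'
#' @param lateral_step_um Lateral A-scan spacing (um).
#' @param axial_pixel_um Axial pixel size in air (um).
#' @param n_blood Refractive index of blood (1.36).
#' @return A `pixel_geometry` list with `A_pix_um2`.
#' @export
pixel_geometry <- function(lateral_step_um, axial_pixel_um, n_blood = 1.36) {
  A <- lateral_step_um * axial_pixel_um / n_blood
  if (A <= 0) stop("pixel area must be > 0")
  structure(list(lateral_step_um = lateral_step_um,
                 axial_pixel_um = axial_pixel_um, n_blood = n_blood,
                 A_pix_um2 = A),
            class = "pixel_geometry")
}

#' @export
pixel_geometry_from_scan <- function(scan) {
  stopifnot(inherits(scan, "stepped_mscan"))
  pixel_geometry(scan$lateral_step_um, scan$axial_pixel_um,
                 if (is.null(scan$n_blood)) 1.36 else scan$n_blood)
}

.vmap_matrix <- function(v) {
  if (inherits(v, "velocity_map")) v$v_mm_s
  else if (inherits(v, "doppler_velocity_map")) v$v_mm_s
  else as.matrix(v)
}

#' Per-pixel flow rate and direct vessel rate
#'
#' `f_rate = v_flow * A_pix` per pixel; the vessel rate is the sum over the
#' lumen mask, reported in uL/min.
#'
#' @param v A velocity map (`velocity_map`, `doppler_velocity_map`, or a
#'   numeric matrix of mm/s).
#' @param geom A [pixel_geometry()].
#' @param mask A `vessel_mask` or logical matrix.
#' @return List with `rate_map_ul_min` (per-pixel) and `rate_ul_min` (sum
#'   over the mask).
#' @export
pixel_flow_rate <- function(v, geom, mask) {
  vm <- .vmap_matrix(v)
  m <- if (inherits(mask, "vessel_mask")) mask$mask else mask
  if (!any(m)) stop("empty vessel mask")
  rate_map <- vm * geom$A_pix_um2 * .UL_MIN_PER_UM2_MM_S
  list(rate_map_ul_min = rate_map, rate_ul_min = sum(rate_map[m]))
}

#' Aperture-masked, paraboloid-extrapolated vessel flow rate
#'
#' Restricts the velocity data to pixels within a radius `Ra * R` of the
#' vessel center (working in physical micrometer coordinates to respect the
#' lateral/axial pixel anisotropy), fits the axisymmetric paraboloid
#' `v(r) = vmax (1 - r^2/R^2)` that is forced to zero at the wall
#' by least squares, and integrates the fitted surface over the full lumen:
#' `rate = vmax * pi * R^2 / 2`.
#'
#' @param v A velocity map (see [pixel_flow_rate()]).
#' @param mask A `vessel_mask` (provides center and equivalent radius).
#' @param geom A [pixel_geometry()].
#' @param ra Aperture radius as a fraction of the vessel radius (0.67).
#' @param R_um,center_px Optional known vessel radius (um) and center (pixel
#'   coordinates); by default both are estimated from the mask (equivalent-
#'   area radius and centroid).
#' @return A `flow_rate_result`: `rate_ul_min`, fitted `vmax_mm_s`,
#'   `center_um`, `R_um`, `ra`, `n_pixels_fit`, `calibrated` flag.
#' @export
masked_flow_rate <- function(v, mask, geom, ra = 0.67, R_um = NULL,
                             center_px = NULL) {
  if (ra <= 0 || ra > 1) stop("ra must be in (0, 1]")
  vm <- .vmap_matrix(v)
  m <- if (inherits(mask, "vessel_mask")) mask else vessel_mask(mask)
  ax_um <- geom$axial_pixel_um / geom$n_blood
  if (is.null(R_um)) R_um <- sqrt(sum(m$mask) * geom$A_pix_um2 / pi)
  if (is.null(center_px)) center_px <- m$center
  idx <- which(m$mask, arr.ind = TRUE)
  dx <- (idx[, 1] - center_px[1]) * geom$lateral_step_um
  dz <- (idx[, 2] - center_px[2]) * ax_um
  r <- sqrt(dx^2 + dz^2)
  inside <- r <= ra * R_um
  if (sum(inside) < 6)
    stop("fewer than 6 pixels inside the fitting aperture")
  u <- 1 - (r[inside] / R_um)^2
  vv <- vm[m$mask][inside]
  vmax <- sum(vv * u) / sum(u^2)
  rate <- vmax * pi * R_um^2 / 2 * .UL_MIN_PER_UM2_MM_S
  structure(list(rate_ul_min = rate, vmax_mm_s = vmax,
                 center_um = center_px * c(geom$lateral_step_um, ax_um),
                 R_um = R_um, ra = ra, n_pixels_fit = sum(inside),
                 calibrated = FALSE),
            class = "flow_rate_result")
}

#' @export
print.flow_rate_result <- function(x, ...) {
  cat(sprintf("<flow_rate_result> %.3f uL/min (vmax %.2f mm/s, R %.1f um, Ra %.2f%s)\n",
              x$rate_ul_min, x$vmax_mm_s, x$R_um, x$ra,
              if (x$calibrated) ", calibrated" else ""))
  invisible(x)
}

#' Calibration constant relating network to reference flow estimates
#'
#' The network's reported speeds exceed the reference (Doppler) speeds by a
#' single multiplicative factor attributed to unmodeled Brownian motion,
#' multiple scattering and intravoxel velocity gradients; the empirically
#' derived value across angles is 3.18.
#'
#' @param scale Dimensionless scale (> 0).
#' @return A `calibration_constant`.
#' @export
calibration_constant <- function(scale = 3.18) {
  if (scale <= 0) stop("calibration scale must be > 0")
  structure(list(scale = scale), class = "calibration_constant")
}

#' Apply a calibration constant to a flow-rate result
#'
#' Divides the rate (and fitted peak speed) by the scale; applying a
#' calibration twice is an error.
#'
#' @param r A `flow_rate_result`.
#' @param cal A [calibration_constant()].
#' @return The calibrated `flow_rate_result`.
#' @export
apply_calibration <- function(r, cal = calibration_constant()) {
  stopifnot(inherits(r, "flow_rate_result"),
            inherits(cal, "calibration_constant"))
  if (r$calibrated) stop("flow-rate result is already calibrated")
  r$rate_ul_min <- r$rate_ul_min / cal$scale
  r$vmax_mm_s <- r$vmax_mm_s / cal$scale
  r$calibrated <- TRUE
  r
}

#' Estimate the calibration scale from paired rates
#'
#' Zero-intercept least-squares slope of network rates against reference
#' rates. Reference measurements at Doppler angles inside the rejection
#' window must be excluded before calling.
#'
#' @param nn_rates,ref_rates Paired positive rates.
#' @return A [calibration_constant()] with the fitted scale.
#' @export
calibrate_scale <- function(nn_rates, ref_rates) {
  if (length(nn_rates) != length(ref_rates) || !length(nn_rates))
    stop("need paired, non-empty rate vectors")
  if (any(nn_rates <= 0) || any(ref_rates <= 0))
    stop("rates must be positive")
  calibration_constant(sum(nn_rates * ref_rates) / sum(ref_rates^2))
}

#' Quadratic fit of flow rate against Doppler angle
#'
#' Fits `y = C0 + C1 (alpha - 90) + C2 (alpha - 90)^2` by least squares. The
#' ratio `C2/C0` quantifies the residual angle dependence of the rate
#' estimate and is the figure of merit for choosing the aperture.
#'
#' @param alphas_deg Doppler angles (degrees).
#' @param rates Flow rates (uL/min).
#' @return An `angle_fit` with `C0`, `C1`, `C2`, `ratio` (= C2/C0) and the
#'   underlying `lm` fit.
#' @export
angle_dependence_fit <- function(alphas_deg, rates) {
  if (length(alphas_deg) != length(rates) || length(rates) < 3)
    stop("need at least 3 paired (angle, rate) observations")
  a <- alphas_deg - 90
  fit <- stats::lm(rates ~ a + I(a^2))
  cf <- stats::coef(fit)
  structure(list(C0 = unname(cf[1]), C1 = unname(cf[2]), C2 = unname(cf[3]),
                 ratio = unname(cf[3] / cf[1]), fit = fit),
            class = "angle_fit")
}

#' Coefficient of variation of repeated measurements
#'
#' @param x Numeric vector of repeated rates (non-empty).
#' @return `sd(x) / mean(x)`.
#' @export
coefficient_of_variation <- function(x) {
  if (!length(x)) stop("empty measurement vector")
  if (length(x) == 1L) return(0)
  stats::sd(x) / mean(x)
}

#' Flow conservation across a vessel bifurcation
#'
#' Compares the inflow of the parent segment with the summed outflow of the
#' daughters: `imbalance = |A - (B + C)| / A`.
#'
#' @param inflow Repeated inflow rates (numeric vector or
#'   `flow_rate_result`).
#' @param outflows List of repeated outflow rates (one element per daughter).
#' @return A `bifurcation_balance` tibble-backed report: per-segment mean and
#'   sd, total outflow, and the fractional `imbalance`.
#' @export
bifurcation_balance <- function(inflow, outflows) {
  as_rates <- function(x)
    if (inherits(x, "flow_rate_result")) x$rate_ul_min else as.numeric(x)
  a <- as_rates(inflow)
  outs <- lapply(outflows, as_rates)
  if (mean(a) == 0) stop("zero inflow")
  seg <- tibble::tibble(
    segment = c("A", paste0("out", seq_along(outs))),
    mean_ul_min = c(mean(a), vapply(outs, mean, numeric(1))),
    sd_ul_min = c(stats::sd(a), vapply(outs, stats::sd, numeric(1))))
  total_out <- sum(vapply(outs, mean, numeric(1)))
  structure(list(segments = seg, inflow_ul_min = mean(a),
                 outflow_ul_min = total_out,
                 imbalance = abs(mean(a) - total_out) / mean(a)),
            class = "bifurcation_balance")
}

#' @export
print.bifurcation_balance <- function(x, ...) {
  cat(sprintf("<bifurcation_balance> inflow %.3f, outflow %.3f uL/min (imbalance %.1f%%)\n",
              x$inflow_ul_min, x$outflow_ul_min, 100 * x$imbalance))
  print(x$segments)
  invisible(x)
}

#' Power-law fit of flow rate against vessel diameter
#'
#' Ordinary least squares on `log(Q) ~ log(D)` (arteries and veins pooled);
#' the slope is the power-law exponent.
#'
#' @param diameters_um Vessel diameters (um).
#' @param rates_ul_min Flow rates (uL/min).
#' @return A `power_law_fit` with `slope`, `intercept`, `r_squared` and the
#'   underlying `lm` fit.
#' @export
power_law_fit <- function(diameters_um, rates_ul_min) {
  if (length(diameters_um) != length(rates_ul_min) ||
      length(diameters_um) < 2)
    stop("need at least 2 paired (diameter, rate) observations")
  if (any(diameters_um <= 0) || any(rates_ul_min <= 0))
    stop("diameters and rates must be positive for the log-log fit")
  fit <- stats::lm(log(rates_ul_min) ~ log(diameters_um))
  cf <- stats::coef(fit)
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 r_squared = suppressWarnings(summary(fit)$r.squared), fit = fit),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> Q ~ D^%.3f (R^2 = %.3f)\n",
              x$slope, x$r_squared))
  invisible(x)
}

#' @export
print.angle_fit <- function(x, ...) {
  cat(sprintf("<angle_fit> C0 %.4g, C1 %.4g, C2 %.4g, C2/C0 %.4g\n",
              x$C0, x$C1, x$C2, x$ratio))
  invisible(x)
}
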