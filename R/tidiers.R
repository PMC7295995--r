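#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an angle-dependence fit
#'
#' @param x An `angle_fit` from [angle_dependence_fit()].
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`C0`, `C1`, `C2`).
#' @export
tidy.angle_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(term = c("C0", "C1", "C2"),
                 estimate = c(x$C0, x$C1, x$C2),
                 std.error = unname(s[, "Std. Error"]),
                 statistic = unname(s[, "t value"]),
                 p.value = unname(s[, "Pr(>|t|)"]))
}

#' @rdname tidy.angle_fit
#' @export
glance.angle_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))
  tibble::tibble(ratio = x$ratio, r.squared = s$r.squared,
                 sigma = s$sigma, nobs = length(x$fit$residuals))
}

#' Tidy a power-law fit
#'
#' @param x A `power_law_fit` from [power_law_fit()].
#' @param ... Unused.
#' @return A tibble with the intercept and exponent rows.
#' @export
tidy.power_law_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(term = c("log_intercept", "exponent"),
                 estimate = c(x$intercept, x$slope),
                 std.error = unname(s[, "Std. Error"]),
                 statistic = unname(s[, "t value"]),
                 p.value = unname(s[, "Pr(>|t|)"]))
}

#' @rdname tidy.power_law_fit
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble::tibble(exponent = x$slope, r.squared = x$r_squared,
                 nobs = length(x$fit$residuals))
}

#' Tidy a flow-rate result
#'
#' @param x A `flow_rate_result`.
#' @param ... Unused.
#' @return One-row tibble with the rate and fit parameters.
#' @export
tidy.flow_rate_result <- function(x, ...) {
  tibble::tibble(rate_ul_min = x$rate_ul_min, vmax_mm_s = x$vmax_mm_s,
                 R_um = x$R_um, ra = x$ra, n_pixels_fit = x$n_pixels_fit,
                 calibrated = x$calibrated)
}

#' Tidy a bifurcation balance report
#'
#' @param x A `bifurcation_balance`.
#' @param ... Unused.
#' @return The per-segment tibble.
#' @export
tidy.bifurcation_balance <- function(x, ...) x$segments

#' @rdname tidy.bifurcation_balance
#' @export
glance.bifurcation_balance <- function(x, ...) {
  tibble::tibble(inflow_ul_min = x$inflow_ul_min,
                 outflow_ul_min = x$outflow_ul_min,
                 imbalance = x$imbalance)
}
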