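#' Logarithmically spaced velocity class grid
#'
#' The classifier discretizes flow speed into `n` classes placed in geometric
#' progression between `vmin` and `vmax`. The full-scale configuration uses 64
#' classes between 0.001 mm/s and 2000 mm/s; scaled configurations cover a
#' narrower range with fewer classes.
#'
#' @param n Number of velocity classes (>= 2).
#' @param vmin,vmax Lowest and highest class velocity in mm/s (0 < vmin < vmax).
#' @return An object of class `velocity_grid`: a numeric vector of class
#'   velocities (mm/s) with `n` entries, strictly increasing, constant ratio
#'   between consecutive entries.
#' @examples
#' g <- velocity_grid(64, 0.001, 2000)
#' head(g)
#' @export
velocity_grid <- function(n = 64L, vmin = 0.001, vmax = 2000) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("invalid velocity grid: n must be a single count >= 2")
  if (!is.numeric(vmin) || !is.numeric(vmax) || vmin <= 0 || vmax <= 0 ||
      vmin >= vmax)
    stop("invalid velocity grid: need 0 < vmin < vmax")
  v <- exp(seq(log(vmin), log(vmax), length.out = as.integer(n)))
  # pin the endpoints exactly
  v[1] <- vmin
  v[length(v)] <- vmax
  structure(v, class = "velocity_grid", vmin = vmin, vmax = vmax)
}

#' @export
print.velocity_grid <- function(x, ...) {
  cat(sprintf("<velocity_grid> %d classes, %.4g .. %.4g mm/s (ratio %.4f)\n",
              length(x), x[1], x[length(x)], x[2] / x[1]))
  invisible(x)
}

#' Map velocities to nearest grid class
#'
#' Nearest class in log-velocity, matching the geometric spacing of the grid.
#'
#' @param grid A [velocity_grid()].
#' @param v_mm_s Velocities to classify (mm/s, > 0).
#' @return Integer class indices (1-based).
#' @export
nearest_class <- function(grid, v_mm_s) {
  stopifnot(inherits(grid, "velocity_grid"))
  lv <- log(as.numeric(grid))
  vapply(v_mm_s, function(v) which.min(abs(lv - log(v))), integer(1))
}
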