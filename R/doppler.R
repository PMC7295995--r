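#' Doppler analysis configuration
#'
#' Phase-difference velocimetry settings: the set of A-scan time delays, the
#' optical constants entering the velocity formula
#' `v = (dphi * lambda0) / (4 pi n tau cos(alpha))`, the SNR threshold for
#' static reference pixels used in bulk-motion correction, and the Doppler
#' angle window inside which measurements are rejected (cos(alpha) ~ 0).
#'
#' @param delays Phase-difference time delays in A-scan counts (default 1:40).
#' @param lambda0_nm Center wavelength (1040).
#' @param n_refr Refractive index of blood (1.36).
#' @param tau_s A-scan period in seconds (1e-5).
#' @param static_snr_threshold_db Minimum SNR for static reference pixels (3).
#' @param angle_reject_deg Rejected Doppler-angle window, degrees (c(88, 92)).
#' @param discontinuity_threshold Maximum tolerated fraction of discontinuous
#'   pixels before an unwrapped image is dropped (0.01).
#' @return A `doppler_config` list.
#' @export
doppler_config <- function(delays = 1:40, lambda0_nm = 1040, n_refr = 1.36,
                           tau_s = 1e-5, static_snr_threshold_db = 3,
                           angle_reject_deg = c(88, 92),
                           discontinuity_threshold = 0.01) {
  if (any(delays < 1)) stop("delays must be positive A-scan counts")
  structure(list(delays = as.integer(delays), lambda0_nm = lambda0_nm,
                 n_refr = n_refr, tau_s = tau_s,
                 static_snr_threshold_db = static_snr_threshold_db,
                 angle_reject_deg = angle_reject_deg,
                 discontinuity_threshold = discontinuity_threshold),
            class = "doppler_config")
}

#' Multi-delay phase-difference stack of a stepped M-scan
#'
#' For each delay `d` and each start sample `t`, the phase-difference image is
#' `arg(a(t + d) * conj(a(t)))` per pixel, giving `n_samples - d` images per
#' delay: 127 at delay 1 down to 88 at delay 40 for a 128-sample series, 4300
#' images over delays 1 to 40. The complex lag products are retained so that
#' downstream averaging can be circular.
#'
#' @param scan A `stepped_mscan` with complex data (see [synth_stepped_mscan()]
#'   or [read_scan()]).
#' @param cfg A [doppler_config()]; delays must be `< n_samples`.
#' @return A `phase_diff_stack`: list with `lag` (list over delays of complex
#'   arrays `[nx x nz x (n_samples - d)]`), `delays`, `n_images` per delay,
#'   and scan geometry.
#' @export
phase_difference_stack <- function(scan, cfg = doppler_config()) {
  stopifnot(inherits(scan, "stepped_mscan"))
  if (!is.complex(scan$data))
    stop("Doppler analysis requires complex-valued scan data")
  nt <- dim(scan$data)[3]
  if (any(cfg$delays >= nt))
    stop("delays must be smaller than the number of samples per series")
  lag <- lapply(cfg$delays, function(d) {
    a0 <- scan$data[, , seq_len(nt - d), drop = FALSE]
    a1 <- scan$data[, , seq_len(nt - d) + d, drop = FALSE]
    a1 * Conj(a0)
  })
  structure(list(lag = lag, delays = cfg$delays,
                 n_images = nt - cfg$delays,
                 nx = dim(scan$data)[1], nz = dim(scan$data)[2],
                 excluded = integer(0)),
            class = "phase_diff_stack")
}

#' Bulk-motion correction of a phase-difference stack
#'
#' Global sample motion adds a common phase offset to every pixel of an
#' A-scan pair. For each phase-difference image and each lateral location
#' (A-scan), the circular-mean phase over static pixels with significant SNR
#' (> threshold) is subtracted. Locations without any usable static pixel are
#' flagged and left uncorrected.
#'
#' @param stack A [phase_difference_stack()].
#' @param static_mask Logical `[nx x nz]`: TRUE for static (non-flow) pixels.
#' @param snr_map An `snr_map` (see [estimate_snr_map()]), used to keep only
#'   static pixels above the SNR threshold.
#' @param cfg A [doppler_config()].
#' @return The corrected stack; attribute `uncorrected_columns` counts
#'   locations that had no static reference.
#' @export
bulk_motion_correct <- function(stack, static_mask, snr_map = NULL,
                                cfg = doppler_config()) {
  stopifnot(inherits(stack, "phase_diff_stack"))
  ref <- static_mask
  if (!is.null(snr_map)) ref <- ref & (snr_map$snr_db > cfg$static_snr_threshold_db)
  if (!any(ref)) stop("no static reference pixels available")
  ncol_bad <- 0L
  has_ref <- rowSums(ref) > 0
  ncol_bad <- sum(!has_ref)
  for (i in seq_along(stack$lag)) {
    L <- stack$lag[[i]]
    nimg <- dim(L)[3]
    for (t in seq_len(nimg)) {
      img <- L[, , t]
      # per-location circular mean of static phases
      refsum <- rowSums(img * ref)
      off <- refsum / Mod(refsum)
      off[!has_ref | !is.finite(Re(off))] <- 1 + 0i
      L[, , t] <- img * Conj(off)
    }
    stack$lag[[i]] <- L
  }
  attr(stack, "uncorrected_columns") <- ncol_bad
  stack
}

#' Per-delay circular averaging of a phase-difference stack
#'
#' Averages the complex lag products over all start times of each delay
#' (Kasai-style circular mean) and returns one wrapped phase image per delay.
#'
#' @param stack A [phase_difference_stack()].
#' @return List with `phase` (list over delays of `[nx x nz]` wrapped phase
#'   images, radians in (-pi, pi]), `magnitude` (mean lag-product magnitude,
#'   a phase-quality surrogate), and `delays`.
#' @export
average_per_delay <- function(stack) {
  stopifnot(inherits(stack, "phase_diff_stack"))
  phase <- vector("list", length(stack$delays))
  magn <- vector("list", length(stack$delays))
  for (i in seq_along(stack$delays)) {
    s <- rowSums(stack$lag[[i]], dims = 2)
    n <- dim(stack$lag[[i]])[3]
    phase[[i]] <- Arg(s)
    magn[[i]] <- Mod(s) / n
  }
  list(phase = phase, magnitude = magn, delays = stack$delays)
}

#' Quality-guided two-dimensional phase unwrapping
#'
#' Flood-fill unwrapping: starting from the highest-quality pixel, pixels are
#' absorbed in order of decreasing quality; each new pixel's phase is adjusted
#' by the multiple of 2 pi that brings it within pi of its already-unwrapped
#' neighbor. Quality defaults to the (negated) local phase-gradient variance.
#'
#' @param img Wrapped phase image `[nx x nz]`, radians in (-pi, pi].
#' @param quality Optional quality map (higher = better); e.g. the lag-product
#'   magnitude from [average_per_delay()].
#' @return Unwrapped phase image (same dimensions). The global 2 pi offset is
#'   unresolved and must be anchored by the caller.
#' @export
unwrap_phase_2d <- function(img, quality = NULL) {
  nx <- nrow(img); nz <- ncol(img)
  if (is.null(quality)) {
    # negative local wrapped-gradient energy as quality
    gx <- matrix(0, nx, nz); gz <- matrix(0, nx, nz)
    wrap <- function(x) Arg(exp(1i * x))
    gx[-nx, ] <- wrap(img[-1, , drop = FALSE] - img[-nx, , drop = FALSE])
    gz[, -nz] <- wrap(img[, -1, drop = FALSE] - img[, -nz, drop = FALSE])
    quality <- -(gx^2 + gz^2)
  }
  .unwrap2d_cpp(img, quality)
}

#' Residual discontinuity fraction of an unwrapped phase image
#'
#' Fraction of 4-neighbor pixel pairs whose phase difference still exceeds pi
#' after unwrapping; used to detect images corrupted by noise, phase
#' decorrelation or unwrapping errors.
#'
#' @param img Unwrapped phase image.
#' @param valid Optional logical mask of pixels whose phase is meaningful
#'   (e.g. SNR above the static threshold); only pairs with both pixels
#'   valid are counted, so the signal-free noise floor does not condemn an
#'   otherwise clean image.
#' @return Fraction in `[0, 1]`.
#' @export
discontinuity_fraction <- function(img, valid = NULL) {
  dx <- abs(img[-1, , drop = FALSE] - img[-nrow(img), , drop = FALSE])
  dz <- abs(img[, -1, drop = FALSE] - img[, -ncol(img), drop = FALSE])
  if (is.null(valid)) return(mean(c(dx, dz) > pi))
  vx <- valid[-1, , drop = FALSE] & valid[-nrow(img), , drop = FALSE]
  vz <- valid[, -1, drop = FALSE] & valid[, -ncol(img), drop = FALSE]
  n <- sum(vx) + sum(vz)
  if (n == 0) return(1)
  (sum(dx[vx] > pi) + sum(dz[vz] > pi)) / n
}

#' Reject corrupted per-delay phase images
#'
#' Unwrapped per-delay images whose residual discontinuity fraction exceeds
#' the configured threshold are dropped: discontinuities remaining after
#' unwrapping indicate noise, phase decorrelation, or unwrapping failure.
#'
#' @param imgs List of unwrapped phase images (one per delay).
#' @param cfg A [doppler_config()].
#' @param valid Optional validity mask forwarded to
#'   [discontinuity_fraction()].
#' @return List with `imgs` (survivors), `keep` (logical), `excluded` (count).
#'   All images corrupted is an error.
#' @export
reject_corrupted <- function(imgs, cfg = doppler_config(), valid = NULL) {
  frac <- vapply(imgs, discontinuity_fraction, numeric(1), valid = valid)
  keep <- frac <= cfg$discontinuity_threshold
  if (!any(keep)) stop("all delay images rejected as corrupted")
  list(imgs = imgs[keep], keep = keep, excluded = sum(!keep), fraction = frac)
}

#' Scale per-delay phase images to one A-scan delay and average
#'
#' Each surviving per-delay average image holds the same velocity information
#' scaled by its delay; dividing by the delay and averaging yields the final
#' phase difference per single A-scan period. Exact for constant-velocity
#' noise-free input, for any subset of delays.
#'
#' @param imgs List of unwrapped per-delay phase images.
#' @param delays Integer delays (A-scan counts) matching `imgs`.
#' @return Averaged phase-difference image at a one-A-scan delay.
#' @export
average_and_scale <- function(imgs, delays) {
  if (length(imgs) != length(delays)) stop("imgs and delays lengths differ")
  if (!length(imgs)) stop("no images to average")
  scaled <- Map(function(im, d) im / d, imgs, delays)
  Reduce(`+`, scaled) / length(scaled)
}

#' Full Doppler velocimetry pipeline for one B-scan
#'
#' Runs the reference phase analysis end to end: multi-delay phase
#' differences, bulk-motion correction against static pixels, per-delay
#' circular averaging, 2D phase unwrapping anchored to the static background,
#' rejection of corrupted delay images (residual discontinuity fraction above
#' the configured threshold), scaling of each surviving delay image to a
#' one-A-scan delay, averaging across delays, and conversion to velocity.
#'
#' @param scan A `stepped_mscan` with complex data.
#' @param alpha_deg Doppler angle in degrees; must lie outside the rejection
#'   window.
#' @param static_mask Logical `[nx x nz]` marking static pixels (for
#'   bulk-motion reference and phase anchoring). If `NULL`, bulk correction
#'   and anchoring are skipped.
#' @param cfg A [doppler_config()].
#' @param snr_map Optional `snr_map` to filter static reference pixels.
#' @return A `doppler_velocity_map`: list with `v_mm_s` `[nx x nz]` (total
#'   flow speed), `dphi` (average phase difference per A-scan), `alpha_deg`,
#'   `excluded` (delays dropped), and `cfg`.
#' @export
doppler_velocimetry <- function(scan, alpha_deg, static_mask = NULL,
                                cfg = doppler_config(), snr_map = NULL) {
  stack <- phase_difference_stack(scan, cfg)
  if (!is.null(static_mask))
    stack <- bulk_motion_correct(stack, static_mask, snr_map, cfg)
  avg <- average_per_delay(stack)
  imgs <- vector("list", length(cfg$delays))
  for (i in seq_along(cfg$delays)) {
    u <- unwrap_phase_2d(avg$phase[[i]], quality = avg$magnitude[[i]])
    if (!is.null(static_mask)) {
      # anchor: static background is truly zero-phase; remove the global
      # 2 pi ambiguity and any residual offset estimated on static pixels
      off <- stats::median(u[static_mask])
      u <- u - 2 * pi * round(off / (2 * pi))
    }
    imgs[[i]] <- u
  }
  valid <- if (!is.null(snr_map))
    snr_map$snr_db > cfg$static_snr_threshold_db else NULL
  surv <- reject_corrupted(imgs, cfg, valid = valid)
  dphi <- average_and_scale(surv$imgs, cfg$delays[surv$keep])
  structure(list(v_mm_s = doppler_velocity(dphi, alpha_deg, cfg)$v_mm_s,
                 dphi = dphi, alpha_deg = alpha_deg,
                 excluded = cfg$delays[!surv$keep], cfg = cfg),
            class = "doppler_velocity_map")
}

#' Convert an averaged phase-difference image to velocity
#'
#' `v = (dphi * lambda0) / (4 pi n tau cos(alpha))`, with `dphi` the phase
#' difference at a one-A-scan delay. Angles inside the rejection window
#' (cos(alpha) ~ 0) are an error: the axial-to-total conversion is unstable
#' there.
#'
#' @param dphi Phase-difference image (radians per A-scan period), or scalar.
#' @param alpha_deg Doppler angle in degrees.
#' @param cfg A [doppler_config()].
#' @return A `doppler_velocity_map` with `v_mm_s` (total flow speed, mm/s;
#'   sign follows the phase sign), `alpha_deg` and `cfg`.
#' @export
doppler_velocity <- function(dphi, alpha_deg, cfg = doppler_config()) {
  w <- cfg$angle_reject_deg
  if (alpha_deg >= w[1] && alpha_deg <= w[2])
    stop(sprintf("Doppler angle %.1f deg lies in the rejected window [%g, %g]",
                 alpha_deg, w[1], w[2]))
  lambda0_mm <- cfg$lambda0_nm * 1e-6
  # dphi [rad], lambda [mm], tau [s] -> v [mm/s]
  v <- dphi * lambda0_mm /
    (4 * pi * cfg$n_refr * cfg$tau_s * cos(alpha_deg * pi / 180))
  structure(list(v_mm_s = v, alpha_deg = alpha_deg, cfg = cfg),
            class = "doppler_velocity_map")
}

#' Doppler angle from the vessel depth shift between two imaging locations
#'
#' Two B-scans of the same vessel separated laterally by `dx` see the vessel
#' at depths `z1` and `z2`. The flow axis then makes an angle
#' `alpha = 90 + atan((z2 - z1) / dx)` degrees with the beam: a vessel that
#' descends with increasing `x` (positive `z2 - z1`, depth positive downward)
#' has alpha above 90 degrees.
#'
#' @param z1_um,z2_um Optical-path-corrected vessel depths (micrometers) at
#'   the two locations (divide raw optical depth by the tissue group index
#'   before calling).
#' @param dx_um Lateral spacing of the two locations (200 in the scan
#'   protocol).
#' @return Doppler angle in degrees.
#' @export
doppler_angle_from_depth_shift <- function(z1_um, z2_um, dx_um) {
  if (dx_um <= 0) stop("dx_um must be > 0")
  90 + atan((z2_um - z1_um) / dx_um) * 180 / pi
}
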