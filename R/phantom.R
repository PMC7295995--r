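#' Synthetic flow-phantom specification
#'
#' Describes a tube (or vessel) cross-section embedded in a static scattering
#' slab, imaged with the stepped M-scan protocol: a 125-um inner-diameter tube
#' carrying laminar (Poiseuille) flow at a set pump rate, at a known Doppler
#' angle, with shot noise at a prescribed SNR. The generated B-scan has the
#' lumen's speckle decorrelation driven by the local total speed and a
#' deterministic axial Doppler phase ramp proportional to `v cos(alpha)`.
#'
#' @param tube_diameter_um Inner diameter of the tube (125).
#' @param doppler_angle_deg Angle between flow axis and beam (90 = transverse).
#' @param pump_rate_ul_min Volumetric flow rate in uL/min.
#' @param snr_db Measurement SNR in dB (`Inf` = noise-free).
#' @param n_locations Lateral A-scan locations (100).
#' @param n_depth Depth pixels of the cropped B-scan.
#' @param lateral_step_um Lateral step between A-scan locations (3).
#' @param axial_pixel_um Axial pixel size in air (4.2); divided by the blood
#'   refractive index for in-tissue geometry.
#' @param n_blood Refractive index of blood (1.36).
#' @param center Tube center as `c(x_pixel, z_pixel)`; default mid-frame.
#' @param static_intensity Mean intensity of the static slab relative to the
#'   lumen's ensemble-mean intensity (1).
#' @param noise_depth_frac Fraction of the deepest image rows left free of
#'   sample signal (0.1): emulates the depths below the sample that carry
#'   only the detection noise floor and anchor SNR estimation.
#' @param bulk_jitter_rad Per-A-scan global phase jitter standard deviation
#'   (models residual bulk motion; 0 disables).
#' @param pulsatility Optional `list(amplitude =, period_s =)` raised-cosine
#'   modulation of the pump rate across repeated B-scans.
#' @param beam,timing,scatterers Forward-model configuration shared with the
#'   signal simulator.
#' @param seed Integer seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(tube_diameter_um = 125, doppler_angle_deg = 90,
                         pump_rate_ul_min = 50, snr_db = 25,
                         n_locations = 100L, n_depth = 60L,
                         lateral_step_um = 3, axial_pixel_um = 4.2,
                         n_blood = 1.36, center = NULL,
                         static_intensity = 1, noise_depth_frac = 0.1,
                         bulk_jitter_rad = 0,
                         pulsatility = NULL,
                         beam = beam_model(), timing = scan_timing(),
                         scatterers = scatterer_config(), seed = 1L) {
  if (tube_diameter_um <= 0) stop("tube diameter must be > 0")
  if (pump_rate_ul_min < 0) stop("pump rate must be >= 0")
  if (is.null(center)) center <- c((n_locations + 1) / 2, (n_depth + 1) / 2)
  structure(list(tube_diameter_um = tube_diameter_um,
                 doppler_angle_deg = doppler_angle_deg,
                 pump_rate_ul_min = pump_rate_ul_min, snr_db = snr_db,
                 n_locations = as.integer(n_locations),
                 n_depth = as.integer(n_depth),
                 lateral_step_um = lateral_step_um,
                 axial_pixel_um = axial_pixel_um, n_blood = n_blood,
                 center = center, static_intensity = static_intensity,
                 noise_depth_frac = noise_depth_frac,
                 bulk_jitter_rad = bulk_jitter_rad,
                 pulsatility = pulsatility,
                 beam = beam, timing = timing, scatterers = scatterers,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Peak speed of a Poiseuille profile from the volumetric rate
#'
#' For laminar tube flow the profile is `v(r) = vmax (1 - r^2/R^2)` and the
#' peak speed is twice the mean: `vmax = 2 Q / (pi R^2)`.
#'
#' @param rate_ul_min Volumetric rate (uL/min).
#' @param diameter_um Tube diameter (um).
#' @return Peak speed in mm/s.
#' @export
poiseuille_peak_speed <- function(rate_ul_min, diameter_um) {
  q_um3_s <- rate_ul_min / 60 * 1e9      # 1 uL = 1e9 um^3
  r_um <- diameter_um / 2
  2 * q_um3_s / (pi * r_um^2) / 1e3      # um/s -> mm/s
}

# physical pixel coordinates (um) relative to tube center; depth uses the
# optical-path-corrected (in-tissue) axial pixel size
.phantom_geometry <- function(spec) {
  ax_um <- spec$axial_pixel_um / spec$n_blood
  x_um <- (seq_len(spec$n_locations) - spec$center[1]) * spec$lateral_step_um
  z_um <- (seq_len(spec$n_depth) - spec$center[2]) * ax_um
  r <- sqrt(outer(x_um^2, z_um^2, "+"))
  list(r_um = r, x_um = x_um, z_um = z_um, ax_um = ax_um)
}

#' Ground-truth maps of a phantom specification
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_truth` list: `v_mm_s` (total-speed map), `dphi_rad`
#'   (axial Doppler phase ramp per A-scan), `mask` (lumen), `rate_ul_min`
#'   (the pump rate), `vmax_mm_s`, and geometry.
#' @export
phantom_truth <- function(spec) {
  geo <- .phantom_geometry(spec)
  R <- spec$tube_diameter_um / 2
  mask <- geo$r_um <= R
  vmax <- poiseuille_peak_speed(spec$pump_rate_ul_min, spec$tube_diameter_um)
  v <- ifelse(mask, vmax * (1 - (geo$r_um / R)^2), 0)
  dphi <- 4 * pi * spec$n_blood * (v * 1e3) *
    cos(spec$doppler_angle_deg * pi / 180) * spec$timing$ascan_period_s /
    (1040 * 1e-3)                        # lambda0 in um; v in um/s
  structure(list(v_mm_s = v, dphi_rad = dphi, mask = mask,
                 rate_ul_min = spec$pump_rate_ul_min, vmax_mm_s = vmax,
                 R_um = R, geometry = geo),
            class = "phantom_truth")
}

#' Synthesize a stepped M-scan B-scan of the flow phantom
#'
#' Static pixels carry a temporally constant speckle field; lumen pixels carry
#' forward-model speckle series at the local Poiseuille speed multiplied by
#' the deterministic axial Doppler phase ramp
#' `exp(i t dphi(r))`, `dphi(r) = 4 pi n v(r) cos(alpha) tau / lambda0`.
#' Shot noise is added at the specified SNR. Optional per-A-scan global phase
#' jitter emulates residual bulk motion.
#'
#' @param spec A [phantom_spec()].
#' @return List with `scan` (a `stepped_mscan`: complex `data`
#'   `[nx x nz x nt]` plus geometry/timing metadata) and `truth`
#'   (a [phantom_truth()]).
#' @examples
#' ph <- synth_stepped_mscan(phantom_spec(pump_rate_ul_min = 10,
#'                                        n_locations = 20L, n_depth = 16L,
#'                                        tube_diameter_um = 30))
#' dim(ph$scan$data)
#' @export
synth_stepped_mscan <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  truth <- phantom_truth(spec)
  nx <- spec$n_locations; nz <- spec$n_depth
  nt <- spec$timing$n_samples
  ibar <- ensemble_mean_intensity(spec$beam, spec$scatterers)
  data <- array(0 + 0i, dim = c(nx, nz, nt))
  # static slab: one complex circular-Gaussian speckle draw per pixel,
  # constant over time, scaled to the requested mean intensity
  amp <- sqrt(spec$static_intensity * ibar / 2)
  static_field <- complex(real = stats::rnorm(nx * nz, 0, amp),
                          imaginary = stats::rnorm(nx * nz, 0, amp))
  dim(static_field) <- c(nx, nz)
  if (spec$noise_depth_frac > 0) {
    # deepest rows carry no sample signal, only the noise floor
    z0 <- nz - ceiling(nz * spec$noise_depth_frac) + 1L
    static_field[, z0:nz] <- 0 + 0i
  }
  data[] <- rep(static_field, nt)
  # lumen: forward-model speckle at the local speed, ramped by the axial phase
  lum <- which(truth$mask, arr.ind = TRUE)
  t_idx <- 0:(nt - 1)
  for (k in seq_len(nrow(lum))) {
    i <- lum[k, 1]; j <- lum[k, 2]
    s <- simulate_field(truth$v_mm_s[i, j], n = 1, beam = spec$beam,
                        timing = spec$timing, scatterers = spec$scatterers)
    data[i, j, ] <- s$field[1, ] * exp(1i * truth$dphi_rad[i, j] * t_idx)
  }
  if (spec$bulk_jitter_rad > 0) {
    # global phase per A-scan: each (location, sample) pair is one A-scan
    jit <- matrix(stats::rnorm(nx * nt, 0, spec$bulk_jitter_rad), nx, nt)
    for (tt in seq_len(nt))
      data[, , tt] <- data[, , tt] * exp(1i * jit[, tt])
  }
  if (is.finite(spec$snr_db)) {
    sigma2 <- ibar / 10^(spec$snr_db / 10)
    nn <- length(data)
    data <- data + complex(real = stats::rnorm(nn, 0, sqrt(sigma2 / 2)),
                           imaginary = stats::rnorm(nn, 0, sqrt(sigma2 / 2)))
  }
  scan <- structure(list(data = data, timing = spec$timing,
                         lateral_step_um = spec$lateral_step_um,
                         axial_pixel_um = spec$axial_pixel_um,
                         wavelength_nm = 1040,
                         n_blood = spec$n_blood,
                         doppler_angle_deg = spec$doppler_angle_deg),
                    class = "stepped_mscan")
  list(scan = scan, truth = truth)
}

#' @export
print.stepped_mscan <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<stepped_mscan> %d locations x %d depth x %d samples (%.0f um wide)\n",
              d[1], d[2], d[3], d[1] * x$lateral_step_um))
  invisible(x)
}

#' Repeated B-scans with optional pulsatile flow
#'
#' Generates `n_repeats` successive stepped M-scan B-scans of the same
#' phantom. If the spec carries a `pulsatility` entry
#' (`list(amplitude =, period_s =)`), the pump rate of repeat `r` is
#' modulated by a raised cosine evaluated at that repeat's acquisition
#' start time: `Q_r = Q (1 + amplitude * cos(2 pi t_r / period_s))`.
#' Speckle is re-drawn independently per repeat.
#'
#' @param spec A [phantom_spec()].
#' @param n_repeats Number of successive B-scans (10 in the standard
#'   protocol).
#' @return List of `synth_stepped_mscan()` results, one per repeat.
#' @export
synth_repeated_mscans <- function(spec, n_repeats = 10L) {
  stopifnot(inherits(spec, "phantom_spec"))
  bscan_s <- spec$n_locations * spec$timing$n_samples *
    spec$timing$ascan_period_s
  lapply(seq_len(n_repeats), function(r) {
    spr <- spec
    if (!is.null(spec$pulsatility)) {
      t_r <- (r - 1) * bscan_s
      spr$pump_rate_ul_min <- spec$pump_rate_ul_min *
        (1 + spec$pulsatility$amplitude *
           cos(2 * pi * t_r / spec$pulsatility$period_s))
    }
    spr$seed <- spec$seed + 7717L * r
    synth_stepped_mscan(spr)
  })
}

#' Synthetic velocity map with injected lumen-edge artifacts
#'
#' Reproduces, on ground-truth velocity maps, the apparent-velocity artifacts
#' observed at the lumen boundary whose magnitude grows with the deviation of
#' the Doppler angle from perpendicular: a one-pixel rim at the lumen wall is
#' elevated by `rim_gain_per_deg * |alpha - 90| * vmax`. Optional
#' multiplicative pixel noise supports variability studies.
#'
#' @param spec A [phantom_spec()].
#' @param rim_gain_per_deg Rim elevation per degree of angle deviation (0.1).
#' @param noise_sd Multiplicative lognormal-ish pixel noise sd (0 = none).
#' @return List with `v_mm_s` (artifact-bearing map), `mask`, `truth`.
#' @export
synth_edge_artifact_map <- function(spec, rim_gain_per_deg = 0.1,
                                    noise_sd = 0) {
  truth <- phantom_truth(spec)
  v <- truth$v_mm_s
  m <- truth$mask
  # rim = lumen pixels with at least one non-lumen 4-neighbor
  nx <- nrow(m); nz <- ncol(m)
  pad <- function(sh_i, sh_j) {
    out <- matrix(FALSE, nx, nz)
    si <- seq_len(nx) + sh_i; sj <- seq_len(nz) + sh_j
    ok_i <- si >= 1 & si <= nx; ok_j <- sj >= 1 & sj <= nz
    out[ok_i, ok_j] <- m[si[ok_i], sj[ok_j]]
    out
  }
  interior <- m & pad(1, 0) & pad(-1, 0) & pad(0, 1) & pad(0, -1)
  rim <- m & !interior
  boost <- rim_gain_per_deg * abs(spec$doppler_angle_deg - 90) * truth$vmax_mm_s
  v[rim] <- v[rim] + boost
  if (noise_sd > 0)
    v[m] <- v[m] * exp(stats::rnorm(sum(m), 0, noise_sd))
  list(v_mm_s = v, mask = m, truth = truth)
}

#' Synthesize a vessel bifurcation (parent and two daughters)
#'
#' Generates three phantom datasets: a parent vessel A carrying rate `Q`, and
#' daughters B and C carrying `split * Q` and `(1 - split) * Q`. Daughter
#' diameters follow a branching power law `D_parent^k = D_B^k + D_C^k` with
#' configurable exponent. Each segment is imaged at two locations offset in
#' depth to encode its Doppler angle from the 200-um location spacing.
#'
#' @param parent_spec A [phantom_spec()] for the parent segment.
#' @param split_fraction Fraction of parent flow entering daughter B.
#' @param branching_exponent Exponent `k` of the branching law (3, Murray).
#' @param daughter_angles_deg Doppler angles of the two daughters (defaults to
#'   the parent's angle).
#' @param dx_um Spacing of the paired imaging locations (200).
#' @return A `bifurcation_phantom`: list of per-segment lists (`A`, `B`, `C`),
#'   each holding the segment `spec`, the synthesized `scan`+`truth` pair, the
#'   paired-location depth offset `dz_um` implied by its angle, and the
#'   ground-truth rates.
#' @export
synth_bifurcation <- function(parent_spec, split_fraction = 0.5,
                              branching_exponent = 3,
                              daughter_angles_deg = NULL, dx_um = 200) {
  stopifnot(inherits(parent_spec, "phantom_spec"))
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("split_fraction must be in (0, 1)")
  if (is.null(daughter_angles_deg))
    daughter_angles_deg <- rep(parent_spec$doppler_angle_deg, 2)
  Q <- parent_spec$pump_rate_ul_min
  Dp <- parent_spec$tube_diameter_um
  k <- branching_exponent
  # area split consistent with the branching law at the given flow split
  Db <- Dp * split_fraction^(1 / k)
  Dc <- Dp * (1 - split_fraction)^(1 / k)
  mk <- function(label, rate, diam, alpha, seed_off) {
    sp <- parent_spec
    sp$pump_rate_ul_min <- rate
    sp$tube_diameter_um <- diam
    sp$doppler_angle_deg <- alpha
    sp$seed <- parent_spec$seed + seed_off
    ph <- synth_stepped_mscan(sp)
    dz <- tan((alpha - 90) * pi / 180) * dx_um
    list(label = label, spec = sp, scan = ph$scan, truth = ph$truth,
         dz_um = dz, rate_ul_min = rate)
  }
  structure(list(
    A = mk("A", Q, Dp, parent_spec$doppler_angle_deg, 0L),
    B = mk("B", split_fraction * Q, Db, daughter_angles_deg[1], 1L),
    C = mk("C", (1 - split_fraction) * Q, Dc, daughter_angles_deg[2], 2L),
    split_fraction = split_fraction, branching_exponent = k,
    dx_um = dx_um),
    class = "bifurcation_phantom")
}

#' Synthesize a vessel series following a diameter power law
#'
#' Ground-truth dataset for power-law validation: vessels with the given
#' diameters carry rates `Q = c D^k`.
#'
#' @param diameters_um Vessel diameters (default 8 values spanning 36-120 um,
#'   the analyzed retinal range).
#' @param exponent Power-law exponent `k` (2.58).
#' @param coef_ul_min Rate of a 100-um vessel, anchoring the coefficient `c`.
#' @param lognormal_sd Optional multiplicative scatter on the rates.
#' @return A tibble with `diameter_um`, `rate_ul_min` and the generating
#'   parameters as attributes.
#' @export
synth_vessel_series <- function(diameters_um = exp(seq(log(36), log(120),
                                                       length.out = 8)),
                                exponent = 2.58, coef_ul_min = 10,
                                lognormal_sd = 0) {
  c0 <- coef_ul_min / 100^exponent
  q <- c0 * diameters_um^exponent
  if (lognormal_sd > 0)
    q <- q * exp(stats::rnorm(length(q), 0, lognormal_sd))
  out <- tibble::tibble(diameter_um = diameters_um, rate_ul_min = q)
  attr(out, "exponent") <- exponent
  attr(out, "coef") <- c0
  out
}
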