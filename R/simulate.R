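#' Gaussian beam model
#'
#' Lateral beam geometry of the OCT system. The amplitude profile used by the
#' forward model is `g(x) = exp(-x^2 / w0^2)` with `w0 = e2_diameter_um / 2`,
#' so that the intensity `|g|^2` falls to `e^-2` at radius `w0`.
#'
#' @param e2_diameter_um Lateral beam diameter at `e^-2` of intensity, in
#'   micrometers (system value 18).
#' @param axial_fwhm_um Axial resolution (FWHM in air), metadata only.
#' @return A `beam_model` list with fields `e2_diameter_um`, `axial_fwhm_um`
#'   and the derived amplitude radius `w0_um`.
#' @export
beam_model <- function(e2_diameter_um = 18, axial_fwhm_um = 10) {
  if (!is.numeric(e2_diameter_um) || e2_diameter_um <= 0)
    stop("beam e2_diameter_um must be > 0")
  structure(list(e2_diameter_um = e2_diameter_um,
                 axial_fwhm_um = axial_fwhm_um,
                 w0_um = e2_diameter_um / 2),
            class = "beam_model")
}

#' A-scan timing of the stepped M-scan protocol
#'
#' @param ascan_period_s Time between successive A-scans in seconds
#'   (1e-5 for a 100 kHz system).
#' @param n_samples Number of repeated A-scans per location (128).
#' @return A `scan_timing` list.
#' @export
scan_timing <- function(ascan_period_s = 1e-5, n_samples = 128L) {
  if (ascan_period_s <= 0) stop("ascan_period_s must be > 0")
  if (n_samples < 2) stop("n_samples must be >= 2")
  structure(list(ascan_period_s = ascan_period_s,
                 n_samples = as.integer(n_samples)),
            class = "scan_timing")
}

#' Point-scatterer field configuration
#'
#' Randomized point scatterers translate transversely through the beam focus.
#' Scatterers have unit amplitude and uniform random optical phase; fully
#' developed (Rayleigh) speckle emerges from their coherent summation. The
#' linear density acts as a scatterer-concentration knob (a crude hematocrit
#' proxy) and defaults to 2 scatterers per `e^-2` amplitude radius.
#'
#' @param density_per_um Linear scatterer density (scatterers per micrometer).
#' @param support_radii Beam support truncation, in units of `w0` (strip
#'   extends this far beyond the beam axis on both sides).
#' @return A `scatterer_config` list.
#' @export
scatterer_config <- function(density_per_um = 2 / 9, support_radii = 3) {
  if (density_per_um <= 0) stop("density_per_um must be > 0")
  structure(list(density_per_um = density_per_um,
                 support_radii = support_radii),
            class = "scatterer_config")
}

#' Ensemble-mean signal intensity of the forward model
#'
#' Closed form: for unit-amplitude scatterers of linear density `rho` and
#' amplitude profile `g(x) = exp(-x^2/w0^2)`, the ensemble mean of `|a|^2` is
#' `rho * integral(g^2) = rho * w0 * sqrt(pi/2)`. Shot noise levels are defined
#' against this fixed target brightness rather than per-record means.
#'
#' @param beam A [beam_model()].
#' @param scatterers A [scatterer_config()].
#' @return Mean intensity (arbitrary linear units).
#' @export
ensemble_mean_intensity <- function(beam = beam_model(),
                                    scatterers = scatterer_config()) {
  scatterers$density_per_um * beam$w0_um * sqrt(pi / 2)
}

#' Simulate noise-free OCT time series of transverse flow
#'
#' Forward model: point scatterers at random transverse positions `x_k` with
#' unit amplitudes and uniform phases `phi_k` translate at speed `v` through a
#' Gaussian beam. The complex field at sample time `t` is
#' `a(t) = sum_k exp(i phi_k) g(x_k - v t)`. Intensity is `|a|^2`. Each
#' realization redraws scatterer positions and phases.
#'
#' The scatterer strip spans the truncated beam support plus the total travel
#' distance `v (n_samples - 1) tau`, so the beam is fully covered throughout
#' the record.
#'
#' @param v_mm_s Transverse speed in mm/s (>= 0).
#' @param n Number of independent realizations.
#' @param beam A [beam_model()].
#' @param timing A [scan_timing()].
#' @param scatterers A [scatterer_config()].
#' @return An `oct_series` object: list with complex `field` and real
#'   `intensity` matrices of dimension `n x n_samples`, and `snr_db = Inf`
#'   (noise-free).
#' @examples
#' set.seed(1)
#' s <- simulate_field(50, n = 4)
#' dim(s$intensity)
#' @export
simulate_field <- function(v_mm_s, n = 1L, beam = beam_model(),
                           timing = scan_timing(),
                           scatterers = scatterer_config()) {
  if (v_mm_s < 0) stop("velocity must be >= 0")
  w0 <- beam$w0_um
  tau <- timing$ascan_period_s
  nt <- timing$n_samples
  v_um_s <- v_mm_s * 1e3
  travel <- v_um_s * tau * (nt - 1)
  half <- scatterers$support_radii * w0
  # strip [-half, half + travel]: covers beam support at t = 0 and t = T
  strip_len <- 2 * half + travel
  lambda_k <- scatterers$density_per_um * strip_len
  t_idx <- (seq_len(nt) - 1) * tau
  field <- matrix(0 + 0i, n, nt)
  for (r in seq_len(n)) {
    nk <- stats::rpois(1, lambda_k)
    if (nk > 0) {
      xk <- stats::runif(nk, -half, half + travel)
      ph <- exp(1i * stats::runif(nk, 0, 2 * pi))
      # positions relative to beam center at each sample time
      d <- outer(xk, v_um_s * t_idx, "-")
      field[r, ] <- crossprod(exp(-d^2 / w0^2), ph)[, 1]
    }
  }
  structure(list(field = field,
                 intensity = Mod(field)^2,
                 snr_db = Inf,
                 beam = beam, timing = timing, scatterers = scatterers),
            class = "oct_series")
}

#' Add shot noise to a simulated series at a prescribed SNR
#'
#' Complex circular Gaussian noise is added to the field with variance
#' `sigma^2 = Ibar / 10^(snr_db/10)` where `Ibar` is the ensemble-mean signal
#' intensity of the forward model ([ensemble_mean_intensity()]). Intensity is
#' recomputed from the noisy field. `snr_db = Inf` returns the input unchanged.
#'
#' @param s An `oct_series` from [simulate_field()] (noise-free).
#' @param snr_db Signal-to-noise ratio in dB (finite, or `Inf` for no noise).
#' @return An `oct_series` with the noisy field and intensity, `snr_db`
#'   recorded.
#' @export
add_shot_noise <- function(s, snr_db) {
  stopifnot(inherits(s, "oct_series"))
  if (is.infinite(snr_db) && snr_db > 0) return(s)
  if (!is.finite(snr_db)) stop("snr_db must be finite (or +Inf for none)")
  if (is.finite(s$snr_db))
    stop("input series already carries noise")
  ibar <- ensemble_mean_intensity(s$beam, s$scatterers)
  sigma2 <- ibar / 10^(snr_db / 10)
  nn <- length(s$field)
  noise <- complex(real = stats::rnorm(nn, 0, sqrt(sigma2 / 2)),
                   imaginary = stats::rnorm(nn, 0, sqrt(sigma2 / 2)))
  f <- s$field + noise
  s$field <- f
  s$intensity <- Mod(f)^2
  s$snr_db <- snr_db
  s
}

#' Self-normalize intensity records to unity mean
#'
#' Each 128-sample intensity record is divided by its own mean; the
#' normalization of a record uses only that record's samples, never a broader
#' ensemble. This is the representation the classifier is trained on.
#'
#' @param x An `oct_series`, or a numeric matrix (rows = records) or vector.
#' @return Same shape as the input, every record with mean exactly 1.
#' @export
self_normalize <- function(x) {
  if (inherits(x, "oct_series")) {
    x$intensity <- self_normalize(x$intensity)
    return(x)
  }
  if (is.matrix(x)) {
    m <- rowMeans(x)
    if (any(m <= 0)) stop("cannot self-normalize a record with mean <= 0")
    return(x / m)
  }
  m <- mean(x)
  if (m <= 0) stop("cannot self-normalize a record with mean <= 0")
  x / m
}

#' Training-library specification
#'
#' The full-scale configuration pairs 64 velocity classes with 31 SNR levels
#' (5 to 35 dB in 1 dB steps) and 25,000 realizations per (velocity, SNR) cell
#' split 22,000/3,000 into training and validation. Scaled specifications use
#' the same structure at smaller sizes.
#'
#' @param grid A [velocity_grid()].
#' @param snr_levels_db Strictly increasing vector of SNR levels (dB).
#' @param realizations Realizations per (velocity, SNR) cell.
#' @param n_train,n_val Training / validation split per cell
#'   (`n_train + n_val <= realizations`).
#' @param seed Integer seed; the library is bit-reproducible given the spec.
#' @param beam,timing,scatterers Forward-model configuration.
#' @return A `library_spec` list.
#' @export
library_spec <- function(grid, snr_levels_db, realizations = 25000L,
                         n_train = 22000L, n_val = 3000L, seed = 1L,
                         beam = beam_model(), timing = scan_timing(),
                         scatterers = scatterer_config()) {
  stopifnot(inherits(grid, "velocity_grid"))
  if (is.unsorted(snr_levels_db, strictly = TRUE))
    stop("snr_levels_db must be strictly increasing")
  if (n_train + n_val > realizations)
    stop("realizations must cover the train + validation split")
  structure(list(grid = grid, snr_levels_db = as.numeric(snr_levels_db),
                 realizations = as.integer(realizations),
                 n_train = as.integer(n_train), n_val = as.integer(n_val),
                 seed = as.integer(seed),
                 beam = beam, timing = timing, scatterers = scatterers),
            class = "library_spec")
}

#' Record count of a library specification
#'
#' Computed without materializing any data: classes x SNR levels x
#' realizations. The full-scale configuration evaluates to 49.6 million
#' (64 x 31 x 25,000).
#'
#' @param spec A [library_spec()].
#' @return Total record count (double, to hold large products).
#' @export
library_size <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  as.numeric(length(spec$grid)) * length(spec$snr_levels_db) *
    spec$realizations
}

#' Build a simulated signal library
#'
#' Generates `realizations` records for every (velocity class, SNR level)
#' cell: fresh scatterer draws per realization, shot noise at the cell's SNR.
#' Deterministic for a fixed spec (each cell reseeds from `spec$seed` and the
#' cell index, so a scaled spec is reproducible and cells are independent).
#'
#' @param spec A [library_spec()].
#' @param normalize Self-normalize the stored intensities (default TRUE; the
#'   classifier consumes normalized records).
#' @return A `signal_library`: list with `intensity` matrix
#'   `[N x n_samples]`, integer `velocity_label` (class index), numeric
#'   `snr_label` (dB), logical `is_train`, and the `spec`.
#' @export
build_library <- function(spec, normalize = TRUE) {
  stopifnot(inherits(spec, "library_spec"))
  nclass <- length(spec$grid)
  nsnr <- length(spec$snr_levels_db)
  nreal <- spec$realizations
  nt <- spec$timing$n_samples
  ntotal <- nclass * nsnr * nreal
  intensity <- matrix(NA_real_, ntotal, nt)
  vlab <- integer(ntotal); slab <- numeric(ntotal); istr <- logical(ntotal)
  row <- 0L
  split <- c(rep(TRUE, spec$n_train), rep(FALSE, nreal - spec$n_train))
  for (iv in seq_len(nclass)) {
    for (isnr in seq_len(nsnr)) {
      cell_seed <- (spec$seed + 7919L * iv + 104729L * isnr) %% .Machine$integer.max
      set.seed(cell_seed)
      s <- simulate_field(spec$grid[iv], n = nreal, beam = spec$beam,
                          timing = spec$timing, scatterers = spec$scatterers)
      s <- add_shot_noise(s, spec$snr_levels_db[isnr])
      idx <- row + seq_len(nreal)
      intensity[idx, ] <- if (normalize) self_normalize(s$intensity) else s$intensity
      vlab[idx] <- iv
      slab[idx] <- spec$snr_levels_db[isnr]
      istr[idx] <- split
      row <- row + nreal
    }
  }
  structure(list(intensity = intensity, velocity_label = vlab,
                 snr_label = slab, is_train = istr, spec = spec,
                 normalized = normalize),
            class = "signal_library")
}

#' @export
print.signal_library <- function(x, ...) {
  cat(sprintf("<signal_library> %d records: %d classes x %d SNRs x %d realizations\n",
              nrow(x$intensity), length(x$spec$grid),
              length(x$spec$snr_levels_db), x$spec$realizations))
  invisible(x)
}

#' Extract one SNR slice of a signal library
#'
#' @param lib A `signal_library`.
#' @param snr_db One of the library's SNR levels.
#' @return A `signal_library` restricted to that SNR.
#' @export
library_slice <- function(lib, snr_db) {
  stopifnot(inherits(lib, "signal_library"))
  keep <- lib$snr_label == snr_db
  if (!any(keep)) stop("library holds no records at ", snr_db, " dB")
  lib$intensity <- lib$intensity[keep, , drop = FALSE]
  lib$velocity_label <- lib$velocity_label[keep]
  lib$snr_label <- lib$snr_label[keep]
  lib$is_train <- lib$is_train[keep]
  lib
}
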