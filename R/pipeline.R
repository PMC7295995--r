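#' Per-pixel SNR map of a stepped M-scan
#'
#' SNR is `10 log10(mean |a|^2 over time / noise_floor)` with the noise floor
#' estimated as the mean intensity over a designated signal-free region. By
#' default the deepest 10 percent of pixels are taken as the noise region.
#'
#' @param scan A `stepped_mscan`.
#' @param noise_region Logical `[nx x nz]` marking noise-only pixels, or
#'   `NULL` for the default (deepest 10 percent of depths).
#' @param exclude Optional logical mask of pixels that must not enter the
#'   noise region (e.g. a vessel mask); overlap is an error.
#' @return An `snr_map`: list with `snr_db` `[nx x nz]` and `noise_floor`.
#' @export
estimate_snr_map <- function(scan, noise_region = NULL, exclude = NULL) {
  stopifnot(inherits(scan, "stepped_mscan"))
  d <- dim(scan$data)
  meanI <- rowMeans(Mod(scan$data)^2, dims = 2)
  if (is.null(noise_region)) {
    noise_region <- matrix(FALSE, d[1], d[2])
    z0 <- ceiling(d[2] * 0.9) + 1L
    if (z0 > d[2]) z0 <- d[2]
    noise_region[, z0:d[2]] <- TRUE
  }
  if (!any(noise_region)) stop("noise region is empty")
  if (!is.null(exclude) && any(noise_region & exclude))
    stop("noise region overlaps excluded (signal) pixels")
  noise_floor <- mean(meanI[noise_region])
  if (noise_floor <= 0)
    stop("noise floor is zero; designate a noise region that contains ",
         "detection noise (noise-free synthetic data has none)")
  structure(list(snr_db = 10 * log10(meanI / noise_floor),
                 noise_floor = noise_floor),
            class = "snr_map")
}

#' Pixel-by-pixel velocity likelihood of a B-scan
#'
#' Applies the SNR-matched classifier bank to every pixel's time series
#' independently: each series is self-normalized, the network nearest the
#' pixel's estimated SNR is selected, and its likelihood curve stored. No
#' information crosses pixels at this stage.
#'
#' @param scan A `stepped_mscan` whose series length matches the bank input.
#' @param bank A `network_bank`.
#' @param snr An `snr_map` from [estimate_snr_map()]; pixel SNRs select the
#'   network (rounded to the nearest trained level, clamped to the range).
#' @return A `likelihood_map`: array `[nx x nz x n_classes]` of likelihood
#'   curves with attributes `grid` and `filtered = FALSE`.
#' @export
classify_bscan <- function(scan, bank, snr) {
  stopifnot(inherits(scan, "stepped_mscan"), inherits(bank, "network_bank"),
            inherits(snr, "snr_map"))
  d <- dim(scan$data)
  nt <- d[3]
  input_len <- bank$nets[[1]]$arch$input_len
  if (nt != input_len)
    stop("scan series length ", nt, " does not match network input length ",
         input_len)
  X <- Mod(scan$data)^2
  dim(X) <- c(d[1] * d[2], nt)
  X <- self_normalize(X)
  lv <- bank$snr_levels_db
  snr_px <- pmin(pmax(as.vector(snr$snr_db), min(lv)), max(lv))
  # nearest trained level per pixel, ties toward the lower level
  nearest <- vapply(snr_px, function(s) {
    dd <- abs(lv - s); which(dd == min(dd))[1]
  }, integer(1))
  nclass <- length(bank$grid)
  L <- matrix(NA_real_, d[1] * d[2], nclass)
  for (k in sort(unique(nearest))) {
    rows <- which(nearest == k)
    L[rows, ] <- predict_likelihood(bank$nets[[as.character(lv[k])]],
                                    X[rows, , drop = FALSE])
  }
  dim(L) <- c(d[1], d[2], nclass)
  structure(L, class = "likelihood_map", grid = bank$grid, filtered = FALSE)
}

#' Spatial likelihood filtering and velocity classification
#'
#' Elementwise product of the likelihood curves over each pixel's 3x3
#' neighborhood (edge pixels use the available neighbors only; no padding).
#' The argmax of the filtered curve gives the velocity class; ties break
#' toward the lower velocity and are flagged.
#'
#' @param lmap A `likelihood_map` from [classify_bscan()] (unfiltered).
#' @param kernel Neighborhood half-width (1 = the 3x3 kernel).
#' @return A `velocity_map`: list with `v_mm_s`, `class_index`, `tie` flags
#'   and the `grid`.
#' @export
filter_likelihood <- function(lmap, kernel = 1L) {
  stopifnot(inherits(lmap, "likelihood_map"))
  if (isTRUE(attr(lmap, "filtered"))) stop("likelihood map already filtered")
  grid <- attr(lmap, "grid")
  d <- dim(lmap)
  nx <- d[1]; nz <- d[2]; nc <- d[3]
  # product over the neighborhood in log space for numerical stability
  logL <- log(pmax(unclass(lmap), 1e-300))
  acc <- array(0, d)
  for (di in -kernel:kernel) {
    i_dst <- max(1, 1 + di):min(nx, nx + di)
    i_src <- i_dst - di
    for (dj in -kernel:kernel) {
      j_dst <- max(1, 1 + dj):min(nz, nz + dj)
      j_src <- j_dst - dj
      acc[i_dst, j_dst, ] <- acc[i_dst, j_dst, , drop = FALSE] +
        logL[i_src, j_src, , drop = FALSE]
    }
  }
  flat <- matrix(acc, nx * nz, nc)
  cls <- max.col(flat, ties.method = "first")
  best <- flat[cbind(seq_len(nx * nz), cls)]
  n_best <- rowSums(flat == best)
  structure(list(v_mm_s = matrix(grid[cls], nx, nz),
                 class_index = matrix(cls, nx, nz),
                 tie = matrix(n_best > 1, nx, nz),
                 grid = grid),
            class = "velocity_map")
}

#' Angiography vessel mask from temporal intensity decorrelation
#'
#' Flow pixels show strong temporal modulation of their speckle intensity
#' while static pixels stay constant. The statistic is the variance of the
#' self-normalized intensity series; pixels above `threshold` are kept and
#' reduced to the largest 4-connected component. The default threshold is 5
#' times the image median of the statistic (the static background dominates
#' the median).
#'
#' @param scan A `stepped_mscan`.
#' @param threshold Absolute threshold on the variance statistic, or `NULL`
#'   for the default (5 times the statistic's median over usable pixels).
#' @param min_pixels Components smaller than this are ignored; the default
#'   scales with the image (0.5 percent of its pixels, at least 9) so that
#'   the scattered high-variance tail of static speckle-plus-noise pixels is
#'   never mistaken for a vessel.
#' @param snr An `snr_map`, or `NULL` to estimate one with the default noise
#'   region. Pixels at or below `min_snr_db` are never part of the mask: the
#'   noise floor decorrelates like flow and must be excluded.
#' @param min_snr_db Minimum pixel SNR for mask membership (3 dB).
#' @return A `vessel_mask`: list with logical `mask`, `center` (lateral,
#'   depth pixel coordinates of the centroid), `R_pix` (equivalent-area
#'   radius in pixels) and the `statistic` map.
#' @export
angiography_mask <- function(scan, threshold = NULL, min_pixels = NULL,
                             snr = NULL, min_snr_db = 3) {
  stopifnot(inherits(scan, "stepped_mscan"))
  d <- dim(scan$data)
  if (is.null(min_pixels)) min_pixels <- max(9L, round(0.005 * d[1] * d[2]))
  if (is.null(snr)) snr <- estimate_snr_map(scan)
  usable <- snr$snr_db > min_snr_db
  X <- Mod(scan$data)^2
  dim(X) <- c(d[1] * d[2], d[3])
  X <- X / pmax(rowMeans(X), .Machine$double.xmin)
  v <- matrix(.row_var(X), d[1], d[2])
  if (is.null(threshold)) threshold <- 5 * stats::median(v[usable])
  if (threshold <= 0) warning("threshold <= 0: mask includes every pixel")
  hit <- v > threshold & usable
  if (!any(hit)) stop("no pixels exceed the angiography threshold")
  comp <- .label_components(hit)
  sizes <- tabulate(comp[comp > 0])
  big <- which.max(sizes)
  if (sizes[big] < min_pixels) stop("no connected component above minimum size")
  mask <- comp == big
  idx <- which(mask, arr.ind = TRUE)
  center <- colMeans(idx)
  structure(list(mask = mask, center = center,
                 R_pix = sqrt(sum(mask) / pi), statistic = v,
                 threshold = threshold),
            class = "vessel_mask")
}

.row_var <- function(X) {
  n <- ncol(X)
  (rowSums(X^2) - n * rowMeans(X)^2) / (n - 1)
}

# 4-connected component labelling (iterative flood fill)
.label_components <- function(m) {
  nx <- nrow(m); nz <- ncol(m)
  lab <- matrix(0L, nx, nz)
  cur <- 0L
  todo <- which(m & lab == 0L)
  while (length(todo)) {
    cur <- cur + 1L
    stack <- todo[1]
    lab[stack] <- cur
    while (length(stack)) {
      k <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- (k - 1L) %% nx + 1L; j <- (k - 1L) %/% nx + 1L
      nb <- c(if (i > 1L) k - 1L, if (i < nx) k + 1L,
              if (j > 1L) k - nx, if (j < nz) k + nx)
      nb <- nb[m[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      stack <- c(stack, nb)
    }
    todo <- which(m & lab == 0L)
  }
  lab
}

#' Construct a vessel mask from known geometry
#'
#' Used when the lumen is segmented externally (e.g. the phantom's known
#' tube position) rather than by angiography processing.
#'
#' @param mask Logical `[nx x nz]` lumen mask.
#' @return A `vessel_mask` with centroid and equivalent-area radius.
#' @export
vessel_mask <- function(mask) {
  if (!any(mask)) stop("empty vessel mask")
  idx <- which(mask, arr.ind = TRUE)
  structure(list(mask = mask, center = colMeans(idx),
                 R_pix = sqrt(sum(mask) / pi), statistic = NULL,
                 threshold = NA_real_),
            class = "vessel_mask")
}
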