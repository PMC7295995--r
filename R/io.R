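.SCAN_SCHEMA <- "octflow-scan/1"
.SCAN_REQUIRED <- c("ascan_period_s", "lateral_step_um", "axial_pixel_um",
                    "wavelength_nm")

#' Write / read a stepped M-scan container
#'
#' Scans are stored as a versioned, self-describing serialized container: the
#' complex data cube plus the acquisition attributes (A-scan period, lateral
#' step, axial pixel size, wavelength, optional Doppler angle). Reading
#' validates the schema stamp and the presence of all required attributes;
#' the round trip is lossless.
#'
#' @param scan A `stepped_mscan`.
#' @param path File path (conventionally `.rds`).
#' @return `write_scan` returns `path` invisibly; `read_scan` the scan.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "stepped_mscan"))
  payload <- list(schema = .SCAN_SCHEMA,
                  data = scan$data,
                  attrs = list(ascan_period_s = scan$timing$ascan_period_s,
                               n_samples = scan$timing$n_samples,
                               lateral_step_um = scan$lateral_step_um,
                               axial_pixel_um = scan$axial_pixel_um,
                               wavelength_nm = scan$wavelength_nm,
                               n_blood = scan$n_blood,
                               doppler_angle_deg = scan$doppler_angle_deg))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$schema, .SCAN_SCHEMA))
    stop("not an octflow scan container: ", path)
  missing <- setdiff(.SCAN_REQUIRED, names(payload$attrs))
  missing <- c(missing,
               .SCAN_REQUIRED[vapply(payload$attrs[.SCAN_REQUIRED],
                                     is.null, logical(1))])
  if (length(missing))
    stop("scan container missing required attributes: ",
         paste(unique(missing), collapse = ", "))
  at <- payload$attrs
  structure(list(data = payload$data,
                 timing = scan_timing(at$ascan_period_s,
                                      if (is.null(at$n_samples))
                                        dim(payload$data)[3] else at$n_samples),
                 lateral_step_um = at$lateral_step_um,
                 axial_pixel_um = at$axial_pixel_um,
                 wavelength_nm = at$wavelength_nm,
                 n_blood = at$n_blood,
                 doppler_angle_deg = at$doppler_angle_deg),
            class = "stepped_mscan")
}

#' B-scan acquisition duration of the stepped M-scan protocol
#'
#' `n_locations * n_samples * ascan_period`; 100 locations of 128 A-scans at
#' 10 us give 0.13 s per B-scan and 1.3 s for 10 repeats.
#'
#' @param n_locations Lateral locations per B-scan.
#' @param timing A [scan_timing()].
#' @param repeats Number of repeated B-scans.
#' @return Duration in seconds.
#' @export
protocol_duration_s <- function(n_locations = 100L, timing = scan_timing(),
                                repeats = 1L) {
  n_locations * timing$n_samples * timing$ascan_period_s * repeats
}

#' Run manifest for provenance
#'
#' Records the configuration digest, seeds, package version and input file
#' digests of a pipeline run so that deterministic stages can be reproduced
#' bit-exactly.
#'
#' @param config A list of configuration values (digested as JSON).
#' @param seed The run seed.
#' @param inputs Character vector of input file paths (digested if present).
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(config = list(), seed = NA_integer_,
                         inputs = character(0)) {
  digest_file <- function(p)
    if (file.exists(p) && !dir.exists(p)) unname(tools::md5sum(p)) else NA_character_
  structure(list(
    config_digest = unname(tools::md5sum(
      {tf <- tempfile(); writeLines(jsonlite::toJSON(config, auto_unbox = TRUE,
                                                     digits = NA, force = TRUE), tf); tf})),
    seed = seed,
    package_version = as.character(utils::packageVersion("octflow")),
    inputs = stats::setNames(vapply(inputs, digest_file, character(1)),
                             inputs),
    timestamp = format(Sys.time(), tz = "UTC")),
    class = "run_manifest")
}

#' Command-line dispatcher
#'
#' Thin dispatcher behind the `octflow` command-line script. Subcommands:
#' `simulate-library`, `train`, `estimate`, `doppler`, `flowrate`,
#' `phantom`. Each takes `--config` (YAML/JSON) and/or direct options plus a
#' global `--seed`, and writes a run manifest next to its output.
#'
#' @param argv Character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit code (0 on success), invisibly.
#' @export
cli_dispatch <- function(argv = commandArgs(trailingOnly = TRUE)) {
  subcommands <- c("simulate-library", "train", "estimate", "doppler",
                   "flowrate", "phantom")
  usage <- function() {
    cat("usage: octflow <subcommand> [--seed N] [options]\n",
        "subcommands:\n",
        paste0("  ", subcommands, "\n"), sep = "")
  }
  if (!length(argv) || argv[1] %in% c("--help", "-h")) {
    usage()
    return(invisible(0L))
  }
  cmd <- argv[1]
  if (!cmd %in% subcommands) {
    message("unknown subcommand: ", cmd)
    usage()
    return(invisible(2L))
  }
  opts <- .parse_cli_options(argv[-1])
  seed <- as.integer(opts$seed %||% 1L)
  set.seed(seed)
  out <- opts$out %||% stop("--out is required")
  cfg <- if (!is.null(opts$config)) .read_config(opts$config) else list()
  code <- switch(cmd,
    "simulate-library" = .cli_simulate_library(cfg, opts, seed, out),
    "train" = .cli_train(cfg, opts, seed, out),
    "estimate" = .cli_estimate(cfg, opts, seed, out),
    "doppler" = .cli_doppler(cfg, opts, seed, out),
    "flowrate" = .cli_flowrate(cfg, opts, seed, out),
    "phantom" = .cli_phantom(cfg, opts, seed, out))
  manifest <- run_manifest(config = c(cfg, opts), seed = seed,
                           inputs = unlist(opts[c("scan", "library", "bank",
                                                  "velocity", "mask")],
                                           use.names = FALSE))
  jsonlite::write_json(unclass(manifest), paste0(out, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(code %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parse_cli_options <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        opts[[key]] <- args[i + 1L]
        i <- i + 2L
      } else {
        opts[[key]] <- TRUE
        i <- i + 1L
      }
    } else i <- i + 1L
  }
  opts
}

.read_config <- function(path) {
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

.scaled_default_spec <- function(cfg, seed) {
  g <- velocity_grid(cfg$n_classes %||% 12L, cfg$vmin %||% 2,
                     cfg$vmax %||% 400)
  library_spec(g, cfg$snr_levels_db %||% c(10, 15, 20),
               realizations = cfg$realizations %||% 1000L,
               n_train = cfg$n_train %||% 880L,
               n_val = cfg$n_val %||% 120L, seed = seed)
}

.cli_simulate_library <- function(cfg, opts, seed, out) {
  spec <- .scaled_default_spec(cfg, seed)
  lib <- build_library(spec)
  saveRDS(lib, out)
  message("wrote ", out, " (", nrow(lib$intensity), " records)")
  0L
}

.cli_train <- function(cfg, opts, seed, out) {
  lib <- readRDS(opts$library %||% stop("--library is required"))
  tc <- training_config(epochs = as.integer(cfg$epochs %||% 30L),
                        seed = seed,
                        patience = cfg$patience %||% 4)
  bank <- train_bank(lib, tc)
  save_bank(bank, out)
  message("wrote bank with ", length(bank$nets), " networks to ", out)
  0L
}

.cli_estimate <- function(cfg, opts, seed, out) {
  scan <- read_scan(opts$scan %||% stop("--scan is required"))
  bank <- load_bank(opts$bank %||% stop("--bank is required"))
  snr <- estimate_snr_map(scan)
  vmap <- filter_likelihood(classify_bscan(scan, bank, snr))
  saveRDS(list(velocity_map = vmap, snr_map = snr), out)
  message("wrote ", out)
  0L
}

.cli_doppler <- function(cfg, opts, seed, out) {
  scan <- read_scan(opts$scan %||% stop("--scan is required"))
  alpha <- if (!is.null(opts$angle)) as.numeric(opts$angle)
    else if (!is.null(opts$scan2)) {
      scan2 <- read_scan(opts$scan2)
      z1 <- .vessel_depth_um(scan); z2 <- .vessel_depth_um(scan2)
      doppler_angle_from_depth_shift(z1, z2, as.numeric(opts$dx %||% 200))
    } else stop("provide --angle or a paired --scan2 with --dx")
  snr <- estimate_snr_map(scan)
  mask <- angiography_mask(scan, snr = snr)
  static <- !mask$mask
  dop <- doppler_velocimetry(scan, alpha, static_mask = static,
                             snr_map = snr)
  saveRDS(dop, out)
  message("wrote ", out, " (alpha ", round(alpha, 2), " deg)")
  0L
}

.vessel_depth_um <- function(scan) {
  m <- angiography_mask(scan)
  n_blood <- scan$n_blood %||% 1.36
  m$center[2] * scan$axial_pixel_um / n_blood
}

.cli_flowrate <- function(cfg, opts, seed, out) {
  obj <- readRDS(opts$velocity %||% stop("--velocity is required"))
  vmap <- if (is.list(obj) && !is.null(obj$velocity_map)) obj$velocity_map else obj
  mask <- readRDS(opts$mask %||% stop("--mask is required"))
  geom <- pixel_geometry(as.numeric(opts$`lateral-step` %||% 3),
                         as.numeric(opts$`axial-pixel` %||% 4.2))
  res <- masked_flow_rate(vmap, mask, geom,
                          ra = as.numeric(opts$ra %||% 0.67))
  if (!is.null(opts$scale))
    res <- apply_calibration(res, calibration_constant(as.numeric(opts$scale)))
  report <- list(rate_ul_min = res$rate_ul_min, vmax_mm_s = res$vmax_mm_s,
                 R_um = res$R_um, ra = res$ra, calibrated = res$calibrated)
  jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA)
  message("wrote ", out)
  0L
}

.cli_phantom <- function(cfg, opts, seed, out) {
  sp <- phantom_spec(
    tube_diameter_um = cfg$tube_diameter_um %||% 125,
    doppler_angle_deg = cfg$doppler_angle_deg %||% 90,
    pump_rate_ul_min = cfg$pump_rate_ul_min %||% 50,
    snr_db = cfg$snr_db %||% 25,
    n_locations = cfg$n_locations %||% 100L,
    n_depth = cfg$n_depth %||% 60L,
    seed = seed)
  ph <- synth_stepped_mscan(sp)
  write_scan(ph$scan, out)
  saveRDS(ph$truth, paste0(out, ".truth.rds"))
  message("wrote ", out)
  0L
}
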