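# Shared fixtures, built once per test run on first use.
#
# The scaled study conditions used throughout the suite: 12 velocity classes
# between 2 and 400 mm/s, SNR levels {10, 15, 20} dB, 1000 realizations per
# (velocity, SNR) cell split 880/120, training for at most 30 epochs with
# early stopping. Training the three-network bank dominates the suite's
# runtime, so it is cached in this environment and shared by every test that
# needs it.

.fixtures <- new.env(parent = emptyenv())

scaled_grid <- function() velocity_grid(12L, 2, 400)

scaled_library_spec <- function() {
  library_spec(scaled_grid(), c(10, 15, 20), realizations = 1000L,
               n_train = 880L, n_val = 120L, seed = 42L)
}

get_scaled_library <- function() {
  if (is.null(.fixtures$lib))
    .fixtures$lib <- build_library(scaled_library_spec())
  .fixtures$lib
}

get_scaled_bank <- function() {
  if (is.null(.fixtures$bank)) {
    cfg <- training_config(epochs = 20L, seed = 7L, patience = 4)
    .fixtures$bank <- train_bank(get_scaled_library(), cfg)
  }
  .fixtures$bank
}

# small, fast phantom for unit tests (not the acceptance phantom)
small_phantom <- function(alpha = 90, rate = 10, snr = 25, seed = 3L,
                          jitter = 0) {
  synth_stepped_mscan(phantom_spec(
    tube_diameter_um = 60, doppler_angle_deg = alpha,
    pump_rate_ul_min = rate, snr_db = snr,
    n_locations = 40L, n_depth = 32L, lateral_step_um = 3,
    axial_pixel_um = 4.2, bulk_jitter_rad = jitter, seed = seed))
}
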