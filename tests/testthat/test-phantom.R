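test_that("Poiseuille peak speed matches the hand-computed closed form", {
  # 50 uL/min in a 125 um tube: vmax = 2 Q / (pi R^2)
  # = 2 * (50/60 * 1e9 um^3/s) / (pi * 62.5^2 um^2) = 135.81 mm/s
  expect_equal(poiseuille_peak_speed(50, 125), 135.8122, tolerance = 1e-5)
  expect_equal(poiseuille_peak_speed(0, 125), 0)
  # peak = 2 x mean
  tr <- phantom_truth(phantom_spec(pump_rate_ul_min = 50))
  mean_v <- 50 / 60 * 1e9 / (pi * 62.5^2) / 1e3
  expect_equal(tr$vmax_mm_s, 2 * mean_v, tolerance = 1e-12)
})

test_that("ground truth is self-consistent: map integral matches the pump rate", {
  sp <- phantom_spec(pump_rate_ul_min = 50)  # ~40 pixels across the lumen
  tr <- phantom_truth(sp)
  A_pix <- sp$lateral_step_um * sp$axial_pixel_um / sp$n_blood
  q <- sum(tr$v_mm_s[tr$mask]) * A_pix * 6e-5
  expect_lt(abs(q - 50) / 50, 0.02)
})

test_that("phantom scans are deterministic and respect the angle convention", {
  ph1 <- small_phantom(alpha = 85, rate = 8, seed = 5L)
  ph2 <- small_phantom(alpha = 85, rate = 8, seed = 5L)
  expect_identical(ph1$scan$data, ph2$scan$data)
  # alpha = 90: no axial phase ramp anywhere
  tr90 <- phantom_truth(phantom_spec(doppler_angle_deg = 90))
  expect_equal(max(abs(tr90$dphi_rad)), 0, tolerance = 1e-12)
  tr85 <- phantom_truth(phantom_spec(doppler_angle_deg = 85,
                                     pump_rate_ul_min = 50))
  expect_gt(max(abs(tr85$dphi_rad)), 0.1)
})

test_that("zero flow makes the lumen temporally static like the background", {
  ph <- small_phantom(rate = 0, snr = Inf)
  I <- Mod(ph$scan$data)^2
  lum_sd <- apply(I, c(1, 2), sd)[ph$truth$mask]
  expect_equal(max(lum_sd), 0, tolerance = 1e-9)
})

test_that("edge-artifact maps elevate only the rim, growing with |alpha - 90|", {
  sp80 <- phantom_spec(doppler_angle_deg = 80, pump_rate_ul_min = 20)
  sp90 <- phantom_spec(doppler_angle_deg = 90, pump_rate_ul_min = 20)
  art80 <- synth_edge_artifact_map(sp80)
  art90 <- synth_edge_artifact_map(sp90)
  tr <- art80$truth
  expect_equal(art90$v_mm_s, tr$v_mm_s, tolerance = 1e-12)  # no boost at 90
  excess <- art80$v_mm_s - tr$v_mm_s
  expect_gt(max(excess), 0.9 * tr$vmax_mm_s)  # 0.1/deg * 10 deg * vmax
  interior <- tr$v_mm_s > 0.5 * tr$vmax_mm_s
  expect_equal(max(abs(excess[interior])), 0)
})

test_that("bifurcation phantoms conserve flow and encode angles in depth shifts", {
  parent <- phantom_spec(pump_rate_ul_min = 40, doppler_angle_deg = 95,
                         n_locations = 30L, n_depth = 24L,
                         tube_diameter_um = 60, seed = 9L)
  bif <- synth_bifurcation(parent, split_fraction = 0.4,
                           branching_exponent = 3)
  expect_equal(bif$A$rate_ul_min,
               bif$B$rate_ul_min + bif$C$rate_ul_min)
  expect_equal(bif$B$rate_ul_min, 16)
  # branching law: D_B^3 + D_C^3 = D_A^3
  expect_equal(bif$B$spec$tube_diameter_um^3 + bif$C$spec$tube_diameter_um^3,
               60^3, tolerance = 1e-9)
  # recover the Doppler angle from the encoded depth shift
  a_hat <- doppler_angle_from_depth_shift(0, bif$A$dz_um, 200)
  expect_equal(a_hat, 95, tolerance = 1e-9)
  expect_error(synth_bifurcation(parent, split_fraction = 1.2))
})

test_that("vessel series follows the prescribed power law exactly", {
  vs <- synth_vessel_series(exponent = 2.58)
  fit <- power_law_fit(vs$diameter_um, vs$rate_ul_min)
  expect_equal(fit$slope, 2.58, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  flat <- synth_vessel_series(exponent = 0)
  expect_equal(sd(flat$rate_ul_min), 0, tolerance = 1e-12)
})

test_that("repeated B-scans modulate the pump rate when pulsatility is set", {
  sp <- phantom_spec(tube_diameter_um = 30, pump_rate_ul_min = 6,
                     n_locations = 16L, n_depth = 14L,
                     pulsatility = list(amplitude = 0.3, period_s = 0.08),
                     seed = 4L)
  reps <- synth_repeated_mscans(sp, n_repeats = 5L)
  rates <- vapply(reps, function(p) p$truth$rate_ul_min, numeric(1))
  bscan_s <- 16 * 128 * 1e-5
  expected <- 6 * (1 + 0.3 * cos(2 * pi * (0:4) * bscan_s / 0.08))
  expect_equal(rates, expected, tolerance = 1e-12)
  # speckle differs between repeats, geometry does not
  expect_false(identical(reps[[1]]$scan$data, reps[[2]]$scan$data))
  expect_identical(reps[[1]]$truth$mask, reps[[2]]$truth$mask)
  # no pulsatility: constant rate
  sp0 <- phantom_spec(tube_diameter_um = 30, pump_rate_ul_min = 6,
                      n_locations = 16L, n_depth = 14L, seed = 4L)
  reps0 <- synth_repeated_mscans(sp0, n_repeats = 3L)
  expect_equal(vapply(reps0, function(p) p$truth$rate_ul_min, numeric(1)),
               rep(6, 3))
})
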