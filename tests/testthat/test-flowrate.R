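test_that("pixel flow rate obeys the unit conversion by hand", {
  geom <- pixel_geometry(lateral_step_um = 5, axial_pixel_um = 2.72)
  expect_equal(geom$A_pix_um2, 5 * 2.72 / 1.36)  # = 10 um^2
  m <- matrix(FALSE, 3, 3); m[2, 2] <- TRUE
  v <- matrix(0, 3, 3); v[2, 2] <- 1  # 1 mm/s
  # 1 mm/s * 10 um^2 = 1e-8 cm^3/s = 1e-5 uL/s = 6e-4 uL/min
  res <- pixel_flow_rate(v, geom, m)
  expect_equal(res$rate_ul_min, 6e-4, tolerance = 1e-12)
  # uniform v over N pixels: N * v * A * 60 s/min
  m2 <- matrix(TRUE, 3, 3)
  v2 <- matrix(2, 3, 3)
  expect_equal(pixel_flow_rate(v2, geom, m2)$rate_ul_min,
               9 * 2 * 10 * 6e-5, tolerance = 1e-12)
  expect_equal(pixel_flow_rate(matrix(0, 3, 3), geom, m2)$rate_ul_min, 0)
  expect_error(pixel_flow_rate(v2, geom, matrix(FALSE, 3, 3)), "empty")
})

test_that("paraboloid fit recovers exact Poiseuille input at any aperture", {
  sp <- phantom_spec(pump_rate_ul_min = 50)
  tr <- phantom_truth(sp)
  geom <- pixel_geometry(sp$lateral_step_um, sp$axial_pixel_um, sp$n_blood)
  mask <- vessel_mask(tr$mask)
  # with the true center and radius supplied, recovery is exact
  for (ra in c(0.4, 0.67, 1.0)) {
    res <- masked_flow_rate(tr$v_mm_s, mask, geom, ra = ra,
                            R_um = tr$R_um, center_px = sp$center)
    expect_equal(res$vmax_mm_s, tr$vmax_mm_s, tolerance = 1e-9)
    # analytic integral: vmax * pi R^2 / 2
    expect_equal(res$rate_ul_min, 50, tolerance = 1e-9)
  }
  # with mask-estimated geometry, recovery carries only pixelation error
  for (ra in c(0.67, 1.0)) {
    res <- masked_flow_rate(tr$v_mm_s, mask, geom, ra = ra)
    expect_equal(res$vmax_mm_s, tr$vmax_mm_s, tolerance = 2e-2)
    expect_equal(res$rate_ul_min, 50, tolerance = 2e-2)
  }
  # aperture invariance within 1% for noise-free paraboloid input
  r1 <- masked_flow_rate(tr$v_mm_s, mask, geom, ra = 0.4)$rate_ul_min
  r2 <- masked_flow_rate(tr$v_mm_s, mask, geom, ra = 1.0)$rate_ul_min
  expect_lt(abs(r1 - r2) / r2, 0.01)
  expect_equal(masked_flow_rate(matrix(0, 100, 60), mask, geom)$rate_ul_min, 0)
  tiny <- vessel_mask(tr$mask & (tr$geometry$r_um < 10))
  expect_error(masked_flow_rate(tr$v_mm_s, tiny, geom, ra = 0.1), "fewer")
})

test_that("flow rate scales linearly with velocity", {
  sp <- phantom_spec(pump_rate_ul_min = 20)
  tr <- phantom_truth(sp)
  geom <- pixel_geometry(sp$lateral_step_um, sp$axial_pixel_um, sp$n_blood)
  mask <- vessel_mask(tr$mask)
  r1 <- masked_flow_rate(tr$v_mm_s, mask, geom)$rate_ul_min
  r3 <- masked_flow_rate(3 * tr$v_mm_s, mask, geom)$rate_ul_min
  expect_equal(r3, 3 * r1, tolerance = 1e-10)
})

test_that("calibration divides once and only once", {
  sp <- phantom_spec(pump_rate_ul_min = 50)
  tr <- phantom_truth(sp)
  geom <- pixel_geometry(sp$lateral_step_um, sp$axial_pixel_um, sp$n_blood)
  res <- masked_flow_rate(tr$v_mm_s, vessel_mask(tr$mask), geom)
  same <- apply_calibration(res, calibration_constant(1))
  expect_equal(same$rate_ul_min, res$rate_ul_min)
  cal <- apply_calibration(res, calibration_constant(3.18))
  expect_equal(cal$rate_ul_min, res$rate_ul_min / 3.18)
  expect_true(cal$calibrated)
  expect_error(apply_calibration(cal, calibration_constant(3.18)),
               "already")
  expect_error(calibration_constant(0))
})

test_that("scale estimation recovers known proportionality", {
  ref <- c(1, 2, 5, 10, 20)
  expect_equal(calibrate_scale(ref, ref)$scale, 1.0, tolerance = 1e-12)
  expect_equal(calibrate_scale(3.2 * ref, ref)$scale, 3.2, tolerance = 1e-12)
  set.seed(5)
  nn <- 2.5 * ref * exp(rnorm(5, 0, 0.02))
  expect_equal(calibrate_scale(nn, ref)$scale, 2.5, tolerance = 0.1)
  expect_error(calibrate_scale(c(1, -2), c(1, 2)), "positive")
  expect_error(calibrate_scale(1:3, 1:4))
})

test_that("angle-dependence fit recovers constructed parabolas", {
  a <- seq(80, 100, by = 2.5)
  flat <- angle_dependence_fit(a, rep(7, length(a)))
  expect_equal(flat$C0, 7, tolerance = 1e-9)
  expect_equal(flat$C1, 0, tolerance = 1e-9)
  expect_equal(flat$C2, 0, tolerance = 1e-9)
  y <- 2 + 0.5 * (a - 90)^2
  fit <- angle_dependence_fit(a, y)
  expect_equal(fit$C0, 2, tolerance = 1e-9)
  expect_equal(fit$C2, 0.5, tolerance = 1e-9)
  expect_equal(fit$ratio, 0.25, tolerance = 1e-9)
  expect_error(angle_dependence_fit(c(80, 90), c(1, 2)), "at least 3")
  td <- tidy(fit); gl <- glance(fit)
  expect_identical(td$term, c("C0", "C1", "C2"))
  expect_equal(gl$ratio, 0.25, tolerance = 1e-9)
})

test_that("coefficient of variation has the hand-computed value", {
  expect_equal(coefficient_of_variation(rep(4, 10)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2)
  expect_error(coefficient_of_variation(numeric(0)), "empty")
})

test_that("bifurcation balance report", {
  rep_a <- c(10, 10.4, 9.6)
  bal <- bifurcation_balance(rep_a, list(c(6, 6.1, 5.9), c(4, 3.9, 4.1)))
  expect_equal(bal$imbalance, 0, tolerance = 1e-12)
  bal2 <- bifurcation_balance(10, list(4, 4))
  expect_equal(bal2$imbalance, 0.2, tolerance = 1e-12)
  expect_error(bifurcation_balance(0, list(1, 2)), "zero")
  expect_identical(nrow(tidy(bal)), 3L)
  expect_equal(glance(bal)$outflow_ul_min, 10, tolerance = 1e-12)
})

test_that("power-law fit on exact and noisy synthetic data", {
  d <- c(40, 60, 80, 100, 120)
  q <- 1e-3 * d^2.58
  fit <- power_law_fit(d, q)
  expect_equal(fit$slope, 2.58, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_error(power_law_fit(100, 5), "at least 2")
  expect_error(power_law_fit(c(40, -60), c(1, 2)), "positive")
  set.seed(6)
  dd <- exp(runif(40, log(36), log(120)))
  qq <- 1e-3 * dd^2.58 * exp(rnorm(40, 0, 0.3))
  nf <- power_law_fit(dd, qq)
  se <- tidy(nf)$std.error[2]
  expect_lt(abs(nf$slope - 2.58), 3 * se)
})
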