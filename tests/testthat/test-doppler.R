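test_that("phase-difference image counts follow n_samples - d", {
  ph <- small_phantom(alpha = 85, rate = 5)
  stack <- phase_difference_stack(ph$scan, doppler_config(delays = c(1, 3, 40)))
  expect_identical(stack$n_images, c(127L, 125L, 88L))
  expect_identical(dim(stack$lag[[1]])[3], 127L)
  expect_identical(dim(stack$lag[[3]])[3], 88L)
  # identity holds for any n_samples
  sc <- ph$scan
  sc$data <- sc$data[, , 1:16]
  st2 <- phase_difference_stack(sc, doppler_config(delays = 1:5))
  expect_identical(st2$n_images, 16L - 1:5)
  expect_error(phase_difference_stack(sc, doppler_config(delays = 16)),
               "smaller")
  sc$data <- Mod(sc$data)
  expect_error(phase_difference_stack(sc, doppler_config(delays = 1)),
               "complex")
})

test_that("bulk-motion correction removes a per-A-scan static offset", {
  ph <- small_phantom(alpha = 85, rate = 5, snr = Inf)
  truth <- ph$truth
  scan <- ph$scan
  nx <- dim(scan$data)[1]
  # inject a known per-location phase offset on every sample after the first
  beta <- seq(-0.4, 0.4, length.out = nx)
  for (tt in 2:dim(scan$data)[3])
    scan$data[, , tt] <- scan$data[, , tt] * exp(1i * beta)
  cfg <- doppler_config(delays = 1L)
  stack <- phase_difference_stack(scan, cfg)
  static <- !truth$mask
  corr <- bulk_motion_correct(stack, static, cfg = cfg)
  img <- Arg(apply(corr$lag[[1]], c(1, 2), sum))
  expect_lt(max(abs(img[static])), 1e-6)
  # zero image stays zero
  z <- stack
  z$lag[[1]][] <- 1 + 0i
  zc <- bulk_motion_correct(z, static, cfg = cfg)
  expect_lt(max(abs(Arg(zc$lag[[1]]))), 1e-12)
  expect_error(bulk_motion_correct(stack, matrix(FALSE, nx, dim(scan$data)[2]),
                                   cfg = cfg), "static")
})

test_that("bulk-motion correction reduces lumen phase error under jitter", {
  ph_j <- small_phantom(alpha = 83, rate = 8, snr = Inf, jitter = 0.3,
                        seed = 6L)
  cfg <- doppler_config(delays = 1L)
  stack <- phase_difference_stack(ph_j$scan, cfg)
  static <- !ph_j$truth$mask
  rmse_of <- function(st) {
    img <- Arg(apply(st$lag[[1]], c(1, 2), sum))
    sqrt(mean((img[ph_j$truth$mask] -
               ph_j$truth$dphi_rad[ph_j$truth$mask])^2))
  }
  expect_lt(rmse_of(bulk_motion_correct(stack, static, cfg = cfg)),
            rmse_of(stack))
})

test_that("2D unwrapping recovers a wrapped plane and leaves smooth images alone", {
  x <- outer(seq(0, 6 * pi, length.out = 40), rep(1, 30))
  wrapped <- Arg(exp(1i * x))
  un <- unwrap_phase_2d(wrapped)
  un <- un - (un[1, 1] - x[1, 1])
  expect_equal(un, x, tolerance = 1e-9, ignore_attr = TRUE)
  smooth <- outer(seq(0, 2, length.out = 40), seq(0, 1, length.out = 30))
  expect_equal(unwrap_phase_2d(smooth), smooth, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(discontinuity_fraction(un), 0)
})

test_that("corrupted-image rejection drops only the noisy image", {
  set.seed(8)
  clean <- list(outer(1:20, 1:20, "+") * 0.001,
                matrix(0, 20, 20),
                matrix(runif(400, -40, 40), 20, 20))  # saturated noise
  res <- reject_corrupted(clean, doppler_config())
  expect_identical(res$keep, c(TRUE, TRUE, FALSE))
  expect_identical(res$excluded, 1L)
  expect_error(reject_corrupted(clean[3], doppler_config()), "rejected")
})

test_that("delay scaling and averaging is exact for constant velocity", {
  dphi1 <- 0.37
  delays <- c(1L, 4L, 9L)
  imgs <- lapply(delays, function(d) matrix(dphi1 * d, 8, 8))
  out <- average_and_scale(imgs, delays)
  expect_equal(out, matrix(dphi1, 8, 8), tolerance = 1e-14)
  expect_equal(average_and_scale(imgs[2], delays[2]),
               matrix(dphi1, 8, 8), tolerance = 1e-14)
  expect_error(average_and_scale(imgs, delays[1:2]))
})

test_that("averaging across delays reduces noise below single-delay level", {
  set.seed(99)
  dphi1 <- 0.2
  delays <- 1:8
  n_rep <- 200
  single <- numeric(n_rep); multi <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    imgs <- lapply(delays, function(d)
      matrix(dphi1 * d + rnorm(16, 0, 0.3), 4, 4))
    single[r] <- mean(imgs[[1]])
    multi[r] <- mean(average_and_scale(imgs, delays))
  }
  expect_lt(sd(multi), sd(single))
})

test_that("velocity conversion matches the closed form and rejects ~90 deg", {
  cfg <- doppler_config()
  # hand evaluation: pi * 1040e-9 / (4 pi * 1.36 * 1e-5 * cos(80 deg)) m/s
  v <- doppler_velocity(pi, 80, cfg)
  expect_equal(v$v_mm_s, 110.0942, tolerance = 1e-5)
  expect_equal(doppler_velocity(0, 80, cfg)$v_mm_s, 0)
  expect_error(doppler_velocity(pi, 90, cfg), "rejected")
  expect_error(doppler_velocity(pi, 88, cfg), "rejected")
  expect_error(doppler_velocity(pi, 92, cfg), "rejected")
  expect_silent(doppler_velocity(pi, 92.1, cfg))
})

test_that("Doppler angle from paired-location depth shift", {
  expect_equal(doppler_angle_from_depth_shift(100, 100, 200), 90)
  expect_equal(doppler_angle_from_depth_shift(0, 200, 200), 135)
  expect_equal(doppler_angle_from_depth_shift(0, 17.6, 200),
               90 + atan(0.088) * 180 / pi)
  expect_error(doppler_angle_from_depth_shift(0, 1, 0))
})
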