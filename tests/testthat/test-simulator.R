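test_that("static scatterers give a constant series and moving ones decorrelate", {
  set.seed(11)
  s0 <- simulate_field(0, n = 5)
  expect_equal(apply(s0$intensity, 1, sd), rep(0, 5), tolerance = 1e-12)

  # v tau >> beam diameter: successive samples are independent speckle draws
  set.seed(12)
  fast <- simulate_field(5000, n = 1200)
  I <- fast$intensity
  Ic <- I - rowMeans(I)
  lag1 <- mean(rowSums(Ic[, -1] * Ic[, -128]) / rowSums(Ic^2))
  expect_lt(abs(lag1), 0.05)
})

test_that("ensemble-mean intensity matches the closed form and is velocity-invariant", {
  ibar <- ensemble_mean_intensity()
  expect_equal(ibar, (2 / 9) * 9 * sqrt(pi / 2))
  set.seed(21)
  m_slow <- mean(simulate_field(5, n = 1500)$intensity)
  m_fast <- mean(simulate_field(200, n = 1500)$intensity)
  # Monte-Carlo standard error of the mean intensity at contrast ~ 1
  se <- ibar / sqrt(1500)
  expect_lt(abs(m_slow - ibar), 3 * se * sqrt(128 / 16))  # samples correlated in t
  expect_lt(abs(m_fast - ibar), 3 * se)
  expect_lt(abs(m_slow - m_fast), 4 * se * sqrt(128 / 16))
})

test_that("intensity decorrelation time decreases with velocity", {
  decorr_halflag <- function(v, seed) {
    set.seed(seed)
    I <- simulate_field(v, n = 1000)$intensity
    Ic <- I - rowMeans(I)
    ac <- vapply(1:40, function(d)
      mean(rowSums(Ic[, -(1:d), drop = FALSE] *
                   Ic[, 1:(128 - d), drop = FALSE]) / rowSums(Ic^2)),
      numeric(1))
    which(ac < 0.5)[1]
  }
  lags <- vapply(seq_along(c(10, 25, 60, 150, 400)), function(i)
    decorr_halflag(c(10, 25, 60, 150, 400)[i], 100 + i), numeric(1))
  expect_true(all(diff(lags) <= 0))
})

test_that("shot noise hits the requested SNR within 0.2 dB", {
  set.seed(31)
  clean <- simulate_field(50, n = 10000)
  noisy <- add_shot_noise(clean, 15)
  sigma2_emp <- mean(Mod(noisy$field - clean$field)^2)
  ibar_emp <- mean(clean$intensity)
  snr_est <- 10 * log10(ibar_emp / sigma2_emp)
  expect_lt(abs(snr_est - 15), 0.2)

  # 0 dB: injected noise variance equals the ensemble-mean signal intensity
  set.seed(32)
  clean0 <- simulate_field(50, n = 5000)
  noisy0 <- add_shot_noise(clean0, 0)
  sigma2_0 <- mean(Mod(noisy0$field - clean0$field)^2)
  expect_equal(sigma2_0, ensemble_mean_intensity(), tolerance = 0.05)

  # Inf sentinel: unchanged
  expect_identical(add_shot_noise(clean, Inf)$field, clean$field)
  expect_error(add_shot_noise(noisy, 20))  # double noising
})

test_that("self-normalization yields unity mean, is idempotent, rejects zeros", {
  expect_equal(self_normalize(rep(3.7, 128)), rep(1, 128))
  set.seed(41)
  x <- matrix(rexp(5 * 128), 5)
  nx <- self_normalize(x)
  expect_equal(rowMeans(nx), rep(1, 5), tolerance = 1e-12)
  expect_equal(self_normalize(nx), nx)
  expect_error(self_normalize(rep(0, 128)))
})

test_that("library accounting and determinism", {
  full <- library_spec(velocity_grid(64, 0.001, 2000), 5:35,
                       realizations = 25000L, n_train = 22000L,
                       n_val = 3000L)
  expect_identical(library_size(full), 64 * 31 * 25000)
  expect_identical(library_size(full), 49.6e6)
  expect_equal(full$n_train + full$n_val, 25000)

  g <- velocity_grid(2, 10, 100)
  spec <- library_spec(g, c(15, 20), realizations = 10L, n_train = 8L,
                       n_val = 2L, seed = 5L)
  lib1 <- build_library(spec)
  lib2 <- build_library(spec)
  expect_identical(lib1$intensity, lib2$intensity)
  expect_identical(nrow(lib1$intensity), 2L * 2L * 10L)
  expect_equal(sum(lib1$is_train), 2 * 2 * 8)
  expect_equal(rowMeans(lib1$intensity), rep(1, 40), tolerance = 1e-12)

  sl <- library_slice(lib1, 15)
  expect_true(all(sl$snr_label == 15))
  expect_error(library_slice(lib1, 12))
  expect_error(library_spec(g, c(20, 15)))                 # not increasing
  expect_error(library_spec(g, 15, realizations = 5L,
                            n_train = 4L, n_val = 2L))     # split too large
})
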