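test_that("velocity grid endpoints and geometric spacing are exact", {
  g <- velocity_grid(64, 0.001, 2000)
  expect_length(g, 64)
  expect_identical(g[1], 0.001)
  expect_identical(g[64], 2000)
  ratios <- g[-1] / g[-64]
  # closed form: (2e6)^(1/63)
  expect_equal(unique(round(ratios, 10)), round((2e6)^(1 / 63), 10))
  expect_equal(ratios[1], 1.2590, tolerance = 1e-4)

  expect_equal(as.numeric(velocity_grid(2, 1, 10)), c(1, 10))
})

test_that("invalid grids are rejected", {
  expect_error(velocity_grid(1, 1, 10))
  expect_error(velocity_grid(10, -1, 10))
  expect_error(velocity_grid(10, 5, 5))
  expect_error(velocity_grid(10, 10, 5))
})

test_that("nearest class is nearest in log velocity", {
  g <- velocity_grid(5, 1, 16)  # 1, 2, 4, 8, 16
  expect_equal(nearest_class(g, c(1, 16, 2.7, 2.9)), c(1L, 5L, 2L, 3L))
})
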