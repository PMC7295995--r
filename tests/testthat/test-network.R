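test_that("parameter count matches an independent hand count of the layer shapes", {
  arch <- network_architecture()
  # valid convolution: 128 kernels x (32 weights + 1 bias)
  # conv output 128 - 32 + 1 = 97 positions; pool length/stride 4 -> 24;
  # flatten 24 * 128 = 3072; FC 3072->1024->256->64 with biases
  hand <- 128 * (32 + 1) +
    (3072 * 1024 + 1024) + (1024 * 256 + 256) + (256 * 64 + 64)
  expect_equal(n_parameters(arch), hand)
  expect_equal(hand, 3429824)
  expect_identical(arch$conv_out, 97L)
  expect_identical(arch$pool_out, 24L)
})

test_that("network outputs are valid likelihood curves and init is deterministic", {
  arch <- network_architecture(n_classes = 8L)
  n1 <- build_network(arch, seed = 3)
  n2 <- build_network(arch, seed = 3)
  expect_identical(n1$Wc, n2$Wc)
  expect_identical(n1$W1, n2$W1)
  set.seed(9)
  X <- matrix(rexp(10 * 128), 10)
  X <- self_normalize(X)
  p <- predict_likelihood(n1, X)
  expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-9)
  expect_true(all(p >= 0))
  expect_error(predict_likelihood(n1, matrix(1, 2, 64)), "length")
})

test_that("compiled passes agree with the pure-R reference implementation", {
  arch <- network_architecture(n_classes = 6L)
  net <- build_network(arch, seed = 5)
  set.seed(10)
  X <- self_normalize(matrix(rexp(32 * 128), 32))
  y <- sample.int(6, 32, replace = TRUE)
  Y <- matrix(0, 32, 6); Y[cbind(1:32, y)] <- 1
  fw <- octflow:::.nn_forward(net, X, keep = TRUE)
  gr <- octflow:::.nn_backward(net, fw, Y)
  gc <- octflow:::.nn_batch_grad_cpp(X, Y, net$Wc, net$bc, net$W1, net$b1,
                                     net$W2, net$b2, net$W3, net$b3, 4L, 4L)
  pc <- octflow:::.nn_predict_cpp(X, net$Wc, net$bc, net$W1, net$b1,
                                  net$W2, net$b2, net$W3, net$b3, 4L, 4L)
  expect_equal(fw$probs, pc, tolerance = 1e-12)
  for (nm in c("Wc", "bc", "W1", "b1", "W2", "b2", "W3", "b3"))
    expect_equal(gr[[nm]], gc[[nm]], tolerance = 1e-10,
                 ignore_attr = TRUE)
})

test_that("training learns to separate well-spaced velocity classes", {
  g <- velocity_grid(4, 8, 200)
  spec <- library_spec(g, 15, realizations = 200L, n_train = 170L,
                       n_val = 30L, seed = 77L)
  lib <- build_library(spec)
  cfg <- training_config(epochs = 10L, seed = 2L, patience = Inf)
  net <- train_network(library_slice(lib, 15), cfg)
  acc <- tail(net$history$val_accuracy, 1)
  expect_gt(acc, 0.5)  # chance = 0.25
  expect_true(net$trained)
  expect_identical(nrow(net$history), 10L)
})

test_that("training requires normalized records and a single-SNR slice", {
  g <- velocity_grid(2, 10, 100)
  spec <- library_spec(g, c(10, 20), realizations = 10L, n_train = 8L,
                       n_val = 2L, seed = 1L)
  lib_raw <- build_library(spec, normalize = FALSE)
  expect_error(train_network(library_slice(lib_raw, 10)), "normaliz")
  lib <- build_library(spec)
  expect_error(train_network(lib), "one SNR")
})

test_that("single-class training collapses onto that class", {
  g <- velocity_grid(2, 10, 100)
  spec <- library_spec(g, 15, realizations = 60L, n_train = 50L,
                       n_val = 10L, seed = 2L)
  lib <- build_library(spec)
  keep <- lib$velocity_label == 1L
  lib$intensity <- lib$intensity[keep, , drop = FALSE]
  lib$velocity_label <- lib$velocity_label[keep]
  lib$snr_label <- lib$snr_label[keep]
  lib$is_train <- lib$is_train[keep]
  net <- train_network(lib, training_config(epochs = 3L, seed = 1L,
                                            patience = Inf))
  preds <- classify_records(net, lib$intensity[!lib$is_train, , drop = FALSE])
  expect_true(all(preds == 1L))
})

test_that("bank selection picks the nearest SNR, clamps, and flags low SNR", {
  arch <- network_architecture(n_classes = 4L)
  nets <- list("10" = build_network(arch, 1), "15" = build_network(arch, 2),
               "20" = build_network(arch, 3))
  for (nm in names(nets)) { nets[[nm]]$snr_db <- as.numeric(nm) }
  bank <- structure(list(nets = nets, snr_levels_db = c(10, 15, 20),
                         grid = velocity_grid(4, 8, 200), spec = NULL),
                    class = "network_bank")
  expect_equal(attr(select_network(bank, 15.4), "snr_used"), 15)
  expect_equal(attr(select_network(bank, 12.5), "snr_used"), 10)  # tie: lower
  expect_warning(sel <- select_network(bank, 50), "clamped")
  expect_equal(attr(sel, "snr_used"), 20)
  expect_warning(sel_lo <- select_network(bank, 2), "clamped")
  expect_true(attr(sel_lo, "unreliable"))
  x <- self_normalize(matrix(rexp(128), 1))
  p <- infer_likelihood(x, bank, 15.4)
  expect_equal(attr(p, "snr_used"), 15)
  expect_equal(rowSums(p), 1, tolerance = 1e-9)
})

test_that("bank serialization round-trips predictions", {
  g <- velocity_grid(2, 10, 100)
  spec <- library_spec(g, c(15, 20), realizations = 20L, n_train = 16L,
                       n_val = 4L, seed = 4L)
  lib <- build_library(spec)
  bank <- train_bank(lib, training_config(epochs = 2L, seed = 1L,
                                          patience = Inf))
  expect_length(bank$nets, 2)
  dir <- tempfile("bank")
  save_bank(bank, dir)
  bank2 <- load_bank(dir)
  probe <- self_normalize(matrix(rexp(6 * 128), 6))
  expect_identical(infer_likelihood(probe, bank, 15),
                   infer_likelihood(probe, bank2, 15))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  unlink(dir, recursive = TRUE)
})
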