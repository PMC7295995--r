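#' Architecture of the 1D convolutional velocity classifier
#'
#' A single convolutional layer (128 one-dimensional kernels of length 32,
#' valid convolution, no padding), ReLU, max pooling of length 4 and stride 4,
#' then three cascaded fully connected layers (1024, 256, and one node per
#' velocity class) with a softmax output. With a 128-sample input the
#' convolution yields 97 positions and pooling 24, giving a 3072-long feature
#' vector.
#'
#' @param input_len Samples per input record (128).
#' @param conv_kernels Number of convolution kernels (128).
#' @param kernel_len Kernel length in samples (32).
#' @param pool_len,pool_stride Max-pooling window and stride (4, 4).
#' @param fc_sizes Sizes of the first two fully connected layers (1024, 256).
#' @param n_classes Output classes; must equal the velocity-grid size.
#' @return A `network_architecture` list with derived sizes `conv_out`,
#'   `pool_out` and `flat`.
#' @export
network_architecture <- function(input_len = 128L, conv_kernels = 128L,
                                 kernel_len = 32L, pool_len = 4L,
                                 pool_stride = 4L, fc_sizes = c(1024L, 256L),
                                 n_classes = 64L) {
  conv_out <- input_len - kernel_len + 1L
  if (conv_out < pool_len) stop("kernel too long for input")
  pool_out <- (conv_out - pool_len) %/% pool_stride + 1L
  structure(list(input_len = as.integer(input_len),
                 conv_kernels = as.integer(conv_kernels),
                 kernel_len = as.integer(kernel_len),
                 pool_len = as.integer(pool_len),
                 pool_stride = as.integer(pool_stride),
                 fc_sizes = as.integer(fc_sizes),
                 n_classes = as.integer(n_classes),
                 conv_out = as.integer(conv_out),
                 pool_out = as.integer(pool_out),
                 flat = as.integer(pool_out * conv_kernels)),
            class = "network_architecture")
}

#' Trainable parameter count of an architecture
#'
#' @param arch A [network_architecture()].
#' @return Total number of weights and biases.
#' @export
n_parameters <- function(arch) {
  stopifnot(inherits(arch, "network_architecture"))
  sizes <- c(arch$flat, arch$fc_sizes, arch$n_classes)
  conv <- arch$conv_kernels * (arch$kernel_len + 1L)
  fc <- sum(sizes[-length(sizes)] * sizes[-1] + sizes[-1])
  conv + fc
}

#' Initialize a velocity-classification network
#'
#' He-initialized weights; deterministic for a fixed seed.
#'
#' @param arch A [network_architecture()].
#' @param seed Integer seed for weight initialization.
#' @return An `oct_net` object holding weight matrices and the architecture.
#' @export
build_network <- function(arch = network_architecture(), seed = 1L) {
  stopifnot(inherits(arch, "network_architecture"))
  set.seed(seed)
  he <- function(nr, nc, fan_in) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  sizes <- c(arch$flat, arch$fc_sizes, arch$n_classes)
  net <- list(
    arch = arch, seed = as.integer(seed),
    Wc = he(arch$kernel_len, arch$conv_kernels, arch$kernel_len),
    bc = numeric(arch$conv_kernels),
    W1 = he(sizes[1], sizes[2], sizes[1]), b1 = numeric(sizes[2]),
    W2 = he(sizes[2], sizes[3], sizes[2]), b2 = numeric(sizes[3]),
    W3 = he(sizes[3], sizes[4], sizes[3]), b3 = numeric(sizes[4]),
    snr_db = NA_real_, grid = NULL, trained = FALSE)
  class(net) <- "oct_net"
  net
}

#' @export
print.oct_net <- function(x, ...) {
  cat(sprintf("<oct_net> %d-sample input -> %d classes, %s parameters%s\n",
              x$arch$input_len, x$arch$n_classes,
              format(n_parameters(x$arch), big.mark = ","),
              if (x$trained) sprintf(" (trained, SNR %s dB)", x$snr_db) else " (untrained)"))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Pure-R reference implementation of the forward and backward passes. The
# compiled passes in src/nn.cpp are the production path; these are retained as
# an independent reference for numerical cross-checking.
# ---------------------------------------------------------------------------

# im2col gather indices: column (p-1)*kernel_len + w maps to input sample p+w-1
.im2col_idx <- function(arch) {
  as.vector(vapply(seq_len(arch$conv_out),
                   function(p) p:(p + arch$kernel_len - 1L),
                   integer(arch$kernel_len)))
}

# row selectors for pooling: for phase j, rows (b, p) with p = j, j+stride, ...
.pool_rows <- function(arch, B) {
  p0 <- (seq_len(arch$pool_out) - 1L) * arch$pool_stride
  lapply(seq_len(arch$pool_len), function(j)
    as.vector(outer(seq_len(B), (p0 + j - 1L) * B, "+")))
}

.add_bias <- function(M, b) M + rep(b, each = nrow(M))

# Forward pass. X: B x input_len matrix of self-normalized intensities.
# Returns softmax probabilities; with keep = TRUE also all intermediates.
.nn_forward <- function(net, X, keep = FALSE) {
  a <- net$arch
  B <- nrow(X)
  Xc <- X[, .im2col_idx(a), drop = FALSE]
  dim(Xc) <- c(B, a$kernel_len, a$conv_out)
  M <- aperm(Xc, c(1, 3, 2))
  dim(M) <- c(B * a$conv_out, a$kernel_len)
  Z <- .add_bias(M %*% net$Wc, net$bc)      # (B*conv_out) x kernels
  A <- Z; A[A < 0] <- 0
  rows <- .pool_rows(a, B)
  cand <- lapply(rows, function(r) A[r, , drop = FALSE])
  P <- cand[[1]]
  for (j in 2:a$pool_len) P <- pmax(P, cand[[j]])
  Fm <- P
  dim(Fm) <- c(B, a$flat)
  H1 <- .add_bias(Fm %*% net$W1, net$b1); H1[H1 < 0] <- 0
  H2 <- .add_bias(H1 %*% net$W2, net$b2); H2[H2 < 0] <- 0
  O <- .add_bias(H2 %*% net$W3, net$b3)
  O <- O - apply(O, 1, max)
  E <- exp(O)
  probs <- E / rowSums(E)
  if (!keep) return(probs)
  list(probs = probs, M = M, A = A, P = P, cand = cand, rows = rows,
       Fm = Fm, H1 = H1, H2 = H2, B = B)
}

# Backward pass; Y is a B x n_classes one-hot matrix. Returns gradients.
# Pool-gradient routing: gradient flows to the candidates equal to the window
# max. Exact ties at nonzero activations have probability zero; ties at zero
# are removed by the ReLU mask, so no explicit tie bookkeeping is needed.
.nn_backward <- function(net, fw, Y) {
  a <- net$arch
  B <- fw$B
  K <- a$conv_kernels
  dO <- (fw$probs - Y) / B
  gW3 <- crossprod(fw$H2, dO); gb3 <- colSums(dO)
  dH2 <- tcrossprod(dO, net$W3); dH2[fw$H2 <= 0] <- 0
  gW2 <- crossprod(fw$H1, dH2); gb2 <- colSums(dH2)
  dH1 <- tcrossprod(dH2, net$W2); dH1[fw$H1 <= 0] <- 0
  gW1 <- crossprod(fw$Fm, dH1); gb1 <- colSums(dH1)
  dP <- tcrossprod(dH1, net$W1)
  dim(dP) <- c(B * a$pool_out, K)
  dA <- matrix(0, B * a$conv_out, K)
  if (a$pool_stride == a$pool_len) {
    # non-overlapping windows: assemble by reshape instead of scatter
    G <- array(0, dim = c(B * a$pool_out, K, a$pool_len))
    for (j in seq_len(a$pool_len))
      G[, , j] <- dP * (fw$cand[[j]] == fw$P)
    dim(G) <- c(B, a$pool_out, K, a$pool_len)
    G <- aperm(G, c(1, 4, 2, 3))
    covered <- a$pool_out * a$pool_stride
    dim(G) <- c(B * covered, K)
    dA[seq_len(B * covered), ] <- G
  } else {
    for (j in seq_len(a$pool_len))
      dA[fw$rows[[j]], ] <- dA[fw$rows[[j]], ] + dP * (fw$cand[[j]] == fw$P)
  }
  dA[fw$A <= 0] <- 0
  gWc <- crossprod(fw$M, dA); gbc <- colSums(dA)
  list(Wc = gWc, bc = gbc, W1 = gW1, b1 = gb1,
       W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

#' Likelihood curves for a batch of normalized records
#'
#' Runs the forward pass of one network; each output row is a velocity
#' likelihood curve (softmax, nonnegative, sums to one).
#'
#' @param net An `oct_net`.
#' @param x Numeric matrix `[B x input_len]` of self-normalized intensity
#'   records, or a single record vector.
#' @return Matrix `[B x n_classes]` of class probabilities.
#' @export
predict_likelihood <- function(net, x) {
  stopifnot(inherits(net, "oct_net"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != net$arch$input_len)
    stop("record length ", ncol(x), " does not match network input length ",
         net$arch$input_len)
  .nn_predict_cpp(x, net$Wc, net$bc, net$W1, net$b1, net$W2, net$b2,
                  net$W3, net$b3, net$arch$pool_len, net$arch$pool_stride)
}

#' Training configuration
#'
#' Stochastic gradient descent with momentum; the full-scale configuration
#' trains for 200 epochs. `patience` enables early stopping when validation
#' accuracy has not improved by `min_delta` for that many epochs.
#'
#' @param epochs Maximum training epochs (full-scale value 200).
#' @param batch_size Mini-batch size.
#' @param lr Learning rate.
#' @param momentum Momentum coefficient.
#' @param seed Seed for shuffling (weights are seeded by [build_network()]).
#' @param patience Early-stopping patience in epochs (`Inf` disables).
#' @param min_delta Minimum validation-accuracy improvement counted as progress.
#' @return A `training_config` list.
#' @export
training_config <- function(epochs = 200L, batch_size = 128L, lr = 0.01,
                            momentum = 0.9, seed = 1L, patience = Inf,
                            min_delta = 0.002) {
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, momentum = momentum, seed = as.integer(seed),
                 patience = patience, min_delta = min_delta),
            class = "training_config")
}

#' Train one velocity classifier on a single-SNR library slice
#'
#' Cross-entropy loss, SGD with momentum. Records must be self-normalized
#' (unity mean); this is checked and violated input is an error, not silently
#' fixed. Validation accuracy is tracked on the slice's held-out records.
#'
#' @param lib_slice A `signal_library` restricted to one SNR
#'   (see [library_slice()]).
#' @param cfg A [training_config()].
#' @param arch A [network_architecture()]; `n_classes` must match the grid.
#' @param verbose Print per-epoch progress.
#' @return A trained `oct_net` with a `history` data frame (epoch, train
#'   loss, validation accuracy) and the grid and SNR recorded.
#' @export
train_network <- function(lib_slice, cfg = training_config(),
                          arch = NULL, verbose = FALSE) {
  stopifnot(inherits(lib_slice, "signal_library"))
  snrs <- unique(lib_slice$snr_label)
  if (length(snrs) != 1L) stop("training slice must hold exactly one SNR level")
  grid <- lib_slice$spec$grid
  if (is.null(arch))
    arch <- network_architecture(input_len = lib_slice$spec$timing$n_samples,
                                 n_classes = length(grid))
  if (arch$n_classes != length(grid))
    stop("architecture n_classes must match the velocity grid")
  X <- lib_slice$intensity
  if (max(abs(rowMeans(X) - 1)) > 1e-8)
    stop("library records are not self-normalized; train on normalized records")
  y <- lib_slice$velocity_label
  tr <- lib_slice$is_train
  Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
  Xva <- X[!tr, , drop = FALSE]; yva <- y[!tr]
  net <- build_network(arch, seed = cfg$seed)
  par_names <- c("Wc", "bc", "W1", "b1", "W2", "b2", "W3", "b3")
  # private deep copies: the in-place SGD kernel mutates weights and
  # momenta directly, so they must not be shared with any other binding
  wts <- lapply(net[par_names], function(w) w + 0)
  vel <- lapply(wts, function(w) w * 0)
  set.seed(cfg$seed + 1L)
  ntr <- nrow(Xtr)
  hist_loss <- numeric(0); hist_acc <- numeric(0)
  best_acc <- -Inf; stall <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(ntr)
    loss_sum <- 0
    for (start in seq(1L, ntr, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, ntr)]
      Xb <- Xtr[idx, , drop = FALSE]
      Yb <- matrix(0, length(idx), arch$n_classes)
      Yb[cbind(seq_along(idx), ytr[idx])] <- 1
      g <- .nn_batch_grad_cpp(Xb, Yb, wts$Wc, wts$bc, wts$W1, wts$b1,
                              wts$W2, wts$b2, wts$W3, wts$b3,
                              arch$pool_len, arch$pool_stride)
      loss_sum <- loss_sum + g$loss * length(idx)
      for (nm in par_names)
        .sgd_step_cpp(wts[[nm]], vel[[nm]], g[[nm]], cfg$momentum, cfg$lr)
    }
    acc <- if (nrow(Xva)) {
      pv <- max.col(.nn_predict_cpp(Xva, wts$Wc, wts$bc, wts$W1, wts$b1,
                                    wts$W2, wts$b2, wts$W3, wts$b3,
                                    arch$pool_len, arch$pool_stride),
                    ties.method = "first")
      mean(pv == yva)
    } else NA_real_
    hist_loss <- c(hist_loss, loss_sum / ntr); hist_acc <- c(hist_acc, acc)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val acc %.3f", ep,
                      loss_sum / ntr, acc))
    if (is.finite(cfg$patience) && !is.na(acc)) {
      if (acc > best_acc + cfg$min_delta) { best_acc <- acc; stall <- 0L }
      else { stall <- stall + 1L; if (stall >= cfg$patience) break }
    }
  }
  net[par_names] <- wts
  net$trained <- TRUE
  net$snr_db <- snrs
  net$grid <- grid
  net$history <- data.frame(epoch = seq_along(hist_loss),
                            train_loss = hist_loss, val_accuracy = hist_acc)
  net
}

#' Hard class assignments for a batch of records
#'
#' @param net A trained `oct_net`.
#' @param x Matrix of self-normalized records.
#' @return Integer class indices (argmax of the likelihood curve; ties break
#'   toward the lower velocity).
#' @export
classify_records <- function(net, x) {
  p <- predict_likelihood(net, x)
  max.col(p, ties.method = "first")
}

#' Train the SNR-stratified network bank
#'
#' One classifier per SNR level of the library; the full-scale configuration
#' yields 31 networks (5 to 35 dB). Each network is trained independently on
#' its own slice.
#'
#' @param lib A `signal_library` covering all configured SNR levels.
#' @param cfg A [training_config()].
#' @param verbose Print progress.
#' @return A `network_bank`: list of trained `oct_net`s keyed by
#'   `"<snr>"`, with the grid and library spec attached.
#' @export
train_bank <- function(lib, cfg = training_config(), verbose = FALSE) {
  stopifnot(inherits(lib, "signal_library"))
  levels <- lib$spec$snr_levels_db
  nets <- list()
  for (s in levels) {
    if (verbose) message("training network at ", s, " dB")
    nets[[as.character(s)]] <- train_network(library_slice(lib, s), cfg)
  }
  structure(list(nets = nets, snr_levels_db = levels,
                 grid = lib$spec$grid, spec = lib$spec),
            class = "network_bank")
}

#' @export
print.network_bank <- function(x, ...) {
  cat(sprintf("<network_bank> %d networks at SNR %s dB, %d velocity classes\n",
              length(x$nets), paste(x$snr_levels_db, collapse = ", "),
              length(x$grid)))
  invisible(x)
}

#' Select the bank network nearest to an estimated SNR
#'
#' Nearest trained SNR; ties break toward the lower SNR (conservative).
#' Estimates outside the trained range are clamped with a warning. Estimates
#' below the reliability floor (4 dB) are still evaluated at the lowest
#' trained SNR but flagged unreliable.
#'
#' @param bank A `network_bank`.
#' @param snr_est_db Estimated SNR of the measurement (dB).
#' @return The selected `oct_net`, with attributes `snr_used` and
#'   `unreliable`.
#' @export
select_network <- function(bank, snr_est_db) {
  stopifnot(inherits(bank, "network_bank"))
  if (length(bank$nets) == 0L) stop("empty network bank")
  lv <- bank$snr_levels_db
  unreliable <- snr_est_db < 4
  if (snr_est_db > max(lv) || snr_est_db < min(lv))
    warning(sprintf("SNR estimate %.1f dB outside trained range [%g, %g]; clamped",
                    snr_est_db, min(lv), max(lv)))
  d <- abs(lv - snr_est_db)
  k <- which(d == min(d))[1]  # ties: lower SNR first (lv is increasing)
  net <- bank$nets[[as.character(lv[k])]]
  attr(net, "snr_used") <- lv[k]
  attr(net, "unreliable") <- unreliable
  net
}

#' Velocity likelihood for measured records via the SNR-matched network
#'
#' @param x A self-normalized record (vector) or matrix of records.
#' @param bank A `network_bank`.
#' @param snr_est_db Estimated SNR in dB (one value for the batch).
#' @return Likelihood matrix `[B x n_classes]` with attributes `snr_used`
#'   and `unreliable`.
#' @export
infer_likelihood <- function(x, bank, snr_est_db) {
  net <- select_network(bank, snr_est_db)
  p <- predict_likelihood(net, x)
  attr(p, "snr_used") <- attr(net, "snr_used")
  attr(p, "unreliable") <- attr(net, "unreliable")
  p
}

#' Serialize / restore a network bank
#'
#' The bank is written as one weights file per SNR plus a JSON manifest
#' recording the architecture, velocity grid, seeds and SNR levels.
#'
#' @param bank A `network_bank`.
#' @param dir Directory to create.
#' @return `save_bank` returns `dir` invisibly; `load_bank` the restored bank.
#' @export
save_bank <- function(bank, dir) {
  stopifnot(inherits(bank, "network_bank"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arch <- bank$nets[[1]]$arch
  manifest <- list(schema = "octflow-bank/1",
                   snr_levels_db = bank$snr_levels_db,
                   grid = as.numeric(bank$grid),
                   architecture = unclass(arch)[c("input_len", "conv_kernels",
                                                  "kernel_len", "pool_len",
                                                  "pool_stride", "fc_sizes",
                                                  "n_classes")],
                   seeds = vapply(bank$nets, function(n) n$seed, integer(1)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(bank$nets))
    saveRDS(bank$nets[[nm]], file.path(dir, paste0("net_", nm, "dB.rds")))
  saveRDS(bank$spec, file.path(dir, "library_spec.rds"))
  invisible(dir)
}

#' @rdname save_bank
#' @export
load_bank <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$schema, "octflow-bank/1"))
    stop("not an octflow network bank: ", dir)
  levels <- as.numeric(manifest$snr_levels_db)
  nets <- lapply(as.character(levels), function(nm)
    readRDS(file.path(dir, paste0("net_", nm, "dB.rds"))))
  names(nets) <- as.character(levels)
  spec <- readRDS(file.path(dir, "library_spec.rds"))
  structure(list(nets = nets, snr_levels_db = levels,
                 grid = spec$grid, spec = spec),
            class = "network_bank")
}
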