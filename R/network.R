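#' Detector network configuration
#'
#' The feature extractor is a 21-convolution stack (3x3 and 1x1 filters,
#' same padding, batch normalization and leaky ReLU with slope
#' `leak_alpha` after every convolution) with five 2x2/stride-2 max-pooling
#' layers, so the input is downsampled by a factor of 32. A passthrough
#' connection takes the activated output of layer 13 (before its pooling),
#' reshapes it space-to-depth by 2 and concatenates it channel-wise into the
#' input of layer 21, preserving fine detail at the detection resolution.
#' Detection is a dropout layer (training only) followed by a single 1x1
#' convolution with 6 filters: per grid cell the channels are the box-center
#' offsets x, y, the box sizes w, h (relative to the anchor), the objectness
#' confidence, and a class score that is redundant for a single particle
#' class and ignored at decode time.
#'
#' The `reduced` flag selects a desk-scale variant with the identical
#' topology (pool positions, passthrough, head) but filter counts capped at
#' `filter_cap` and a smaller default input, trainable in minutes on a CPU.
#'
#' @param input_size Square input side length in pixels, divisible by 32.
#' @param reduced If `TRUE`, cap the filter schedule for CPU-scale use.
#' @param filter_cap Maximum filters per layer when `reduced`.
#' @param leak_alpha Negative slope of the leaky ReLU.
#' @param dropout_rate Dropout fraction before the detection convolution.
#' @return A list of class `network_config` including the per-layer filter
#'   schedule and kernel sizes.
#' @export
network_config <- function(input_size = if (reduced) 256L else 1024L,
                           reduced = FALSE, filter_cap = 32L,
                           leak_alpha = 0.1, dropout_rate = 0.2) {
  if (input_size %% 32 != 0) stop_cfg("input_size must be divisible by 32")
  filters <- c(32L, 64L, 128L, 64L, 128L, 256L, 128L, 256L, 512L, 256L,
               512L, 256L, 512L, 1024L, 512L, 1024L, 512L, 1024L, 1024L,
               1024L, 1024L)
  kernels <- c(3L, 3L, 3L, 1L, 3L, 3L, 1L, 3L, 3L, 1L, 3L, 1L, 3L, 3L, 1L,
               3L, 1L, 3L, 3L, 3L, 3L)
  pool_after <- seq_along(filters) %in% c(1L, 2L, 5L, 8L, 13L)
  if (reduced) filters <- pmin(filters, as.integer(filter_cap))
  if (any(filters <= 0) || length(filters) != 21L)
    stop_cfg("invalid filter schedule")
  structure(list(input_size = as.integer(input_size), reduced = reduced,
                 filters_per_layer = filters, kernels = kernels,
                 pool_after = pool_after, pass_from = 13L, pass_into = 21L,
                 leak_alpha = leak_alpha, dropout_rate = dropout_rate,
                 output_channels = 6L),
            class = "network_config")
}

# per-conv-layer input channel counts, including the passthrough concat
conv_in_channels <- function(cfg) {
  cin <- integer(21)
  cin[1] <- 1L
  for (i in 2:21) cin[i] <- cfg$filters_per_layer[i - 1]
  cin[cfg$pass_into] <- cin[cfg$pass_into] +
    4L * cfg$filters_per_layer[cfg$pass_from]
  cin
}

#' Build a randomly initialized detector
#'
#' Allocates He-initialized convolution weights (variance `2 / ((1 +
#' alpha^2) * fan_in)`, the correction appropriate for leaky-ReLU stacks),
#' unit batch-norm scales, and a detection head whose confidence and class
#' biases start at -2 so that the initial objectness prior is low. The
#' anchor (expected particle box size in input pixels) may be supplied now
#' or set later by [fit_detector()].
#'
#' @param cfg A [network_config()].
#' @param box_size Optional anchor side length in network-input pixels.
#' @param seed Seed for weight initialization.
#' @return A list of class `detector_model` with fields `cfg`, `weights`
#'   (21 convolution entries), `head`, `grid` (a [grid_spec()] or `NULL`),
#'   and `trained`.
#' @export
build_detector <- function(cfg = network_config(), box_size = NULL,
                           seed = 1) {
  cin <- conv_in_channels(cfg)
  with_seed(child_seed(seed, "init"), {
    weights <- vector("list", 21L)
    for (i in 1:21) {
      k <- cfg$kernels[i]
      fan_in <- k * k * cin[i]
      sdw <- sqrt(2 / ((1 + cfg$leak_alpha^2) * fan_in))
      nf <- cfg$filters_per_layer[i]
      weights[[i]] <- list(
        W = matrix(rnorm(fan_in * nf, 0, sdw), fan_in, nf),
        gamma = rep(1, nf), beta = rep(0, nf),
        rmean = rep(0, nf), rvar = rep(1, nf))
    }
    c21 <- cfg$filters_per_layer[21]
    head <- list(W = matrix(rnorm(c21 * 6, 0, 0.1 / sqrt(c21)), c21, 6),
                 b = c(0, 0, 0, 0, -2, -2))
    grid <- if (!is.null(box_size)) grid_spec(cfg$input_size, box_size)
            else NULL
    structure(list(cfg = cfg, weights = weights, head = head, grid = grid,
                   trained = FALSE), class = "detector_model")
  })
}

#' Per-layer metadata of a detector
#'
#' One row per layer in network order: the 21 feature convolutions, the max
#' pooling layers at their positions, the passthrough, the dropout layer and
#' the 1x1 detection convolution. Used for programmatic architecture audits.
#'
#' @param model A [build_detector()] model.
#' @return Data frame with columns `layer`, `kind`, `filters`, `kernel`.
#' @export
layer_census <- function(model) {
  cfg <- model$cfg
  rows <- list()
  add <- function(kind, filters = NA, kernel = NA)
    rows[[length(rows) + 1]] <<- data.frame(kind = kind, filters = filters,
                                            kernel = kernel)
  for (i in 1:21) {
    add("conv", cfg$filters_per_layer[i], cfg$kernels[i])
    if (i == cfg$pass_from) add("passthrough_source")
    if (cfg$pool_after[i]) add("maxpool")
  }
  add("dropout")
  add("conv", 6L, 1L)
  out <- do.call(rbind, rows)
  out$layer <- seq_len(nrow(out))
  out[, c("layer", "kind", "filters", "kernel")]
}

net_cfg_for_cpp <- function(cfg) {
  list(conv_k = cfg$kernels, pool_after = cfg$pool_after,
       pass_from = cfg$pass_from, pass_into = cfg$pass_into,
       leak_alpha = cfg$leak_alpha)
}

# logistic on x, y, confidence, class; exponential on w, h
apply_head_activations <- function(raw) {
  act <- raw
  sig <- function(z) 1 / (1 + exp(-z))
  act[, , 1, ] <- sig(raw[, , 1, ]); act[, , 2, ] <- sig(raw[, , 2, ])
  act[, , 5, ] <- sig(raw[, , 5, ]); act[, , 6, ] <- sig(raw[, , 6, ])
  act[, , 3, ] <- exp(raw[, , 3, ]); act[, , 4, ] <- exp(raw[, , 4, ])
  act
}

#' Run the detector forward
#'
#' Applies the network to a batch of normalized input patches and returns
#' activated prediction tensors: logistic activations keep the center
#' offsets and confidences in (0, 1) and an exponential keeps the sizes
#' positive (decoded size = anchor * exp(raw)). With `training = FALSE`
#' (the default) dropout is disabled and batch normalization uses its
#' running statistics, so the pass is deterministic.
#'
#' @param model A [build_detector()] model.
#' @param x A single `input_size` square matrix or a list of them.
#' @param training Use training-mode stochastic layers and batch statistics.
#' @return Array of shape S x S x 6 x batch.
#' @export
forward_detector <- function(model, x, training = FALSE) {
  if (is.matrix(x)) x <- list(x)
  insz <- model$cfg$input_size
  for (xm in x)
    if (nrow(xm) != insz || ncol(xm) != insz)
      stop_cfg("input patch shape must be ", insz, " x ", insz)
  res <- cpp_net_run(net_cfg_for_cpp(model$cfg), model$weights, model$head,
                     x, training, NULL, NULL, 0.9)
  raw <- res$out
  if (!all(is.finite(raw))) stop("non-finite network output")
  apply_head_activations(raw)
}

#' Save or load a detector checkpoint
#'
#' The checkpoint is a self-describing single-file container (R
#' serialization) holding the configuration, all weights, the grid spec and
#' the training flag; loading restores it bit-exactly.
#'
#' @param model A `detector_model`.
#' @param path Checkpoint file path.
#' @return `save_detector` returns `path` invisibly; `load_detector`
#'   returns the model.
#' @export
save_detector <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "detector_model"))
    stop_cfg(path, " is not a detector checkpoint")
  model
}
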