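#' Configure the coarse-output segmentation network
#'
#' The network is a stack of `n_blocks` convolution blocks. A block applies
#' two 3x3 convolutions (each followed by batch normalization), a
#' squeeze-and-excitation channel recalibration and an additive residual
#' path, with a ReLU closing the block. Between consecutive blocks a 2x2
#' stride-2 convolution followed by BN and ReLU halves the spatial
#' resolution and doubles the feature width, so the output grid is
#' `2^(n_blocks - 1)` times smaller than the input; a final 1x1 convolution
#' and per-pixel softmax produce the class probability maps. With the
#' defaults (6 blocks, 1024 px input) the output is 32x32 per patch.
#'
#' @param n_blocks Number of convolution blocks (default 6).
#' @param base_features Feature width of the first block; widths double per
#'   block (default 32).
#' @param se_ratio Squeeze-and-excitation bottleneck reduction (default 16).
#' @param input_size Expected square input size in pixels (default 1024).
#' @param n_classes Number of output classes (default 7).
#' @return An object of class `cribnet_netconfig`, including the derived
#'   `downsample_factor` and `output_size`.
#' @export
network_config <- function(n_blocks = 6L, base_features = 32L,
                           se_ratio = 16L, input_size = 1024L,
                           n_classes = 7L) {
  if (n_blocks < 1L) stop("n_blocks must be at least 1")
  if (base_features < 1L) stop("base_features must be positive")
  factor <- 2L^(n_blocks - 1L)
  if (input_size %% factor != 0L || input_size %/% factor < 1L) {
    stop("input size ", input_size, " is not divisible by the downsampling ",
         "factor 2^(n_blocks-1) = ", factor)
  }
  structure(
    list(n_blocks = as.integer(n_blocks),
         base_features = as.integer(base_features),
         se_ratio = as.integer(se_ratio),
         input_size = as.integer(input_size),
         n_classes = as.integer(n_classes),
         downsample_factor = factor,
         output_size = as.integer(input_size %/% factor)),
    class = "cribnet_netconfig")
}

#' Build a network with freshly initialized weights
#'
#' Weights are sampled from a fan-scaled uniform distribution
#' (Glorot-style) with a deterministic generator, so the same seed always
#' yields the same weights.
#'
#' @param config A [network_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `cribnet_network`.
#' @export
build_network <- function(config = network_config(), seed = 1L) {
  ptr <- cnet_create(config$n_blocks, config$base_features,
                     config$se_ratio, config$n_classes, as.double(seed))
  structure(list(ptr = ptr, config = config, seed = seed),
            class = "cribnet_network")
}

#' Run the network forward
#'
#' @param network A [build_network()] result.
#' @param x Numeric `(H, W, 3)` array or `(H, W, 3, N)` batch with values
#'   in `[0, 1]`; spatial dimensions must be divisible by the network's
#'   downsampling factor.
#' @param train Use batch statistics in the normalization layers (training
#'   mode). Inference (`FALSE`, default) is deterministic.
#' @return Probability array `(H', W', K)` (or `(H', W', K, N)` for a
#'   batch); per output pixel the class probabilities sum to 1.
#' @export
net_forward <- function(network, x, train = FALSE) {
  d <- dim(x)
  single <- length(d) == 3L
  if (single) dim(x) <- c(d, 1L)
  d <- dim(x)
  if (d[3] != 3L) stop("input must have 3 colour channels, got ", d[3])
  f <- network$config$downsample_factor
  if (d[1] %% f != 0L || d[2] %% f != 0L) {
    stop("input spatial size must be divisible by the downsampling factor ",
         f)
  }
  out <- cnet_forward(network$ptr, x, train)
  if (single) {
    dim(out) <- dim(out)[1:3]
  }
  out
}

#' One SGD step on a batch with the weighted soft Dice loss
#'
#' @param network A [build_network()] result.
#' @param x Batch `(H, W, 3, N)`.
#' @param y_pooled Block-averaged reference `(H', W', K, N)` on the output
#'   grid.
#' @param weights Per-class Dice weights.
#' @param eps Dice denominator stabiliser.
#' @param lr Learning rate.
#' @param momentum Momentum coefficient.
#' @param weight_decay L2 penalty added to the gradient (0 when the decay
#'   is applied to the learning rate instead).
#' @return The batch loss, invisibly.
#' @export
net_train_step <- function(network, x, y_pooled,
                           weights = label_set()$weights, eps = 1e-5,
                           lr = 0.01, momentum = 0.99, weight_decay = 0) {
  loss <- cnet_train_step(network$ptr, x, y_pooled, weights, eps, lr,
                          momentum, weight_decay)
  invisible(loss)
}

#' Number of trainable parameters
#' @param network A [build_network()] result.
#' @return Integer parameter count (BN running statistics excluded).
#' @export
n_parameters <- function(network) {
  as.integer(cnet_nparams(network$ptr))
}

#' Extract or restore network weights
#'
#' Weights are plain named numeric matrices/vectors, suitable for
#' checkpointing in R.
#'
#' @param network A [build_network()] result.
#' @return For `get_network_weights`, a named list of arrays.
#' @export
get_network_weights <- function(network) {
  cnet_get_weights(network$ptr)
}

#' @rdname get_network_weights
#' @param weights A list previously produced by `get_network_weights`.
#' @export
set_network_weights <- function(network, weights) {
  cnet_set_weights(network$ptr, weights)
  invisible(network)
}

#' @export
print.cribnet_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Segmentation network: %d blocks (features %s), SE ratio %d\n",
    cfg$n_blocks,
    paste(cfg$base_features * 2L^(seq_len(cfg$n_blocks) - 1L),
          collapse = "/"),
    cfg$se_ratio))
  cat(sprintf("  input %dx%d -> output %dx%dx%d  (%s parameters)\n",
              cfg$input_size, cfg$input_size, cfg$output_size,
              cfg$output_size, cfg$n_classes,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}
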