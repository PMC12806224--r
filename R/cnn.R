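#' Dilated residual CNN regressor baseline
#'
#' A non-attention baseline for protein-level regression: a kernel-9 input
#' convolution embedding the 25 amino-acid channels into 256 feature maps,
#' followed by 35 residual blocks (each two same-padded convolutions with 256
#' filters, kernel size 9, dilation rate 2, ReLU, identity skip), global
#' average pooling, and a scalar linear head. The default configuration has
#' about 41 million trainable parameters.
#'
#' @param n_blocks Number of residual blocks (default 35).
#' @param filters Feature maps per convolution (default 256).
#' @param kernel Kernel size (default 9).
#' @param dilation Dilation rate inside blocks (default 2).
#' @param in_channels Input channels: the 25 amino-acid codes (default 25).
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(n_blocks = 35L, filters = 256L, kernel = 9L,
                       dilation = 2L, in_channels = 25L) {
  cfg <- list(n_blocks = as.integer(n_blocks), filters = as.integer(filters),
              kernel = as.integer(kernel), dilation = as.integer(dilation),
              in_channels = as.integer(in_channels))
  class(cfg) <- "cnn_config"
  cfg
}

#' Build the CNN regressor
#'
#' @param config A [cnn_config()].
#' @param seed Integer seed for deterministic initialization.
#' @return Parameter tree of class `cnn_regressor`. Convolution weights are
#'   stored as (in_channels * kernel) x filters matrices (tap-major rows).
#' @export
build_cnn_regressor <- function(config = cnn_config(), seed = 1L) {
  rng <- .local_rng(seed)
  Fm <- config$filters; k <- config$kernel
  conv_init <- function(cin) {
    list(W = rng$mat(cin * k, Fm, sd = sqrt(2 / (cin * k))), b = numeric(Fm))
  }
  p <- list(
    embed = conv_init(config$in_channels),
    blocks = lapply(seq_len(config$n_blocks), function(i) {
      list(conv1 = conv_init(Fm), conv2 = conv_init(Fm))
    }),
    head = list(W = rng$mat(Fm, 1L, sd = 0.02), b = 0),
    config = config
  )
  class(p) <- "cnn_regressor"
  p
}

# same-padded 1-D convolution; X: L x Cin, W: (Cin*k) x Cout rows tap-major
.conv1d_same <- function(X, W, b, k, dilation = 1L) {
  L <- nrow(X); Cin <- ncol(X)
  center <- (k + 1L) %/% 2L
  Y <- matrix(rep(b, each = L), L, length(b))
  for (j in seq_len(k)) {
    off <- (j - center) * dilation
    Wj <- W[((j - 1L) * Cin + 1L):(j * Cin), , drop = FALSE]
    src_lo <- max(1L, 1L - off); src_hi <- min(L, L - off)
    if (src_lo > src_hi) next
    rows_out <- src_lo:src_hi
    rows_in <- rows_out + off
    Y[rows_out, ] <- Y[rows_out, ] + X[rows_in, , drop = FALSE] %*% Wj
  }
  Y
}

#' Run the CNN regressor on one sequence
#'
#' @param tokens A `token_seq` or character sequence; tokens are one-hot
#'   encoded over the 25 amino-acid channels (special tokens map to zero
#'   vectors).
#' @param params A `cnn_regressor` from [build_cnn_regressor()].
#' @return A single finite numeric prediction.
#' @export
cnn_forward <- function(tokens, params) {
  cfg <- params$config
  ids <- .as_token_ids(tokens, 28L)
  L <- length(ids)
  X <- matrix(0, L, cfg$in_channels)
  aa <- which(ids < cfg$in_channels)
  X[cbind(aa, ids[aa] + 1L)] <- 1
  H <- pmax(.conv1d_same(X, params$embed$W, params$embed$b, cfg$kernel), 0)
  for (blk in params$blocks) {
    A <- pmax(.conv1d_same(H, blk$conv1$W, blk$conv1$b, cfg$kernel,
                           cfg$dilation), 0)
    Bv <- .conv1d_same(A, blk$conv2$W, blk$conv2$b, cfg$kernel, cfg$dilation)
    H <- pmax(H + Bv, 0)
  }
  pooled <- colMeans(H)
  drop(pooled %*% params$head$W) + params$head$b
}
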