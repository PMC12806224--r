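# Internal neural-network primitives.
#
# Convention: activations are dense matrices with rows = positions and
# columns = features. Batched sequence tensors of logical shape (L, B, C) are
# stored as (L*B) x C matrices, column-major over (L, B), so `dim<-` reshapes
# between (L*B) x C and L x (B*C) views without copying semantics.
# All math is double precision; backward passes are hand-derived and verified
# against finite differences in the test suite.

.next_pow2 <- function(n) {
  p <- 1L
  while (p < n) p <- p * 2L
  p
}

# ---- causal FFT long convolution --------------------------------------------
# Linear causal convolution y[t] = sum_{j=0..t} h[j] v[t-j], realized by
# zero-padding to a highly composite length Lp >= 2L-1 so that circular
# convolution in the frequency domain equals the linear one. Never builds an
# L x L matrix. The transforms run in the compiled kernel (src/kernels.cpp),
# which transforms each shared filter once per channel and reduces the
# filter gradient over batch copies in the frequency domain.

# V: L x (B*C) with batch index fastest over columns; H: L x C.
# Returns y (L x B*C) plus the frequency-domain cache needed for backward.
.fft_conv_fwd <- function(V, H, B = 1L) {
  L <- nrow(V)
  stopifnot(ncol(V) == B * ncol(H))
  if (L == 1L) {
    # single tap: convolution reduces to an element-wise product
    He <- if (B == 1L) H else H[, rep(seq_len(ncol(H)), each = B), drop = FALSE]
    return(list(y = V * He, V1 = V, H1 = H, Lp = 1L, L = L, B = B,
                C = ncol(H)))
  }
  Lp <- stats::nextn(2L * L - 1L, c(2L, 3L, 5L))
  r <- .cpp_fftconv_fwd(V, H, as.integer(B), as.integer(Lp))
  list(y = r$y, Vf = r$Vf, Hf = r$Hf, Lp = Lp, L = L, B = B, C = ncol(H))
}

# dZ: L x (B*C) upstream gradient. Returns dV (L x B*C) and dH (L x C,
# reduced over the batch):
#   dV[s] = sum_j h[j] dz[s+j]   (correlation with h)
#   dH[j] = sum_t v[t] dz[t+j]   (correlation with v, summed over batch)
.fft_conv_bwd <- function(dZ, cache, need_dH = TRUE) {
  if (cache$L == 1L) {
    B <- cache$B; C <- cache$C
    He <- if (B == 1L) cache$H1 else
      cache$H1[, rep(seq_len(C), each = B), drop = FALSE]
    dH <- NULL
    if (need_dH) {
      S <- cache$V1 * dZ
      dH <- if (B == 1L) S else
        matrix(colSums(matrix(as.vector(S), B, C)), 1L, C)
    }
    return(list(dV = dZ * He, dH = dH))
  }
  .cpp_fftconv_bwd(dZ, cache$Vf, cache$Hf, as.integer(cache$B),
                   as.integer(cache$L), need_dH)
}

# ---- depthwise causal short convolution -------------------------------------
# X is (L*B) x C; kernel K is C x w (tap 1 = lag 0). Causal left pad.

.short_conv_fwd <- function(X, K, L, B) {
  Xl <- X; dim(Xl) <- c(L, B * nrow(K))
  Y <- .cpp_shortconv_fwd(Xl, K, as.integer(B))
  dim(Y) <- dim(X)
  Y
}

.short_conv_bwd <- function(dZ, X, K, L, B) {
  dZl <- dZ; dim(dZl) <- c(L, B * nrow(K))
  Xl <- X; dim(Xl) <- c(L, B * nrow(K))
  r <- .cpp_shortconv_bwd(dZl, Xl, K, as.integer(B))
  dX <- r$dX
  dim(dX) <- dim(dZ)
  list(dX = dX, dK = r$dK)
}

# ---- dense / layer norm / GELU ----------------------------------------------

.dense_fwd <- function(X, W, b) {
  Y <- X %*% W
  if (!is.null(b)) Y <- .cpp_add_bias(Y, b)
  Y
}

.dense_bwd <- function(dZ, X, W) {
  list(dX = dZ %*% t(W), dW = crossprod(X, dZ), db = colSums(dZ))
}

.layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  .cpp_layernorm_fwd(X, g, b, eps)
}

.layernorm_bwd <- function(dZ, cache, g) {
  .cpp_layernorm_bwd(dZ, cache$xhat, cache$inv, g)
}

.gelu_fwd <- function(X) .cpp_gelu_fwd(X)

.gelu_bwd <- function(dZ, X, P) .cpp_gelu_bwd(dZ, X, P)

# ---- softmax + cross entropy ------------------------------------------------

.row_max <- function(Z) Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]

.softmax_rows <- function(Z) {
  Z <- Z - .row_max(Z)
  E <- exp(Z)
  E / rowSums(E)
}

.log_softmax_rows <- function(Z) {
  Z <- Z - .row_max(Z)
  Z - log(rowSums(exp(Z)))
}

# logits: M x K, target: integer 1-based class per row (NA = masked out).
# Returns mean NLL over unmasked rows and the gradient w.r.t. logits.
.ce_loss <- function(logits, target, want_grad = TRUE) {
  keep <- which(!is.na(target))
  if (length(keep) == 0L) stop("cross-entropy loss over an all-masked batch")
  ls <- .log_softmax_rows(logits[keep, , drop = FALSE])
  idx <- cbind(seq_along(keep), target[keep])
  loss <- -mean(ls[idx])
  g <- NULL
  if (want_grad) {
    P <- exp(ls)
    P[idx] <- P[idx] - 1
    g <- matrix(0, nrow(logits), ncol(logits))
    g[keep, ] <- P / length(keep)
  }
  list(loss = loss, grad = g, n = length(keep))
}

# ---- parameter-tree utilities -----------------------------------------------
# Model parameters are nested named lists of numeric arrays. Elements named
# "config" or "const" hold non-trainable metadata and are skipped everywhere.

.tree_idx <- function(x) {
  nms <- names(x)
  keep <- seq_along(x)
  if (!is.null(nms)) keep <- keep[!nms %in% c("config", "const")]
  keep
}

.tree_map <- function(x, f) {
  if (is.list(x)) {
    out <- x
    for (i in .tree_idx(x)) out[[i]] <- .tree_map(x[[i]], f)
    out
  } else f(x)
}

.tree_map2 <- function(x, y, f) {
  if (is.list(x)) {
    out <- x
    nms <- names(x)
    for (i in .tree_idx(x)) {
      j <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
      out[[i]] <- .tree_map2(x[[i]], y[[j]], f)
    }
    out
  } else f(x, y)
}

.tree_reduce <- function(x, f, init = 0) {
  acc <- init
  rec <- function(z) {
    if (is.list(z)) {
      for (i in .tree_idx(z)) rec(z[[i]])
    } else acc <<- f(acc, z)
  }
  rec(x)
  acc
}

.tree_zeros_like <- function(x) .tree_map(x, function(a) a * 0)

.grad_global_norm <- function(g) {
  sqrt(.tree_reduce(g, function(acc, a) acc + sum(a * a)))
}
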