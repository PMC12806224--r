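# Causal multi-head self-attention mixer (decoder-only baseline).
#
# Scores are scaled by 1/sqrt(head_dim) and masked so position t attends only
# to positions <= t; positional information enters through parameter-free
# rotary embeddings applied to queries and keys, so the layer adds no
# length-dependent learnables.

# rotary angles for one head: L x (Dh/2)
.rotary_angles <- function(L, Dh, base = 10000) {
  half <- Dh %/% 2L
  freqs <- base^(-(2 * (seq_len(half) - 1)) / Dh)
  outer(seq_len(L) - 1, freqs)
}

# apply rotation (sign = +1) or its inverse (sign = -1) to L x Dh matrix
.rotary_apply <- function(Q, ang, sign = 1) {
  half <- ncol(ang)
  od <- seq_len(half) * 2L - 1L
  ev <- od + 1L
  co <- cos(ang); si <- sin(ang) * sign
  out <- Q
  out[, od] <- Q[, od] * co - Q[, ev] * si
  out[, ev] <- Q[, od] * si + Q[, ev] * co
  out
}

#' Causal self-attention layer (single input sequence)
#'
#' Computes masked, scaled dot-product attention
#' `y = softmax(mask(x W_q (x W_k)^T / sqrt(d_head))) x W_v` per head,
#' followed by the output projection. Attention rows are stochastic over
#' positions <= t, so the layer is autoregressive.
#'
#' @param x L x D input matrix.
#' @param params List with `W_q`, `W_k`, `W_v`, `W_o` (D x D), biases `b_q`,
#'   `b_k`, `b_v`, `b_o`, and `config$n_heads`. See [attention_params()].
#' @param rotary Apply rotary position embeddings (default TRUE).
#' @return L x D output matrix.
#' @export
attention_forward <- function(x, params, rotary = TRUE) {
  x <- as.matrix(x)
  L <- nrow(x)
  cache <- .attn_mixer_fwd(x, params, L, 1L, rotary = rotary)
  cache$y
}

#' Create parameters for a standalone attention layer
#'
#' @param embed_dim Model width D.
#' @param n_heads Number of attention heads (must divide D).
#' @param seed Integer seed.
#' @return Named list of weights with `config` metadata.
#' @export
attention_params <- function(embed_dim, n_heads = 4L, seed = 1L) {
  D <- as.integer(embed_dim)
  stopifnot(D %% n_heads == 0L)
  rng <- .local_rng(seed)
  p <- list(
    W_q = rng$mat(D, D, sd = 0.02), b_q = numeric(D),
    W_k = rng$mat(D, D, sd = 0.02), b_k = numeric(D),
    W_v = rng$mat(D, D, sd = 0.02), b_v = numeric(D),
    W_o = rng$mat(D, D, sd = 0.02), b_o = numeric(D),
    config = list(embed_dim = D, n_heads = as.integer(n_heads))
  )
  class(p) <- "attention_params"
  p
}

# X: (L*B) x D. Loops over batch items and heads; L is small at desk scale.
.attn_mixer_fwd <- function(X, p, L, B, rotary = TRUE) {
  D <- ncol(X); H <- p$config$n_heads; Dh <- D %/% H
  Q <- .dense_fwd(X, p$W_q, p$b_q)
  K <- .dense_fwd(X, p$W_k, p$b_k)
  V <- .dense_fwd(X, p$W_v, p$b_v)
  ang <- if (rotary) .rotary_angles(L, Dh) else NULL
  mask <- upper.tri(matrix(0, L, L))          # j > i: disallowed
  Yc <- matrix(0, nrow(X), D)
  pc <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * L + 1L):(b * L)
    hc <- vector("list", H)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * Dh + 1L):(h * Dh)
      Qh <- Q[rows, cols, drop = FALSE]
      Kh <- K[rows, cols, drop = FALSE]
      if (rotary) {
        Qh <- .rotary_apply(Qh, ang)
        Kh <- .rotary_apply(Kh, ang)
      }
      S <- tcrossprod(Qh, Kh) / sqrt(Dh)
      S[mask] <- -Inf
      P <- .softmax_rows(S)
      Yc[rows, cols] <- P %*% V[rows, cols, drop = FALSE]
      hc[[h]] <- list(P = P, Qr = Qh, Kr = Kh)
    }
    pc[[b]] <- hc
  }
  y <- .dense_fwd(Yc, p$W_o, p$b_o)
  list(y = y, X = X, Q = Q, K = K, V = V, Yc = Yc, pc = pc, ang = ang,
       L = L, B = B, H = H, Dh = Dh, rotary = rotary)
}

.attn_mixer_bwd <- function(dY, cache, p) {
  L <- cache$L; B <- cache$B; H <- cache$H; Dh <- cache$Dh
  do <- .dense_bwd(dY, cache$Yc, p$W_o)
  dYc <- do$dX
  dQ <- matrix(0, nrow(dY), ncol(dY))
  dK <- matrix(0, nrow(dY), ncol(dY))
  dV <- matrix(0, nrow(dY), ncol(dY))
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * L + 1L):(b * L)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * Dh + 1L):(h * Dh)
      hc <- cache$pc[[b]][[h]]
      P <- hc$P
      dYh <- dYc[rows, cols, drop = FALSE]
      Vh <- cache$V[rows, cols, drop = FALSE]
      dP <- tcrossprod(dYh, Vh)
      dV[rows, cols] <- crossprod(P, dYh)
      dS <- P * (dP - rowSums(dP * P))
      dQh <- (dS %*% hc$Kr) / sqrt(Dh)
      dKh <- (crossprod(dS, hc$Qr)) / sqrt(Dh)
      if (cache$rotary) {
        dQh <- .rotary_apply(dQh, cache$ang, sign = -1)
        dKh <- .rotary_apply(dKh, cache$ang, sign = -1)
      }
      dQ[rows, cols] <- dQh
      dK[rows, cols] <- dKh
    }
  }
  gq <- .dense_bwd(dQ, cache$X, p$W_q)
  gk <- .dense_bwd(dK, cache$X, p$W_k)
  gv <- .dense_bwd(dV, cache$X, p$W_v)
  list(dX = gq$dX + gk$dX + gv$dX,
       grads = list(W_q = gq$dW, b_q = gq$db, W_k = gk$dW, b_k = gk$db,
                    W_v = gv$dW, b_v = gv$db, W_o = do$dW, b_o = do$db))
}
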