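#' Language-model configuration
#'
#' Defines the architecture of a character-level autoregressive protein
#' language model. Two mixer families are supported: `"hyena"` (long
#' convolutions + gating, see [hyena-operator]) and `"attention"` (causal
#' multi-head self-attention with rotary position embeddings). Each block is
#' pre-normalized: layer norm -> mixer -> residual add, layer norm ->
#' feed-forward (GELU) -> residual add; a final layer norm precedes the
#' decoding head, which is weight-tied to the embedding table.
#'
#' The default hyena configuration (2 blocks, D = 256, 1024 feed-forward
#' units, order N = 2, vocabulary 28, maximum length 1024) has about 1.6
#' million trainable parameters; the attention "tiny" preset matches it and
#' the "base" preset (8 blocks, D = 512, 2048 feed-forward units) has about
#' 25.2 million.
#'
#' @param arch `"hyena"` or `"attention"`.
#' @param n_layers Number of blocks.
#' @param embed_dim Embedding width D.
#' @param ffn_dim Feed-forward hidden width.
#' @param order Hyena recurrence order N (hyena only).
#' @param n_heads Attention heads (attention only).
#' @param max_len Maximum sequence length.
#' @param vocab_size Vocabulary size (default 28).
#' @param head_tied Tie the decoding head to the embedding table.
#' @param short_conv_width,filter_features,filter_hidden Hyena operator
#'   hyperparameters, see [hyena_op_params()].
#' @return A `model_config` list.
#' @export
model_config <- function(arch = c("hyena", "attention"),
                         n_layers = 2L, embed_dim = 256L, ffn_dim = 1024L,
                         order = 2L, n_heads = 4L, max_len = 1024L,
                         vocab_size = 28L, head_tied = TRUE,
                         short_conv_width = 3L, filter_features = 8L,
                         filter_hidden = 32L) {
  arch <- match.arg(arch)
  cfg <- list(arch = arch, n_layers = as.integer(n_layers),
              embed_dim = as.integer(embed_dim), ffn_dim = as.integer(ffn_dim),
              order = as.integer(order), n_heads = as.integer(n_heads),
              max_len = as.integer(max_len), vocab_size = as.integer(vocab_size),
              head_tied = isTRUE(head_tied),
              short_conv_width = as.integer(short_conv_width),
              filter_features = as.integer(filter_features),
              filter_hidden = as.integer(filter_hidden))
  if (cfg$embed_dim < 1L || cfg$n_layers < 1L || cfg$ffn_dim < 1L)
    stop("invalid model dimensions")
  if (arch == "attention" && cfg$embed_dim %% cfg$n_heads != 0L)
    stop("embed_dim must be divisible by n_heads")
  class(cfg) <- "model_config"
  cfg
}

#' Preset: default Hyena protein language model (about 1.6 M parameters)
#' @inheritParams model_config
#' @return A `model_config`.
#' @export
hyena_lm_config <- function(max_len = 1024L) {
  model_config("hyena", n_layers = 2L, embed_dim = 256L, ffn_dim = 1024L,
               order = 2L, max_len = max_len)
}

#' Preset: attention baselines ("tiny" about 1.6 M, "base" about 25.2 M)
#' @param size `"tiny"` (2 layers, D = 256) or `"base"` (8 layers, D = 512,
#'   maximum length 512).
#' @return A `model_config`.
#' @export
attention_lm_config <- function(size = c("tiny", "base")) {
  size <- match.arg(size)
  if (size == "tiny") {
    model_config("attention", n_layers = 2L, embed_dim = 256L,
                 ffn_dim = 1024L, n_heads = 4L, max_len = 1024L)
  } else {
    model_config("attention", n_layers = 8L, embed_dim = 512L,
                 ffn_dim = 2048L, n_heads = 8L, max_len = 512L)
  }
}

#' Build (initialize) a language model
#'
#' Deterministic given the seed: two calls with identical config and seed
#' return identical parameters. Every trainable array lives in the returned
#' nested list; `config` and `const` entries are non-trainable metadata.
#'
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return A parameter tree of class `protein_lm`.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  rng <- .local_rng(seed)
  D <- config$embed_dim
  blocks <- lapply(seq_len(config$n_layers), function(i) {
    mixer <- if (config$arch == "hyena") {
      .strip_class(hyena_op_params(D, order = config$order,
                                   short_conv_width = config$short_conv_width,
                                   filter_features = config$filter_features,
                                   filter_hidden = config$filter_hidden,
                                   seed = rng$int()))
    } else {
      .strip_class(attention_params(D, n_heads = config$n_heads,
                                    seed = rng$int()))
    }
    list(
      ln1_g = rep(1, D), ln1_b = numeric(D),
      mixer = mixer,
      ln2_g = rep(1, D), ln2_b = numeric(D),
      ffn = list(W1 = rng$mat(D, config$ffn_dim, sd = 0.02),
                 b1 = numeric(config$ffn_dim),
                 W2 = rng$mat(config$ffn_dim, D, sd = 0.02),
                 b2 = numeric(D))
    )
  })
  params <- list(
    tok_emb = rng$mat(config$vocab_size, D, sd = 0.02),
    blocks = blocks,
    lnf_g = rep(1, D), lnf_b = numeric(D),
    config = config
  )
  if (!config$head_tied) {
    params <- append(params, list(head = rng$mat(config$vocab_size, D, sd = 0.02)),
                     after = 3L)
  }
  class(params) <- "protein_lm"
  params
}

.strip_class <- function(x) { class(x) <- NULL; x }

#' Count trainable parameters
#'
#' Walks the parameter tree and sums the lengths of every trainable array
#' (entries named `config`/`const` are metadata and excluded).
#'
#' @param params A parameter tree (`protein_lm`, `hyena_op_params`,
#'   `cnn_regressor`, task model, ...).
#' @return Exact integer count of trainable scalars.
#' @seealso [param_millions()]
#' @export
count_parameters <- function(params) {
  .tree_reduce(params, function(acc, a) acc + length(a))
}

#' Parameter count in millions, rounded to one decimal
#' @inheritParams count_parameters
#' @param digits Decimal places (default 1).
#' @return Numeric scalar, e.g. `1.6`.
#' @export
param_millions <- function(params, digits = 1L) {
  round(count_parameters(params) / 1e6, digits)
}

#' Per-component parameter breakdown
#' @inheritParams count_parameters
#' @return Named integer vector of counts for the top-level components.
#' @export
param_breakdown <- function(params) {
  comps <- names(params)
  comps <- comps[!comps %in% c("config", "const")]
  out <- vapply(comps, function(nm) count_parameters(params[[nm]]),
                numeric(1))
  out
}

# ---- forward ----------------------------------------------------------------

# ids: L x B integer matrix of 0-based token ids (time-major).
# Returns final hidden state (pre-head, post final layer norm), logits, cache.
.lm_forward <- function(params, ids, want_cache = FALSE, want_logits = TRUE) {
  cfg <- params$config
  L <- nrow(ids); B <- ncol(ids)
  if (L > cfg$max_len) stop("sequence length ", L, " exceeds max_len = ",
                            cfg$max_len)
  X <- params$tok_emb[as.vector(ids) + 1L, , drop = FALSE]
  cache <- list(ids = ids, L = L, B = B, blocks = vector("list", cfg$n_layers))
  for (i in seq_len(cfg$n_layers)) {
    blk <- params$blocks[[i]]
    ln1 <- .layernorm_fwd(X, blk$ln1_g, blk$ln1_b)
    mx <- if (cfg$arch == "hyena") {
      .hyena_mixer_fwd(ln1$y, blk$mixer, L, B)
    } else {
      .attn_mixer_fwd(ln1$y, blk$mixer, L, B)
    }
    X1 <- X + mx$y
    ln2 <- .layernorm_fwd(X1, blk$ln2_g, blk$ln2_b)
    A <- .dense_fwd(ln2$y, blk$ffn$W1, blk$ffn$b1)
    gl <- .gelu_fwd(A)
    Fo <- .dense_fwd(gl$y, blk$ffn$W2, blk$ffn$b2)
    X2 <- X1 + Fo
    if (want_cache) {
      cache$blocks[[i]] <- list(ln1 = ln1, mx = mx, ln2 = ln2, A = A,
                                Hg = gl$y, gP = gl$P, X = X, X1 = X1)
    }
    X <- X2
  }
  lnf <- .layernorm_fwd(X, params$lnf_g, params$lnf_b)
  head_w <- if (cfg$head_tied) params$tok_emb else params$head
  logits <- if (want_logits) lnf$y %*% t(head_w) else NULL
  if (want_cache) { cache$lnf <- lnf; cache$Xpre <- X }
  list(hidden = lnf$y, logits = logits, cache = if (want_cache) cache)
}

# Backward. Supply dlogits ((L*B) x V) and/or dhidden ((L*B) x D, gradient on
# the post-final-norm hidden state). Returns nested gradient tree matching
# `params`.
.lm_backward <- function(params, cache, dlogits = NULL, dhidden = NULL) {
  cfg <- params$config
  L <- cache$L; B <- cache$B
  dE <- matrix(0, nrow(params$tok_emb), ncol(params$tok_emb))
  dHead <- NULL
  dH <- if (is.null(dhidden)) matrix(0, L * B, cfg$embed_dim) else dhidden
  if (!is.null(dlogits)) {
    head_w <- if (cfg$head_tied) params$tok_emb else params$head
    dH <- dH + dlogits %*% head_w
    if (cfg$head_tied) dE <- dE + crossprod(dlogits, cache$lnf$y)
    else dHead <- crossprod(dlogits, cache$lnf$y)
  } else if (!cfg$head_tied) {
    dHead <- matrix(0, nrow(params$head), ncol(params$head))
  }
  lb <- .layernorm_bwd(dH, cache$lnf, params$lnf_g)
  dX <- lb$dX
  g <- list(tok_emb = NULL, blocks = vector("list", cfg$n_layers),
            lnf_g = lb$dg, lnf_b = lb$db)
  for (i in rev(seq_len(cfg$n_layers))) {
    blk <- params$blocks[[i]]
    bc <- cache$blocks[[i]]
    # feed-forward branch
    d2 <- .dense_bwd(dX, bc$Hg, blk$ffn$W2)
    dA <- .gelu_bwd(d2$dX, bc$A, bc$gP)
    d1 <- .dense_bwd(dA, bc$ln2$y, blk$ffn$W1)
    l2 <- .layernorm_bwd(d1$dX, bc$ln2, blk$ln2_g)
    dX1 <- dX + l2$dX
    # mixer branch
    mb <- if (cfg$arch == "hyena") {
      .hyena_mixer_bwd(dX1, bc$mx, blk$mixer)
    } else {
      .attn_mixer_bwd(dX1, bc$mx, blk$mixer)
    }
    l1 <- .layernorm_bwd(mb$dX, bc$ln1, blk$ln1_g)
    dX <- dX1 + l1$dX
    g$blocks[[i]] <- list(
      ln1_g = l1$dg, ln1_b = l1$db,
      mixer = mb$grads,
      ln2_g = l2$dg, ln2_b = l2$db,
      ffn = list(W1 = d1$dW, b1 = d1$db, W2 = d2$dW, b2 = d2$db)
    )
  }
  # embedding-lookup gradient (tied head already accumulated above)
  idx <- as.vector(cache$ids) + 1L
  agg <- rowsum(dX, group = idx)
  dE[as.integer(rownames(agg)), ] <- dE[as.integer(rownames(agg)), ] + agg
  g$tok_emb <- dE
  if (!cfg$head_tied) g$head <- dHead
  g$config <- cfg
  g
}

#' Run the language model over one token sequence
#'
#' @param tokens A `token_seq` (0-based ids) or character sequence.
#' @param params A `protein_lm` from [build_model()].
#' @return An `lm_output` list: `logits` (L x vocab), `log_probs`
#'   (row-normalized log conditional distributions
#'   `log P(a_(i+1) | a_1..a_i)` at row i), and `tokens`.
#' @export
forward_lm <- function(tokens, params) {
  ids <- .as_token_ids(tokens, params$config$vocab_size)
  fw <- .lm_forward(params, matrix(ids, ncol = 1L))
  out <- list(logits = fw$logits, log_probs = .log_softmax_rows(fw$logits),
              tokens = ids)
  class(out) <- "lm_output"
  out
}

.as_token_ids <- function(tokens, vocab_size) {
  if (is.character(tokens)) tokens <- encode(tokens)
  ids <- as.integer(tokens)
  if (length(ids) == 0L) stop("empty token sequence")
  if (anyNA(ids) || any(ids < 0L) || any(ids >= vocab_size))
    stop("token ids must lie in [0, ", vocab_size, ")")
  ids
}

#' Extract final-layer embeddings for a sequence
#'
#' Returns the pre-head representation (after the final layer norm) used by
#' the fine-tuning heads: one D-dimensional row per position.
#'
#' @inheritParams forward_lm
#' @return L x D numeric matrix.
#' @export
extract_embeddings <- function(tokens, params) {
  ids <- .as_token_ids(tokens, params$config$vocab_size)
  .lm_forward(params, matrix(ids, ncol = 1L), want_logits = FALSE)$hidden
}
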