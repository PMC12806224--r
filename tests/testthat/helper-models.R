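# Shared fixtures: all built in code, seeded.

tiny_hyena_config <- function(D = 8L, ffn = 12L, layers = 2L, max_len = 64L) {
  model_config("hyena", n_layers = layers, embed_dim = D, ffn_dim = ffn,
               max_len = max_len, filter_hidden = 6L, filter_features = 4L)
}

tiny_attn_config <- function(D = 8L, ffn = 12L, layers = 2L, heads = 2L,
                             max_len = 64L) {
  model_config("attention", n_layers = layers, embed_dim = D, ffn_dim = ffn,
               n_heads = heads, max_len = max_len)
}

random_aa_string <- function(n, alphabet = build_vocabulary()$tokens[1:25]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# An analytic language model: all block weights zero (blocks reduce to the
# identity on the residual stream), zero embeddings, and a hand-set untied
# head, so the conditional distribution is a fixed, known softmax.
constant_logit_model <- function(logit_by_token, D = 4L) {
  cfg <- model_config("hyena", n_layers = 1L, embed_dim = D, ffn_dim = 4L,
                      max_len = 2048L, head_tied = FALSE,
                      filter_hidden = 4L, filter_features = 4L)
  m <- build_model(cfg, seed = 1)
  m <- hyenalm:::.tree_map(m, function(a) a * 0)
  # zero hidden state after the final layer norm gets bias (1, 0, 0, ...)
  m$lnf_b[1] <- 1
  head <- matrix(0, cfg$vocab_size, D)
  head[, 1] <- logit_by_token
  m$head <- head
  class(m) <- "protein_lm"
  m
}

# numeric gradient of f at params along one leaf entry
leaf_assign <- function(tree, path, idx, value) {
  if (length(path) == 0L) {
    tree[idx] <- value
    return(tree)
  }
  k <- path[[1]]
  tree[[k]] <- leaf_assign(tree[[k]], path[-1], idx, value)
  tree
}

leaf_paths <- function(tree) {
  paths <- list()
  rec <- function(x, pre) {
    if (is.list(x)) {
      nms <- names(x)
      for (i in seq_along(x)) {
        if (!is.null(nms) && nms[i] %in% c("config", "const")) next
        key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
        rec(x[[i]], c(pre, list(key)))
      }
    } else paths[[length(paths) + 1L]] <<- pre
  }
  rec(tree, list())
  paths
}

leaf_get <- function(tree, path) {
  for (p in path) tree <- tree[[p]]
  tree
}
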