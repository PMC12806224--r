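#' Training configuration
#'
#' Defaults follow the reference pretraining setup: batch size 256, maximum
#' length 1024, Adam with initial learning rate 6e-4 and cosine decay to 0
#' over about 30,000 steps. Desk-scale runs override `batch_size`,
#' `total_steps` and `max_len`; the schedule shape is unchanged.
#'
#' @param batch_size Sequences per step.
#' @param max_len Maximum sequence length (longer pretraining sequences are
#'   truncated with a warning).
#' @param lr Initial (post-warmup) learning rate.
#' @param min_lr Final learning rate of the cosine schedule.
#' @param total_steps Total optimization steps.
#' @param warmup_steps Linear warmup steps (default 0).
#' @param val_fraction Fraction of records held out for validation.
#' @param eval_every Steps between validation-perplexity evaluations.
#' @param clip_norm Global gradient-norm clip (default 1).
#' @param seed Integer seed controlling splitting, batching and
#'   initialization noise within the run.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 256L, max_len = 1024L, lr = 6e-4,
                         min_lr = 0, total_steps = 30000L, warmup_steps = 0L,
                         val_fraction = 0.01, eval_every = 200L,
                         clip_norm = 1, seed = 1L) {
  cfg <- list(batch_size = as.integer(batch_size), max_len = as.integer(max_len),
              lr = lr, min_lr = min_lr, total_steps = as.integer(total_steps),
              warmup_steps = as.integer(warmup_steps),
              val_fraction = val_fraction, eval_every = as.integer(eval_every),
              clip_norm = clip_norm, seed = as.integer(seed))
  class(cfg) <- "train_config"
  cfg
}

#' Cosine learning-rate schedule
#'
#' Linear warmup (if any) to `lr`, then cosine interpolation down to
#' `min_lr` at `total_steps`.
#'
#' @param step 0-based step, `0 <= step <= total_steps`.
#' @param schedule A [train_config()] or any list with `lr`, `min_lr`,
#'   `total_steps`, `warmup_steps`.
#' @return Learning rate at `step`.
#' @examples
#' cosine_lr(0, train_config(lr = 6e-4, warmup_steps = 0))      # 6e-4
#' cosine_lr(15000, train_config(total_steps = 30000))          # 3e-4
#' @export
cosine_lr <- function(step, schedule) {
  if (step < 0) stop("step must be nonnegative")
  w <- schedule$warmup_steps %||% 0L
  if (w > 0 && step < w) return(schedule$lr * step / w)
  total <- schedule$total_steps
  frac <- min(1, (step - w) / max(1L, total - w))
  schedule$min_lr + 0.5 * (schedule$lr - schedule$min_lr) *
    (1 + cos(pi * frac))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean negative log-likelihood of the next-token predictions
#'
#' Position i's logits predict token i+1, so a length-L sequence contributes
#' L-1 predictions; pad positions are excluded. The returned value is the
#' cross-entropy H in nats per predicted position.
#'
#' @param output An `lm_output` from [forward_lm()].
#' @param tokens The `token_seq` the output was computed on.
#' @param pad_id Pad token id excluded from the loss (default 25).
#' @return Mean negative log conditional probability (nats).
#' @export
nll_loss <- function(output, tokens, pad_id = 25L) {
  ids <- as.integer(tokens)
  L <- length(ids)
  if (L < 2L) stop("need at least 2 tokens for a next-token loss")
  targ <- ids[-1L]
  keep <- targ != pad_id & ids[-L] != pad_id
  if (!any(keep)) stop("no non-pad positions to predict")
  lp <- output$log_probs[seq_len(L - 1L), , drop = FALSE]
  -mean(lp[cbind(which(keep), targ[keep] + 1L)])
}

# targets for a padded L x B id matrix: 1-based class of the next token, NA
# where the prediction or the target is pad / out of range
.lm_targets <- function(ids, lengths, pad_id) {
  L <- nrow(ids); B <- ncol(ids)
  targ <- matrix(NA_integer_, L, B)
  if (L >= 2L) {
    targ[1:(L - 1L), ] <- ids[2:L, ] + 1L
    targ[L, ] <- NA_integer_
    for (b in seq_len(B)) {
      if (lengths[b] < L) targ[lengths[b]:L, b] <- NA_integer_
      # positions >= length predict nothing; position length-1 predicts last
    }
  }
  targ
}

# one forward/backward step on a padded batch; returns loss and grads
.lm_loss_grads <- function(params, ids, lengths, pad_id, want_grad = TRUE) {
  fw <- .lm_forward(params, ids, want_cache = want_grad)
  targ <- .lm_targets(ids, lengths, pad_id)
  ce <- .ce_loss(fw$logits, as.vector(targ), want_grad = want_grad)
  g <- NULL
  if (want_grad) g <- .lm_backward(params, fw$cache, dlogits = ce$grad)
  list(loss = ce$loss, grads = g, n = ce$n)
}

# ---- Adam -------------------------------------------------------------------

.adam_init <- function(params) {
  list(m = .tree_zeros_like(params), v = .tree_zeros_like(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  state$m <- .tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- .tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g * g)
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  upd <- .tree_map2(state$m, state$v, function(m, v) {
    (m / bc1) / (sqrt(v / bc2) + eps)
  })
  params <- .tree_map2(params, upd, function(p, u) p - lr * u)
  list(params = params, state = state)
}

.clip_grads <- function(grads, clip_norm) {
  gn <- .grad_global_norm(grads)
  if (is.finite(clip_norm) && clip_norm > 0 && gn > clip_norm) {
    grads <- .tree_map(grads, function(g) g * (clip_norm / gn))
  }
  list(grads = grads, norm = gn)
}

# ---- corpus handling --------------------------------------------------------

# Accepts a FASTA path, a character vector of sequences, or a list of
# token_seq vectors; returns a list of integer id vectors.
.as_corpus <- function(corpus, vocab = build_vocabulary(), max_len = 1024L,
                       overflow = "truncate") {
  if (is.character(corpus) && length(corpus) == 1L && file.exists(corpus)) {
    corpus <- read_fasta(corpus)$sequence
  }
  if (is.character(corpus)) {
    if (length(corpus) == 0L) return(list())
    enc <- encode_batch(corpus, vocab, max_len, overflow)
    return(lapply(seq_along(corpus), function(b)
      enc$ids[seq_len(enc$lengths[b]), b]))
  }
  if (is.list(corpus)) return(lapply(corpus, as.integer))
  stop("corpus must be a FASTA path, character vector, or list of token ids")
}

# group sequence indices into batches of similar length
.length_buckets <- function(lens, batch_size) {
  ord <- order(lens, stats::runif(length(lens)))
  split(ord, ceiling(seq_along(ord) / batch_size))
}

.pad_batch <- function(seqs, pad_id) {
  lens <- lengths(seqs)
  L <- max(lens)
  ids <- matrix(pad_id, L, length(seqs))
  for (b in seq_along(seqs)) ids[seq_len(lens[b]), b] <- seqs[[b]]
  list(ids = ids, lengths = lens)
}

#' Corpus perplexity of a language model
#'
#' Computes the corpus-level cross-entropy H (mean negative log conditional
#' probability per predicted position, in nats) and the perplexity
#' `PPL = exp(H)`. A perfect predictor has PPL = 1; a uniform predictor over
#' 20 tokens has PPL = 20.
#'
#' @param model A `protein_lm`.
#' @param corpus FASTA path, character vector of sequences, or list of token
#'   id vectors.
#' @param batch_size Evaluation batch size.
#' @return A `perplexity_report` list with `H`, `PPL`, `n_positions`.
#' @export
perplexity <- function(model, corpus, batch_size = 32L) {
  vocab <- build_vocabulary()
  seqs <- .as_corpus(corpus, vocab, model$config$max_len)
  if (length(seqs) == 0L) stop("empty corpus")
  seqs <- seqs[lengths(seqs) >= 2L]
  if (length(seqs) == 0L) stop("no sequence long enough to score")
  total <- 0; n <- 0L
  buckets <- split(order(lengths(seqs)),
                   ceiling(seq_along(seqs) / batch_size))
  for (idx in buckets) {
    pb <- .pad_batch(seqs[idx], vocab$pad_id)
    r <- .lm_loss_grads(model, pb$ids, pb$lengths, vocab$pad_id,
                        want_grad = FALSE)
    total <- total + r$loss * r$n
    n <- n + r$n
  }
  H <- total / n
  structure(list(H = H, PPL = exp(H), n_positions = n),
            class = "perplexity_report")
}

#' Autoregressive pretraining
#'
#' Trains a language model to maximize the probability of the next amino
#' acid, `prod_i P(a_i | a_1..a_(i-1))`, with Adam, cosine learning-rate
#' decay, global gradient-norm clipping, and length-bucketed padded batches
#' whose pad positions are masked out of the loss. Deterministic given
#' `config$seed`.
#'
#' @param model A `protein_lm` from [build_model()].
#' @param corpus FASTA path, character vector, or list of token id vectors.
#' @param config A [train_config()].
#' @param log_file Optional TSV path for the per-step log.
#' @param verbose Print progress.
#' @return List with `params` (final), `best` (lowest validation PPL
#'   checkpoint), `log` (data.frame: step, loss, lr, val_ppl), `val_ppl`.
#' @export
pretrain <- function(model, corpus, config = train_config(),
                     log_file = NULL, verbose = FALSE) {
  vocab <- build_vocabulary()
  seqs <- .as_corpus(corpus, vocab, config$max_len)
  if (length(seqs) == 0L) stop("empty corpus")
  set.seed(config$seed)
  n_val <- max(0L, round(config$val_fraction * length(seqs)))
  val_idx <- if (n_val > 0) sample(seq_along(seqs), n_val) else integer(0)
  train_seqs <- if (n_val > 0) seqs[-val_idx] else seqs
  val_seqs <- seqs[val_idx]
  train_seqs <- train_seqs[lengths(train_seqs) >= 2L]

  state <- .adam_init(model)
  log <- data.frame(step = integer(0), loss = numeric(0), lr = numeric(0),
                    val_ppl = numeric(0))
  best <- list(params = model, val_ppl = Inf)
  step <- 0L
  batches <- list()
  while (step < config$total_steps) {
    if (length(batches) == 0L) {
      batches <- .length_buckets(lengths(train_seqs), config$batch_size)
      batches <- batches[sample(length(batches))]
    }
    idx <- batches[[1L]]; batches <- batches[-1L]
    pb <- .pad_batch(train_seqs[idx], vocab$pad_id)
    r <- .lm_loss_grads(model, pb$ids, pb$lengths, vocab$pad_id)
    cg <- .clip_grads(r$grads, config$clip_norm)
    lr <- cosine_lr(step, config)
    upd <- .adam_step(model, cg$grads, state, lr)
    model <- upd$params; state <- upd$state
    step <- step + 1L
    vp <- NA_real_
    if (length(val_seqs) > 0 &&
        (step %% config$eval_every == 0L || step == config$total_steps)) {
      vp <- perplexity(model, val_seqs)$PPL
      if (vp < best$val_ppl) best <- list(params = model, val_ppl = vp)
    }
    log <- rbind(log, data.frame(step = step, loss = r$loss, lr = lr,
                                 val_ppl = vp))
    if (verbose && (step %% 50L == 0L || step == 1L)) {
      message(sprintf("step %d  loss %.4f  lr %.2e  val_ppl %s", step,
                      r$loss, lr, ifelse(is.na(vp), "-", sprintf("%.3f", vp))))
    }
  }
  if (!is.null(log_file)) {
    utils::write.table(log, log_file, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  final_vp <- if (length(val_seqs) > 0) perplexity(model, val_seqs)$PPL else NA_real_
  if (is.finite(final_vp) && final_vp < best$val_ppl)
    best <- list(params = model, val_ppl = final_vp)
  list(params = model, best = best, log = log, val_ppl = final_vp)
}
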