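#' Downstream task specification
#'
#' @param task_type `"binary"`, `"multiclass"`, or `"regression"`.
#' @param resolution `"protein"` (one prediction per sequence via mean-pooled
#'   embeddings) or `"residue"` (one prediction per position).
#'   Residue-level regression is not supported (no such task exists in the
#'   benchmark family this mirrors).
#' @param n_classes Number of classes; 1 for regression.
#' @return A `task_spec` list.
#' @export
task_spec <- function(task_type = c("binary", "multiclass", "regression"),
                      resolution = c("protein", "residue"), n_classes = NULL) {
  task_type <- match.arg(task_type)
  resolution <- match.arg(resolution)
  if (is.null(n_classes)) {
    n_classes <- switch(task_type, binary = 2L, regression = 1L,
                        stop("n_classes required for multiclass"))
  }
  n_classes <- as.integer(n_classes)
  if (task_type == "regression" && n_classes != 1L)
    stop("regression uses n_classes = 1")
  if (task_type == "regression" && resolution == "residue")
    stop("residue-level regression is not supported")
  if (n_classes < 1L) stop("n_classes must be >= 1")
  structure(list(task_type = task_type, resolution = resolution,
                 n_classes = n_classes), class = "task_spec")
}

#' Mean-pool per-position embeddings into one protein vector
#'
#' Arithmetic mean over non-pad positions only, so right-padding a sequence
#' never changes its pooled representation.
#'
#' @param embeddings L x D matrix.
#' @param pad_mask Logical vector of length L, TRUE at pad positions
#'   (default: none).
#' @return Numeric vector of length D.
#' @export
pool_protein <- function(embeddings, pad_mask = NULL) {
  embeddings <- as.matrix(embeddings)
  if (is.null(pad_mask)) pad_mask <- rep(FALSE, nrow(embeddings))
  keep <- !pad_mask
  if (!any(keep)) stop("all positions are padding")
  colMeans(embeddings[keep, , drop = FALSE])
}

#' Attach a task head to a language model
#'
#' The head is a fresh linear decoder `D -> n_classes`: applied per position
#' for residue-level tasks, or to the mean-pooled embedding for
#' protein-level tasks. Classification heads are followed by a softmax;
#' the regression head (n_classes = 1) emits the raw scalar.
#'
#' @param model A `protein_lm` backbone (pretrained or fresh).
#' @param spec A [task_spec()].
#' @param seed Seed for head initialization.
#' @return A `task_model` list: `backbone`, `head` (with `W`, `b`), `spec`.
#' @export
attach_head <- function(model, spec, seed = 1L) {
  stopifnot(inherits(model, "protein_lm"), inherits(spec, "task_spec"))
  rng <- .local_rng(seed)
  D <- model$config$embed_dim
  tm <- list(backbone = .strip_class(model),
             head = list(W = rng$mat(D, spec$n_classes, sd = 0.02),
                         b = numeric(spec$n_classes)),
             const = list(spec = spec))
  class(tm) <- "task_model"
  tm
}

# ---- batched task forward/backward ------------------------------------------

# Returns predictions for a padded batch. outputs: for protein resolution a
# B x K matrix; for residue resolution an (L*B) x K matrix plus masks.
.task_forward <- function(tm, ids, lengths, want_cache = FALSE) {
  spec <- tm$const$spec
  bb <- tm$backbone
  class(bb) <- "protein_lm"
  fw <- .lm_forward(bb, ids, want_cache = want_cache, want_logits = FALSE)
  L <- nrow(ids); B <- ncol(ids)
  if (spec$resolution == "protein") {
    Hm <- fw$hidden; dim(Hm) <- c(L, B, ncol(Hm))
    pooled <- matrix(0, B, dim(Hm)[3])
    for (b in seq_len(B)) {
      pooled[b, ] <- colMeans(Hm[seq_len(lengths[b]), b, , drop = FALSE])
    }
    out <- .dense_fwd(pooled, tm$head$W, tm$head$b)
    list(out = out, pooled = pooled, fw = fw, L = L, B = B)
  } else {
    out <- .dense_fwd(fw$hidden, tm$head$W, tm$head$b)
    list(out = out, fw = fw, L = L, B = B)
  }
}

# dOut matches .task_forward()$out. Returns loss gradients for head+backbone.
.task_backward <- function(tm, cache, dOut, lengths) {
  spec <- tm$const$spec
  bb <- tm$backbone
  class(bb) <- "protein_lm"
  if (spec$resolution == "protein") {
    hb <- .dense_bwd(dOut, cache$pooled, tm$head$W)
    L <- cache$L; B <- cache$B; D <- ncol(cache$pooled)
    dH <- array(0, c(L, B, D))
    for (b in seq_len(B)) {
      lb <- lengths[b]
      dH[seq_len(lb), b, ] <- matrix(hb$dX[b, ] / lb, lb, D, byrow = TRUE)
    }
    dim(dH) <- c(L * B, D)
  } else {
    hb <- .dense_bwd(dOut, cache$fw$hidden, tm$head$W)
    dH <- hb$dX
  }
  gb <- .lm_backward(bb, cache$fw$cache, dhidden = dH)
  list(backbone = gb, head = list(W = hb$dW, b = hb$db))
}

# loss + grads for one batch of a task dataset
.task_loss_grads <- function(tm, ids, lengths, targets, want_grad = TRUE) {
  spec <- tm$const$spec
  fw <- .task_forward(tm, ids, lengths, want_cache = want_grad)
  if (spec$task_type == "regression") {
    r <- drop(fw$out) - targets
    loss <- mean(r^2)
    dOut <- matrix(2 * r / length(r), ncol = 1L)
  } else {
    ce <- .ce_loss(fw$out, targets, want_grad = want_grad)
    loss <- ce$loss
    dOut <- ce$grad
  }
  g <- NULL
  if (want_grad) g <- .task_backward(tm, fw, dOut, lengths)
  list(loss = loss, grads = g)
}

# residue targets: (L*B) vector of 1-based classes, NA at pads
.residue_targets <- function(label_strings, L, B, lengths) {
  targ <- matrix(NA_integer_, L, B)
  for (b in seq_len(B)) {
    lab <- as.integer(strsplit(label_strings[b], "", fixed = TRUE)[[1]])
    targ[seq_len(lengths[b]), b] <- lab + 1L
  }
  as.vector(targ)
}

# ---- fine-tuning loop -------------------------------------------------------

#' Fine-tune a task model
#'
#' Trains backbone and head end-to-end (set `freeze_backbone = TRUE` for the
#' frozen-feature alternative) with Adam, cosine decay and early stopping on
#' validation loss. Evaluates on the test split and returns the metric set
#' for the task type.
#'
#' @param tm A `task_model` from [attach_head()].
#' @param dataset A `task_dataset` (see [read_task_tsv()], [motif_task()],
#'   [landscape_task()]).
#' @param config A [train_config()]; `total_steps` is interpreted as the
#'   maximum number of optimization steps across epochs.
#' @param epochs Maximum passes over the training split.
#' @param patience Early-stopping patience in epochs (validation loss).
#' @param freeze_backbone Update only the head.
#' @param head_lr_mult Learning-rate multiplier for the fresh head relative
#'   to the backbone (default 30). The mean-pooled representation of a
#'   layer-normalized backbone has small per-feature scale, so the linear
#'   decoder needs weights far larger than the backbone's; a discriminative
#'   learning rate reaches them within a desk-scale step budget.
#' @param verbose Print progress.
#' @return List with `model` (fitted), `metrics` (a `metrics_report` on the
#'   test split, or NULL if absent), `history` (per-epoch losses).
#' @export
finetune <- function(tm, dataset, config = train_config(batch_size = 16L,
                                                        lr = 1e-4,
                                                        total_steps = 2000L),
                     epochs = 10L, patience = 5L, freeze_backbone = FALSE,
                     head_lr_mult = 30, verbose = FALSE) {
  stopifnot(inherits(tm, "task_model"))
  spec <- tm$const$spec
  vocab <- build_vocabulary()
  .validate_task_dataset(dataset, spec)
  split <- if ("split" %in% names(dataset)) dataset$split else
    rep("train", nrow(dataset))
  tr <- dataset[split == "train", , drop = FALSE]
  va <- dataset[split == "valid", , drop = FALSE]
  te <- dataset[split == "test", , drop = FALSE]
  if (nrow(tr) == 0L) stop("empty train split")
  set.seed(config$seed)
  if (spec$task_type == "regression") {
    # standardize targets for optimization; predictions are mapped back
    mu <- mean(as.numeric(tr$label)); sdv <- stats::sd(as.numeric(tr$label))
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
    tm$const$y_center <- mu
    tm$const$y_scale <- sdv
  }
  state <- .adam_init(tm)
  best <- list(model = tm, val = Inf, since = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- .length_buckets(nchar(tr$sequence), config$batch_size)
    ord <- ord[sample(length(ord))]
    ep_loss <- 0; nb <- 0L
    for (idx in ord) {
      if (step >= config$total_steps) break
      batch <- tr[idx, , drop = FALSE]
      lg <- .task_batch_loss(tm, batch, spec, vocab, config, want_grad = TRUE)
      g <- lg$grads
      if (freeze_backbone) g$backbone <- .tree_zeros_like(g$backbone)
      cg <- .clip_grads(g, config$clip_norm)
      lr <- cosine_lr(step, config)
      upd <- .adam_step(tm["backbone"], cg$grads["backbone"],
                        list(m = state$m["backbone"], v = state$v["backbone"],
                             t = state$t), lr)
      tm$backbone <- upd$params$backbone
      state$m$backbone <- upd$state$m$backbone
      state$v$backbone <- upd$state$v$backbone
      updh <- .adam_step(tm["head"], cg$grads["head"],
                         list(m = state$m["head"], v = state$v["head"],
                              t = state$t), lr * head_lr_mult)
      tm$head <- updh$params$head
      state$m$head <- updh$state$m$head
      state$v$head <- updh$state$v$head
      state$t <- updh$state$t
      class(tm) <- "task_model"
      step <- step + 1L
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
    }
    vl <- if (nrow(va) > 0) .task_eval_loss(tm, va, spec, vocab, config) else NA_real_
    history <- rbind(history, data.frame(epoch = ep, train_loss = ep_loss / max(nb, 1L),
                                         val_loss = vl))
    if (verbose) message(sprintf("epoch %d  train %.4f  val %s", ep,
                                 ep_loss / max(nb, 1L),
                                 ifelse(is.na(vl), "-", sprintf("%.4f", vl))))
    if (!is.na(vl)) {
      if (vl < best$val) best <- list(model = tm, val = vl, since = 0L)
      else {
        best$since <- best$since + 1L
        if (best$since >= patience) break
      }
    }
    if (step >= config$total_steps) break
  }
  fitted <- if (is.finite(best$val)) best$model else tm
  metrics <- if (nrow(te) > 0) evaluate_task(fitted, te) else NULL
  list(model = fitted, metrics = metrics, history = history)
}

.task_batch_loss <- function(tm, batch, spec, vocab, config, want_grad) {
  enc <- encode_batch(batch$sequence, vocab, config$max_len, overflow = "error")
  if (spec$resolution == "protein") {
    targets <- if (spec$task_type == "regression") {
      (as.numeric(batch$label) - (tm$const$y_center %||% 0)) /
        (tm$const$y_scale %||% 1)
    } else as.integer(batch$label) + 1L
  } else {
    targets <- .residue_targets(batch$labels, nrow(enc$ids), ncol(enc$ids),
                                enc$lengths)
  }
  .task_loss_grads(tm, enc$ids, enc$lengths, targets, want_grad = want_grad)
}

.task_eval_loss <- function(tm, data, spec, vocab, config) {
  total <- 0; n <- 0L
  buckets <- split(seq_len(nrow(data)), ceiling(seq_len(nrow(data)) / 32L))
  for (idx in buckets) {
    lg <- .task_batch_loss(tm, data[idx, , drop = FALSE], spec, vocab, config,
                           want_grad = FALSE)
    total <- total + lg$loss * length(idx)
    n <- n + length(idx)
  }
  total / n
}

#' Predict with a task model
#'
#' @param tm A `task_model`.
#' @param sequences Character vector of amino-acid sequences.
#' @param batch_size Evaluation batch size.
#' @return For protein-level tasks a list with `scores` (n x K softmax
#'   probabilities, or n x 1 raw values for regression) and `predictions`;
#'   for residue-level tasks per-sequence lists of the same.
#' @export
predict_task <- function(tm, sequences, batch_size = 32L) {
  spec <- tm$const$spec
  vocab <- build_vocabulary()
  n <- length(sequences)
  buckets <- split(order(nchar(sequences)), ceiling(seq_len(n) / batch_size))
  if (spec$resolution == "protein") {
    scores <- matrix(NA_real_, n, spec$n_classes)
    for (idx in buckets) {
      enc <- encode_batch(sequences[idx], vocab, tm$backbone$config$max_len,
                          overflow = "error")
      fw <- .task_forward(tm, enc$ids, enc$lengths)
      scores[idx, ] <- fw$out
    }
    if (spec$task_type == "regression") {
      preds <- drop(scores) * (tm$const$y_scale %||% 1) +
        (tm$const$y_center %||% 0)
      list(scores = scores, predictions = preds)
    } else {
      probs <- .softmax_rows(scores)
      list(scores = probs, predictions = max.col(probs) - 1L)
    }
  } else {
    out <- vector("list", n)
    for (idx in buckets) {
      enc <- encode_batch(sequences[idx], vocab, tm$backbone$config$max_len,
                          overflow = "error")
      fw <- .task_forward(tm, enc$ids, enc$lengths)
      L <- nrow(enc$ids)
      for (j in seq_along(idx)) {
        rows <- ((j - 1L) * L + 1L):((j - 1L) * L + enc$lengths[j])
        probs <- .softmax_rows(fw$out[rows, , drop = FALSE])
        out[[idx[j]]] <- list(scores = probs, predictions = max.col(probs) - 1L)
      }
    }
    out
  }
}

#' Evaluate a task model on a labeled dataset
#'
#' @param tm A `task_model`.
#' @param data A `task_dataset` slice (e.g. the test split).
#' @return A [metrics_report()] for the task type.
#' @export
evaluate_task <- function(tm, data) {
  spec <- tm$const$spec
  .validate_task_dataset(data, spec)
  pred <- predict_task(tm, data$sequence)
  if (spec$resolution == "protein") {
    if (spec$task_type == "regression") {
      metrics_report("regression", as.numeric(data$label), pred$predictions)
    } else {
      type <- if (spec$n_classes == 2L) "binary" else "multiclass"
      metrics_report(type, as.integer(data$label), pred$predictions,
                     scores = pred$scores, n_classes = spec$n_classes)
    }
  } else {
    labs <- unlist(lapply(data$labels, function(s)
      as.integer(strsplit(s, "", fixed = TRUE)[[1]])))
    preds <- unlist(lapply(pred, `[[`, "predictions"))
    scores <- do.call(rbind, lapply(pred, `[[`, "scores"))
    type <- if (spec$n_classes == 2L) "binary" else "multiclass"
    metrics_report(type, labs, preds, scores = scores,
                   n_classes = spec$n_classes)
  }
}

.validate_task_dataset <- function(data, spec) {
  if (spec$resolution == "protein") {
    if (!"label" %in% names(data)) stop("protein-level dataset needs a `label` column")
  } else {
    if (!"labels" %in% names(data)) stop("residue-level dataset needs a `labels` column")
    bad <- which(nchar(data$labels) != nchar(data$sequence))
    if (length(bad) > 0)
      stop("residue label string does not match sequence length at row ",
           bad[1])
  }
  invisible(TRUE)
}
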