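# Fine-tuning heads, pooling, prediction shapes, and a quick end-to-end
# learning sanity check on an easy synthetic task.

test_that("protein pooling is a masked arithmetic mean", {
  E <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  expect_equal(pool_protein(E), c(1, 2, 3))
  expect_equal(pool_protein(rbind(c(1, 0), c(0, 1))), c(0.5, 0.5))
  # right-padding never changes the pooled vector
  set.seed(61)
  X <- matrix(rnorm(15), 5, 3)
  Xp <- rbind(X, matrix(99, 4, 3))
  mask <- c(rep(FALSE, 5), rep(TRUE, 4))
  expect_equal(pool_protein(Xp, mask), pool_protein(X))
  expect_error(pool_protein(X, rep(TRUE, 5)), "padding")
})

test_that("task specs enforce the supported task/resolution grid", {
  expect_equal(task_spec("binary", "protein")$n_classes, 2L)
  expect_equal(task_spec("regression", "protein")$n_classes, 1L)
  expect_error(task_spec("regression", "residue"), "not supported")
  expect_error(task_spec("regression", n_classes = 3L), "n_classes = 1")
  expect_error(task_spec("multiclass", "protein"), "n_classes required")
})

test_that("heads add exactly D*K + K parameters and produce the right shapes", {
  m <- build_model(tiny_hyena_config(D = 8L), seed = 62)
  base_n <- count_parameters(m)
  tm <- attach_head(m, task_spec("multiclass", "protein", n_classes = 5L))
  expect_equal(count_parameters(tm), base_n + 8 * 5 + 5)
  # residue binary head on a length-10 sequence: ten score pairs
  tmr <- attach_head(m, task_spec("binary", "residue"))
  pr <- predict_task(tmr, strrep("DNEKV", 2L))
  expect_equal(dim(pr[[1]]$scores), c(10L, 2L))
  expect_equal(rowSums(pr[[1]]$scores), rep(1, 10), tolerance = 1e-9)
  # protein regression head: a single finite scalar per sequence
  tmg <- attach_head(m, task_spec("regression", "protein"))
  pg <- predict_task(tmg, c("DNEKV", "ACDEFGH"))
  expect_length(pg$predictions, 2L)
  expect_true(all(is.finite(pg$predictions)))
  # protein classification: softmax rows normalize
  tmc <- attach_head(m, task_spec("binary", "protein"))
  pc <- predict_task(tmc, c("DNEKV", "ACDEFGH", "WWYY"))
  expect_equal(rowSums(pc$scores), rep(1, 3), tolerance = 1e-9)
})

test_that("datasets are validated against the head's spec", {
  m <- build_model(tiny_hyena_config(D = 8L), seed = 63)
  tm <- attach_head(m, task_spec("binary", "residue"))
  bad <- data.frame(sequence = c("DNEKV", "ACD"), labels = c("01100", "01"),
                    split = "train")
  expect_error(finetune(tm, bad), "row 2")
  tmp <- attach_head(m, task_spec("binary", "protein"))
  expect_error(finetune(tmp, data.frame(sequence = "DNE", split = "train")),
               "`label` column")
})

test_that("fine-tuning learns an easy protein-level motif task end to end", {
  set.seed(64)
  ds <- motif_task(n = 160L, motif = motif_spec(length = 8L,
                                                consensus_prob = 0.95,
                                                seed = 1),
                   class_ratio = 0.5, length_range = c(20L, 40L), seed = 65)
  cfg <- model_config("hyena", n_layers = 1L, embed_dim = 16L, ffn_dim = 32L,
                      max_len = 64L, filter_hidden = 8L, filter_features = 4L)
  m <- build_model(cfg, seed = 66)
  tm <- attach_head(m, task_spec("binary", "protein"), seed = 66)
  tc <- train_config(batch_size = 16L, max_len = 64L, lr = 2e-3,
                     total_steps = 150L, val_fraction = 0, eval_every = 1000L,
                     seed = 67)
  fit <- finetune(tm, ds, tc, epochs = 15L, patience = 5L)
  expect_false(is.null(fit$metrics))
  expect_named(fit$metrics,
               c("accuracy", "f1_macro", "mcc", "auroc", "confusion"))
  expect_gt(fit$metrics$auroc, 0.7)
  # training reduced the loss
  expect_lt(utils::tail(fit$history$train_loss, 1), fit$history$train_loss[1])
})

test_that("freezing the backbone leaves backbone weights untouched", {
  set.seed(68)
  ds <- motif_task(n = 40L, class_ratio = 0.5, length_range = c(15L, 25L),
                   seed = 69)
  m <- build_model(tiny_hyena_config(D = 8L, layers = 1L), seed = 70)
  tm <- attach_head(m, task_spec("binary", "protein"), seed = 70)
  tc <- train_config(batch_size = 8L, max_len = 64L, lr = 1e-3,
                     total_steps = 6L, val_fraction = 0, seed = 71)
  fit <- finetune(tm, ds, tc, epochs = 1L, freeze_backbone = TRUE)
  expect_identical(fit$model$backbone$tok_emb, tm$backbone$tok_emb)
  expect_false(identical(fit$model$head$W, tm$head$W))
})
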