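# Loss definitions, the cosine schedule, perplexity identities, and the
# training loop's reproducibility/memorization behavior.

test_that("nll_loss reproduces closed-form values", {
  # position i predicts token i+1; hand-built conditional distributions
  mk_out <- function(log_probs) list(log_probs = log_probs)
  # certain model: probability 1 on every true next token -> loss 0
  lp <- matrix(-1e9, 2, 28)
  lp[1, 2] <- 0; lp[2, 3] <- 0          # predicts ids 1 then 2
  expect_equal(nll_loss(mk_out(lp), c(0L, 1L, 2L)), 0)
  # uniform over the 20 standard tokens -> ln 20
  lpu <- matrix(log(1 / 20), 4, 28)
  expect_equal(nll_loss(mk_out(lpu), c(0L, 5L, 7L, 9L)), log(20),
               tolerance = 1e-12)
  # hand-computed two-prediction example: probabilities 0.5 and 0.25
  lph <- matrix(log(1e-12), 2, 28)
  lph[1, 4] <- log(0.5); lph[2, 6] <- log(0.25)
  expect_equal(nll_loss(mk_out(lph), c(1L, 3L, 5L)),
               (0.6931472 + 1.3862944) / 2, tolerance = 1e-6)
  expect_error(nll_loss(mk_out(lp), c(0L)), "at least 2 tokens")
})

test_that("the cosine schedule hits its printed anchor points", {
  sc <- train_config(lr = 6e-4, min_lr = 0, total_steps = 30000L,
                     warmup_steps = 0L)
  expect_equal(cosine_lr(0, sc), 6e-4)
  expect_equal(cosine_lr(15000, sc), 3e-4, tolerance = 1e-12)
  expect_equal(cosine_lr(30000, sc), 0, tolerance = 1e-12)
  expect_error(cosine_lr(-1, sc), "nonnegative")
  scw <- train_config(lr = 6e-4, total_steps = 1000L, warmup_steps = 100L)
  expect_equal(cosine_lr(0, scw), 0)
  expect_equal(cosine_lr(50, scw), 3e-4)
  expect_equal(cosine_lr(100, scw), 6e-4)
  # monotone decay after warmup
  lrs <- vapply(100:1000, cosine_lr, numeric(1), schedule = scw)
  expect_true(all(diff(lrs) <= 1e-15))
})

test_that("perplexity is the exponentiated cross entropy, bounded below by 1", {
  m <- build_model(tiny_hyena_config(), seed = 21)
  set.seed(21)
  corpus <- replicate(8, random_aa_string(sample(10:30, 1),
                                          build_vocabulary()$standard_tokens))
  rep_ <- perplexity(m, corpus)
  expect_equal(rep_$PPL, exp(rep_$H), tolerance = 1e-9)
  expect_gte(rep_$PPL, 1)
  expect_error(perplexity(m, character(0)), "empty")
})

test_that("analytic models give PPL 20 (uniform over standard tokens) and 1 (certain)", {
  # uniform over the 20 standard tokens: zero logits for them, -1e4 for rest
  uni <- constant_logit_model(c(rep(0, 20), rep(-1e4, 8)))
  set.seed(22)
  corpus <- replicate(6, random_aa_string(40, build_vocabulary()$standard_tokens))
  expect_equal(perplexity(uni, corpus)$PPL, 20, tolerance = 1e-9)
  # deterministic alternating corpus + a head that always puts probability
  # ~1 on the correct next token (embeddings distinguish current token)
  cfg <- model_config("hyena", n_layers = 1L, embed_dim = 2L, ffn_dim = 2L,
                      max_len = 64L, head_tied = FALSE,
                      filter_hidden = 4L, filter_features = 4L)
  m <- build_model(cfg, seed = 1)
  m <- hyenalm:::.tree_map(m, function(a) a * 0)
  m$lnf_g <- rep(1, 2)
  m$tok_emb[1, ] <- c(1, -1)    # token D
  m$tok_emb[2, ] <- c(-1, 1)    # token N
  head <- matrix(0, 28, 2)
  head[2, ] <- 50 * c(1, -1)    # after D predict N
  head[1, ] <- 50 * c(-1, 1)    # after N predict D
  m$head <- head
  class(m) <- "protein_lm"
  expect_equal(perplexity(m, list(encode(strrep("DN", 20))))$PPL, 1,
               tolerance = 1e-9)
})

test_that("pretraining is reproducible and starts near the uniform loss", {
  set.seed(23)
  corpus <- replicate(24, random_aa_string(sample(8:20, 1),
                                           build_vocabulary()$standard_tokens))
  cfg <- tiny_hyena_config(D = 8L, max_len = 32L)
  m <- build_model(cfg, seed = 3)
  tc <- train_config(batch_size = 8L, max_len = 32L, lr = 3e-3,
                     total_steps = 10L, val_fraction = 0.1, eval_every = 5L,
                     seed = 77)
  f1 <- pretrain(m, corpus, tc)
  f2 <- pretrain(m, corpus, tc)
  expect_identical(f1$log$loss, f2$log$loss)
  expect_identical(f1$params, f2$params)
  # fresh-model loss starts near ln(28) (near-uniform logits at init)
  expect_lt(abs(f1$log$loss[1] - log(28)) / log(28), 0.1)
})

test_that("a tiny model memorizes a small fixed corpus (training PPL < 1.2)", {
  set.seed(24)
  corpus <- replicate(16, random_aa_string(sample(10:16, 1),
                                           build_vocabulary()$standard_tokens))
  cfg <- model_config("hyena", n_layers = 2L, embed_dim = 32L, ffn_dim = 64L,
                      max_len = 32L, filter_hidden = 8L, filter_features = 4L)
  m <- build_model(cfg, seed = 4)
  tc <- train_config(batch_size = 16L, max_len = 32L, lr = 3e-3,
                     total_steps = 500L, warmup_steps = 10L,
                     val_fraction = 0, eval_every = 1000L, seed = 9)
  fit <- pretrain(m, corpus, tc)
  expect_lt(perplexity(fit$params, corpus)$PPL, 1.2)
})
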