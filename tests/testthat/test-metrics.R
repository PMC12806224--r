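test_that("MCC reproduces its analytic values and conventions", {
  expect_equal(mcc(tp = 50, tn = 50, fp = 0, fn = 0), 1)
  expect_equal(mcc(tp = 0, tn = 0, fp = 50, fn = 50), -1)
  expect_equal(mcc(tp = 90, tn = 80, fp = 10, fn = 20),
               7000 / sqrt(100 * 110 * 90 * 100), tolerance = 1e-9)
  expect_equal(mcc(tp = 10, tn = 0, fp = 0, fn = 0), 0)  # degenerate: 0
  expect_error(mcc(0, 0, 0, 0), "zero")
  expect_error(mcc(-1, 2, 3, 4), "nonnegative")
})

test_that("MCC is symmetric under class swap and matches the multiclass generalization", {
  set.seed(51)
  for (i in 1:10) {
    cc <- as.list(sample(0:30, 4, TRUE))
    names(cc) <- c("tp", "tn", "fp", "fn")
    if (sum(unlist(cc)) == 0) next
    expect_equal(do.call(mcc, cc),
                 mcc(tp = cc$tn, tn = cc$tp, fp = cc$fn, fn = cc$fp))
  }
  labs <- c(1, 1, 0, 0, 1, 0); preds <- c(1, 0, 0, 1, 1, 0)
  cc <- confusion_counts(labs, preds)
  expect_equal(mcc_from_predictions(labs, preds),
               mcc(cc$tp, cc$tn, cc$fp, cc$fn))
})

test_that("macro F1 averages per-class F1 with the absent-class convention", {
  expect_equal(f1_macro(c(0, 1, 1), c(0, 1, 1)), 1)
  n <- 10
  labs <- rep(c(0, 1), each = n / 2)
  expect_equal(f1_macro(labs, rep(1, n)), mean(c(0, 2 / 3)))
  # invariant under class relabeling
  set.seed(52)
  labs <- sample(0:2, 30, TRUE); preds <- sample(0:2, 30, TRUE)
  perm <- c(2L, 0L, 1L)
  expect_equal(f1_macro(labs, preds, 3L),
               f1_macro(perm[labs + 1L], perm[preds + 1L], 3L))
  expect_error(f1_macro(1, c(1, 0)), "length mismatch")
})

test_that("AUROC is the pair-winning probability with half-credit ties", {
  expect_equal(auroc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auroc(c(0, 0, 1, 1), c(0.9, 0.8, 0.2, 0.1)), 0)
  expect_equal(auroc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.1)), 0.75)
  expect_equal(auroc(c(1, 0), c(0.5, 0.5)), 0.5)  # tie counts one half
  expect_error(auroc(c(1, 1), c(0.2, 0.3)), "one class")
  # complement under score reversal; invariance under monotone transforms
  set.seed(53)
  labs <- rbinom(50, 1, 0.4); sc <- rnorm(50)
  expect_equal(auroc(labs, sc) + auroc(labs, -sc), 1)
  expect_equal(auroc(labs, sc), auroc(labs, exp(sc)))
})

test_that("AUROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(54)
  for (i in 1:5) {
    labs <- rbinom(60, 1, 0.5)
    if (length(unique(labs)) < 2) next
    sc <- rnorm(60)
    ref <- as.numeric(pROC::auc(pROC::roc(labs, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auroc(labs, sc), ref, tolerance = 1e-10)
  }
})

test_that("AUPRC follows the average-precision formulation", {
  expect_equal(auprc(c(0, 1, 1), c(0.1, 0.8, 0.9)), 1)
  expect_equal(auprc(c(1, rep(0, 9)), c(10, 9:1)), 1)
  expect_error(auprc(c(0, 0), c(0.1, 0.2)), "no positives")
  # random scores give roughly the positive prevalence
  set.seed(55)
  labs <- rbinom(4000, 1, 0.3)
  sc <- runif(4000)
  expect_equal(auprc(labs, sc), mean(labs), tolerance = 0.05)
})

test_that("Spearman correlation is rank-based and monotone-invariant", {
  x <- c(0.3, 1.2, -0.5, 2.0)
  expect_equal(spearman(x, exp(x)), 1)
  expect_equal(spearman(x, -x), -1)
  expect_equal(spearman(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(spearman(rep(1, 5), rnorm(5)), "constant")
  expect_error(spearman(1, 1), "two observations")
  set.seed(56)
  a <- rnorm(40); b <- rnorm(40)
  expect_equal(spearman(a, b), spearman(exp(a), b), tolerance = 1e-12)
})

test_that("regression losses match direct arithmetic and the Student-t loss grows sub-quadratically", {
  z <- regression_losses(c(1, 2), c(1, 2))
  expect_equal(unlist(z), c(mse = 0, mae = 0, student_t = 0))
  r <- regression_losses(c(0, 0), c(1, -1))
  expect_equal(r$mse, 1)
  expect_equal(r$mae, 1)
  expect_equal(r$student_t, log(2), tolerance = 1e-12)
  big <- regression_losses(0, 10)$student_t
  small <- regression_losses(0, 1)$student_t
  expect_lt(big / small, 100)
  expect_error(regression_losses(1:3, 1:2), "length mismatch")
})

test_that("bounded metrics stay in range and near their null values on random predictions", {
  set.seed(57)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    labs <- rbinom(n, 1, runif(1, 0.2, 0.8))
    preds <- rbinom(n, 1, 0.5)
    sc <- runif(n)
    if (length(unique(labs)) < 2) next
    cc <- confusion_counts(labs, preds)
    expect_true(abs(mcc(cc$tp, cc$tn, cc$fp, cc$fn)) <= 1)
    expect_true(f1_macro(labs, preds, 2L) >= 0 && f1_macro(labs, preds, 2L) <= 1)
    expect_true(auroc(labs, sc) >= 0 && auroc(labs, sc) <= 1)
    expect_true(accuracy(labs, preds) >= 0 && accuracy(labs, preds) <= 1)
  }
  # random scores concentrate AUROC near 1/2
  labs <- rbinom(5000, 1, 0.5); sc <- runif(5000)
  expect_lt(abs(auroc(labs, sc) - 0.5), 0.05)
})

test_that("metric reports carry the task-appropriate metric sets", {
  set.seed(58)
  labs <- rbinom(50, 1, 0.5); preds <- rbinom(50, 1, 0.5); sc <- runif(50)
  rb <- metrics_report("binary", labs, preds, scores = sc)
  expect_named(rb, c("accuracy", "f1_macro", "mcc", "auroc", "confusion"))
  labs3 <- sample(0:2, 60, TRUE); preds3 <- sample(0:2, 60, TRUE)
  sc3 <- matrix(runif(180), 60, 3); sc3 <- sc3 / rowSums(sc3)
  rm3 <- metrics_report("multiclass", labs3, preds3, scores = sc3, n_classes = 3L)
  expect_named(rm3, c("accuracy", "f1_macro", "mcc", "auroc", "auprc"))
  rr <- metrics_report("regression", rnorm(30), rnorm(30))
  expect_named(rr, c("spearman", "mse", "mae", "student_t_loss"))
  expect_true(all(is.finite(unlist(rr))))
})
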