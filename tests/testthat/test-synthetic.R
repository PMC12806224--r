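# Seeded generators with known ground truth: Markov sources and their
# entropy rates, motif classification tasks, epistatic landscapes.

test_that("entropy rate is exact for analytic chains", {
  expect_equal(entropy_rate(uniform_source()), log(20), tolerance = 1e-12)
  # two-state chain with stay probability 0.9
  P2 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  src2 <- markov_source(P2, states = c("A", "C"))
  expect_equal(entropy_rate(src2), -(0.9 * log(0.9) + 0.1 * log(0.1)),
               tolerance = 1e-12)
  expect_equal(entropy_rate(src2), 0.3251, tolerance = 1e-4)
  # deterministic cycle has zero entropy
  P3 <- diag(3)[, c(2, 3, 1)]
  expect_equal(entropy_rate(markov_source(P3, states = c("A", "C", "D"))), 0)
  # reducible chains are rejected
  expect_error(markov_source(diag(2), states = c("A", "C")), "reducible")
  expect_error(markov_source(matrix(c(0.5, 0.6, 0.2, 0.8), 2, 2)), "sum to 1")
})

test_that("the entropy rate matches a long-run empirical log-loss estimate", {
  src <- random_markov_source(concentration = 0.5, n_states = 5L, seed = 31)
  set.seed(31)
  n <- 200000L
  P <- src$transition
  states <- integer(n)
  states[1] <- sample.int(5L, 1, prob = src$stationary)
  for (t in 2:n) states[t] <- sample.int(5L, 1, prob = P[states[t - 1], ])
  emp <- -mean(log(P[cbind(states[-n], states[-1])]))
  expect_equal(emp, entropy_rate(src), tolerance = 0.01)
})

test_that("corpus generation is bit-reproducible and carries its oracle", {
  src <- random_markov_source(seed = 32)
  a <- markov_proteome(src, n = 20, length_range = c(10, 30), seed = 5)
  b <- markov_proteome(src, n = 20, length_range = c(10, 30), seed = 5)
  expect_identical(a$records, b$records)
  expect_equal(a$optimal_ppl, exp(src$entropy_rate))
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  markov_proteome(src, n = 20, length_range = c(10, 30), seed = 5, fasta = f1)
  markov_proteome(src, n = 20, length_range = c(10, 30), seed = 5, fasta = f2)
  expect_identical(readLines(f1), readLines(f2))
  side <- jsonlite::read_json(paste0(f1, ".json"))
  expect_equal(side$entropy_rate, src$entropy_rate, tolerance = 1e-12)
  # sequences use only the declared states
  expect_true(all(strsplit(paste(a$records$sequence, collapse = ""), "")[[1]]
                  %in% src$states))
})

test_that("motif tasks hit their class ratios, including the imbalanced presets", {
  for (ratio in c(0.7, 0.8, 0.5)) {
    ds <- motif_task(n = 1000L, class_ratio = ratio, seed = 6)
    expect_equal(sum(ds$label), round(1000 * ratio))
    expect_lt(abs(mean(ds$label) - ratio), 0.02)
  }
  # near-degenerate preset: >= 99% one class
  dd <- motif_task(n = 1000L, class_ratio = 0.99, seed = 7)
  expect_gte(mean(dd$label), 0.99)
  expect_error(motif_task(n = 3L, class_ratio = 0.01, seed = 8),
               "unachievable")
  expect_error(motif_task(n = 100L, class_ratio = 1.2), "class_ratio")
})

test_that("residue-resolution motif labels mark exactly the implanted window", {
  ds <- motif_task(n = 50L, motif = motif_spec(length = 8L, seed = 2),
                   resolution = "residue", seed = 9)
  expect_true(all(nchar(ds$labels) == nchar(ds$sequence)))
  ones <- vapply(strsplit(ds$labels, ""), function(x) sum(x == "1"), numeric(1))
  expect_true(all(ones %in% c(0L, 8L)))
  # positive sequences carry one contiguous run of 1s
  pos <- which(ones == 8L)
  expect_gt(length(pos), 0L)
  runs <- vapply(strsplit(ds$labels[pos], ""), function(x) {
    r <- rle(x); sum(r$values == "1")
  }, numeric(1))
  expect_true(all(runs == 1L))
})

test_that("landscape labels decompose into baseline, additive and epistatic terms", {
  lm0 <- landscape_model(parent_length = 30L, n_epistatic = 0L,
                         noise_sd = 0, seed = 10)
  expect_equal(landscape_label(lm0, lm0$parent), lm0$baseline)
  # single mutation: label = baseline + the corresponding additive effect
  chars <- lm0$parent
  alt <- setdiff(colnames(lm0$additive), chars[4])[1]
  chars[4] <- alt
  expect_equal(landscape_label(lm0, chars),
               unname(lm0$baseline + lm0$additive[4, alt]))
  # additive limit: multi-mutants sum their effects exactly
  chars2 <- lm0$parent
  sites <- c(2L, 9L, 17L)
  total <- lm0$baseline
  for (s in sites) {
    alt <- setdiff(colnames(lm0$additive), lm0$parent[s])[2]
    chars2[s] <- alt
    total <- total + lm0$additive[s, alt]
  }
  expect_equal(landscape_label(lm0, chars2), unname(total))
})

test_that("the distance split produces the intended label distribution shift", {
  lmod <- landscape_model(seed = 11)
  ds <- landscape_task(lmod, n_train = 1500L, n_test = 800L, seed = 12)
  tr <- ds[ds$split %in% c("train", "valid"), ]
  te <- ds[ds$split == "test", ]
  expect_true(all(tr$distance <= 3L))
  expect_true(all(te$distance >= 4L))
  # deleterious additive bias: expected shift = additive_mean * (E d_test - E d_train)
  shift <- mean(tr$label) - mean(te$label)
  expected <- -(-0.4) * (mean(te$distance) - mean(tr$distance))
  expect_equal(shift, expected, tolerance = 0.35)
  expect_gt(shift, 1)
})
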