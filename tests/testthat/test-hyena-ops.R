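# The operator core: Toeplitz reference, FFT path, gating, projections,
# implicit filters, and the order-2 recurrence against its dense matrix form.

test_that("Toeplitz reference reproduces impulse, shift, and a hand-built dense product", {
  set.seed(21)
  L <- 8L; D <- 3L
  v <- matrix(rnorm(L * D), L, D)
  impulse <- c(1, rep(0, L - 1))
  expect_equal(toeplitz_conv_reference(impulse, v), v)
  shift <- c(0, 1, rep(0, L - 2))
  expect_equal(toeplitz_conv_reference(shift, v),
               rbind(0, v[1:(L - 1), ]))
  # independent dense construction, channel by channel
  h <- matrix(rnorm(L * D), L, D)
  want <- matrix(0, L, D)
  for (d in seq_len(D)) {
    Th <- matrix(0, L, L)
    for (i in seq_len(L)) for (j in seq_len(i)) Th[i, j] <- h[i - j + 1, d]
    want[, d] <- Th %*% v[, d]
  }
  expect_equal(toeplitz_conv_reference(h, v), want)
  expect_error(toeplitz_conv_reference(h[1:4, ], v), "taps")
})

test_that("causal FFT convolution matches the Toeplitz oracle across lengths", {
  set.seed(22)
  for (L in c(4L, 16L, 128L, 1024L)) {
    v <- matrix(rnorm(L * 3L), L, 3L)
    h <- matrix(rnorm(L * 3L), L, 3L)
    ref <- toeplitz_conv_reference(h, v)
    fft <- causal_fft_conv(h, v)
    expect_lt(max(abs(fft - ref)) / max(abs(ref)), 1e-5)
  }
  v <- matrix(rnorm(12), 4, 3)
  expect_equal(causal_fft_conv(c(1, 0, 0, 0), v), v, tolerance = 1e-12)
  expect_equal(causal_fft_conv(rep(0, 4), v), matrix(0, 4, 3),
               tolerance = 1e-12)
})

test_that("gating equals per-channel diagonal-matrix multiplication", {
  set.seed(23)
  u <- matrix(rnorm(12), 6, 2)
  x <- matrix(rnorm(12), 6, 2)
  expect_equal(gate(matrix(1, 6, 2), u), u)
  expect_equal(gate(matrix(0, 6, 2), u), matrix(0, 6, 2))
  want <- sapply(1:2, function(d) diag(x[, d]) %*% u[, d])
  expect_equal(gate(x, u), want)
  expect_error(gate(x[1:3, ], u), "shape mismatch")
})

test_that("input projections replicate the input under identity weights and are causal", {
  D <- 4L; N <- 2L; L <- 10L
  p <- hyena_op_params(D, order = N, seed = 31)
  # identity dense weights + delta short-conv kernel
  p$W_in <- do.call(cbind, rep(list(diag(D)), N + 1L))
  p$b_in <- numeric((N + 1L) * D)
  p$k_short <- cbind(1, matrix(0, (N + 1L) * D, 2))
  set.seed(31)
  x <- matrix(rnorm(L * D), L, D)
  pr <- project_inputs(x, p)
  expect_equal(pr$v, x)
  expect_equal(pr$x[[1]], x)
  expect_equal(pr$x[[2]], x)
  # zero input: only the bias pattern flows through the short convolution,
  # so every stream is constant once the causal kernel is fully overlapped
  p2 <- hyena_op_params(D, order = N, seed = 32)
  p2$b_in <- rnorm((N + 1L) * D)
  pr0 <- project_inputs(matrix(0, L, D), p2)
  expect_true(all(abs(sweep(pr0$v[3:L, ], 2, pr0$v[L, ], "-")) < 1e-12))
  expect_equal(pr0$v[L, ], p2$b_in[1:D] * rowSums(p2$k_short)[1:D])
  # causality: perturbing position t changes streams only at positions >= t
  p3 <- hyena_op_params(D, order = N, seed = 33)
  t0 <- 5L
  x2 <- x; x2[t0, ] <- x2[t0, ] + rnorm(D)
  a <- project_inputs(x, p3); b <- project_inputs(x2, p3)
  expect_equal(a$v[1:(t0 - 1L), ], b$v[1:(t0 - 1L), ])
  expect_false(isTRUE(all.equal(a$v[t0:L, ], b$v[t0:L, ])))
  expect_error(project_inputs(cbind(x, 0), p3), "does not match")
})

test_that("implicit filters are deterministic, defined at L = 1, and length-independent in parameter count", {
  p <- hyena_op_params(6L, filter_features = 4L, filter_hidden = 6L, seed = 41)
  f1 <- generate_filters(64L, p)$h
  f2 <- generate_filters(64L, p)$h
  expect_identical(f1, f2)
  expect_equal(dim(f1), c(64L, 12L))
  expect_equal(dim(generate_filters(1L, p)$h), c(1L, 12L))
  # the learnable state does not grow with L: same parameter object serves
  # both lengths, and the filter-network weight count is L-free
  n_params <- count_parameters(p)
  invisible(generate_filters(1024L, p))
  expect_identical(count_parameters(p), n_params)
  expect_equal(count_parameters(p$filt),
               4 * 6 + 6 + 6 * 6 + 6 + 6 * 12 + 12)
})

test_that("the order-2 forward equals the dense matrix form D_x2 T_h2 D_x1 T_h1 v", {
  set.seed(42)
  L <- 8L; D <- 3L
  p <- hyena_op_params(D, order = 2L, seed = 7)
  x <- matrix(rnorm(L * D), L, D)
  y <- hyena_forward(x, p)
  # oracle: explicit dense matrices built from the same projections/filters
  pr <- project_inputs(x, p)
  h <- generate_filters(L, p)$h
  want <- matrix(0, L, D)
  for (d in seq_len(D)) {
    mk_T <- function(hv) {
      Th <- matrix(0, L, L)
      for (i in seq_len(L)) for (j in seq_len(i)) Th[i, j] <- hv[i - j + 1]
      Th
    }
    H1 <- mk_T(h[, d]); H2 <- mk_T(h[, D + d])
    Hm <- diag(pr$x[[2]][, d]) %*% H2 %*% diag(pr$x[[1]][, d]) %*% H1
    want[, d] <- Hm %*% pr$v[, d]
  }
  want <- want %*% p$W_out + rep(p$b_out, each = L)
  expect_equal(y, want, tolerance = 1e-10)
})

test_that("the full operator is causal and linear in the value stream with frozen gates", {
  set.seed(43)
  L <- 16L; D <- 4L
  p <- hyena_op_params(D, seed = 9)
  x <- matrix(rnorm(L * D), L, D)
  for (t0 in c(2L, L %/% 2L, L)) {
    x2 <- x
    x2[t0:L, ] <- x2[t0:L, ] + rnorm((L - t0 + 1L) * D)
    y1 <- hyena_forward(x, p); y2 <- hyena_forward(x2, p)
    expect_equal(y1[1:(t0 - 1L), ], y2[1:(t0 - 1L), ], tolerance = 1e-12)
  }
  # conv + gate are jointly linear in v (superposition)
  h <- generate_filters(L, p)$h[, 1:D]
  g <- matrix(rnorm(L * D), L, D)
  v1 <- matrix(rnorm(L * D), L, D); v2 <- matrix(rnorm(L * D), L, D)
  lhs <- gate(g, causal_fft_conv(h, 2 * v1 + 3 * v2))
  rhs <- 2 * gate(g, causal_fft_conv(h, v1)) + 3 * gate(g, causal_fft_conv(h, v2))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})
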