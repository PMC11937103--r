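test_that("schedules are valid and match a naive cumulative product", {
  s <- make_schedule(1000, "linear")
  expect_length(s$beta, 1000)
  expect_true(all(diff(s$alpha_bar) < 0))
  expect_lt(s$alpha_bar[1000], 0.05)
  expect_true(all(s$beta > 0 & s$beta < 1))

  s2 <- make_schedule(2, "linear")
  expect_equal(s2$alpha_bar[1], s2$alpha[1])
  expect_equal(s2$alpha_bar[2], s2$alpha[1] * s2$alpha[2])

  s3 <- make_schedule(50, "cosine")
  naive <- numeric(50)
  acc <- 1
  for (t in 1:50) { acc <- acc * s3$alpha[t]; naive[t] <- acc }
  expect_equal(s3$alpha_bar, naive, tolerance = 1e-12)
  expect_true(all(diff(s3$alpha_bar) < 0))

  expect_error(make_schedule(1), ">= 2")
  expect_error(make_schedule(10, "exotic"))
})

test_that("forward diffusion obeys the closed-form marginal", {
  s <- make_schedule(50, "linear")
  x0 <- array(runif(64), c(4, 4, 4))
  zero <- array(0, c(4, 4, 4))
  expect_equal(forward_diffuse(x0, 7, zero, s), sqrt(s$alpha_bar[7]) * x0)
  n <- array(rnorm(64), c(4, 4, 4))
  expect_equal(forward_diffuse(zero, 7, n, s), sqrt(1 - s$alpha_bar[7]) * n)
  expect_error(forward_diffuse(x0, 0, n, s), "out of range")
  expect_error(forward_diffuse(x0, 7, array(0, c(2, 2, 2)), s), "shapes")
})

test_that("closed-form marginal matches iterated single-step transitions", {
  # single-step transition: x_t = sqrt(alpha_t) x_{t-1} + sqrt(beta_t) eps_t
  s <- make_schedule(20, "linear", beta_start = 0.01, beta_end = 0.2)
  t_star <- 12
  n_mc <- 10000
  set.seed(42)
  iterated <- vapply(seq_len(n_mc), function(i) {
    x <- 1
    for (t in seq_len(t_star))
      x <- sqrt(s$alpha[t]) * x + sqrt(s$beta[t]) * rnorm(1)
    x
  }, numeric(1))
  closed <- forward_diffuse(rep(1, n_mc), t_star,
                            withr::with_seed(7, rnorm(n_mc)), s)
  m_th <- sqrt(s$alpha_bar[t_star]); v_th <- 1 - s$alpha_bar[t_star]
  se_m <- sqrt(v_th / n_mc)
  expect_lt(abs(mean(iterated) - m_th), 4 * se_m)
  expect_lt(abs(mean(closed) - m_th), 4 * se_m)
  expect_lt(abs(var(iterated) - v_th), 5 * v_th * sqrt(2 / n_mc))
  expect_lt(abs(var(closed) - v_th), 5 * v_th * sqrt(2 / n_mc))
})

test_that("dual-prompt attention reduces and scales per its algebra", {
  set.seed(3)
  Q <- matrix(rnorm(8), 2, 4); Kt <- matrix(rnorm(12), 3, 4)
  Vt <- matrix(rnorm(12), 3, 4)
  Ki <- matrix(rnorm(8), 2, 4); Vi <- matrix(rnorm(8), 2, 4)
  # lambda = 0 collapses to single-prompt attention exactly
  expect_identical(dual_prompt_attention(Q, Kt, Vt, Ki, Vi, 0),
                   attention(Q, Kt, Vt))
  # identical paths at lambda = 1 double the output
  expect_equal(dual_prompt_attention(Q, Kt, Vt, Kt, Vt, 1),
               2 * attention(Q, Kt, Vt))
  # brute-force softmax oracle
  Z <- dual_prompt_attention(Q, Kt, Vt, Ki, Vi, 0.7)
  Zo <- naive_attention(Q, Kt, Vt, 4) + 0.7 * naive_attention(Q, Ki, Vi, 4)
  expect_equal(Z, Zo, tolerance = 1e-6)
  expect_error(attention(Q, Kt[0, ], Vt[0, ]), "empty")
  expect_error(dual_prompt_attention(Q, Kt, Vt, Ki, Vi, -1), ">= 0")
})

test_that("attention output is linear and continuous in the prompt weight", {
  set.seed(8)
  Q <- matrix(rnorm(12), 3, 4); Kt <- matrix(rnorm(8), 2, 4)
  Vt <- matrix(rnorm(8), 2, 4); Ki <- matrix(rnorm(12), 3, 4)
  Vi <- matrix(rnorm(12), 3, 4)
  z0 <- dual_prompt_attention(Q, Kt, Vt, Ki, Vi, 0)
  z1 <- dual_prompt_attention(Q, Kt, Vt, Ki, Vi, 1)
  z05 <- dual_prompt_attention(Q, Kt, Vt, Ki, Vi, 0.5)
  expect_equal(z05, (z0 + z1) / 2, tolerance = 1e-12)
})

test_that("softmax rows always sum to one", {
  set.seed(9)
  for (i in 1:5) {
    x <- matrix(rnorm(12, sd = 10^(i - 3)), 3, 4)
    s <- petdiffuse:::softmax_rows(x)
    expect_equal(rowSums(s), rep(1, 3), tolerance = 1e-6)
  }
})

test_that("adapter initialization copies and then decouples from the source", {
  set.seed(2)
  WK <- matrix(rnorm(16), 4, 4); WV <- matrix(rnorm(16), 4, 4)
  ad <- init_adapter(WK, WV)
  expect_identical(ad$W_K_i, WK)
  expect_identical(ad$W_V_i, WV)
  # a gradient-style update on the adapter leaves the sources untouched
  ad$W_K_i <- ad$W_K_i - 0.1 * matrix(1, 4, 4)
  expect_identical(ad$source_W_K, WK)
  expect_identical(WK + 0, ad$source_W_K)
  # with adapter at init and identical token inputs, both paths agree
  X <- matrix(rnorm(12), 3, 4)
  Q <- matrix(rnorm(8), 2, 4)
  ad2 <- init_adapter(WK, WV)
  base_scores <- Q %*% t(X %*% WK) / sqrt(4)
  img_scores <- Q %*% t(X %*% ad2$W_K_i) / sqrt(4)
  expect_identical(base_scores, img_scores)
  expect_error(init_adapter(WK, WV[, 1:2]), "dimension")
})
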