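test_that("pixel tokenization yields one token per patch", {
  set.seed(1)
  vol <- array(runif(16^3), c(16, 16, 16))
  proj <- list(W_K = matrix(rnorm(512 * 4), 512, 4),
               W_V = matrix(rnorm(512 * 4), 512, 4))
  tok <- pixel_tokens(vol, c(8, 8, 8), proj)
  expect_equal(nrow(tok$K), 8)  # 2x2x2 patch grid
  expect_equal(ncol(tok$K), 4)
  # constant volume -> all patches identical -> identical tokens
  tokc <- pixel_tokens(array(0.4, c(16, 16, 16)), c(8, 8, 8), proj)
  expect_true(all(abs(sweep(tokc$K, 2, tokc$K[1, ])) < 1e-12))
  # index-arithmetic oracle for one patch: patch (2,1,1) spans x in 9:16
  manual <- as.numeric(vol[9:16, 1:8, 1:8]) %*% proj$W_K
  expect_equal(tok$K[2, ], as.numeric(manual), tolerance = 1e-12)
  expect_error(pixel_tokens(vol, c(32, 8, 8), proj), "patch larger")
})

test_that("cross-attention follows the scaled softmax algebra", {
  set.seed(2)
  Q <- matrix(rnorm(8), 2, 4)
  K <- matrix(rnorm(12), 3, 4); V <- matrix(rnorm(12), 3, 4)
  out <- cross_attention(Q, K, V, d_k = 4)
  expect_equal(out, naive_attention(Q, K, V, 4), tolerance = 1e-6)
  # one key: softmax over a single element is 1, every query gets that value
  out1 <- cross_attention(Q, K[1, , drop = FALSE], V[1, , drop = FALSE], 4)
  expect_equal(out1[1, ], V[1, ], tolerance = 1e-12)
  expect_equal(out1[2, ], V[1, ], tolerance = 1e-12)
  # identical queries produce identical rows
  Q2 <- rbind(Q[1, ], Q[1, ])
  out2 <- cross_attention(Q2, K, V, 4)
  expect_identical(out2[1, ], out2[2, ])
})

test_that("fusion is lambda-weighted and bit-independent of PET at zero", {
  set.seed(3)
  am <- matrix(rnorm(20), 5, 4); ap <- matrix(rnorm(20), 5, 4)
  pz <- fusion_init(4, lambda_fusion = 0, seed = 1)
  expect_identical(fuse(am, ap, pz), fuse(am, matrix(99, 5, 4), pz))
  p1 <- fusion_init(4, lambda_fusion = 1, seed = 1)
  # compositional oracle: sum, FFN, mean-pool as separate steps
  ff <- petdiffuse:::ffn_fw(am + 1 * ap, p1)
  expect_equal(fuse(am, ap, p1), colMeans(ff$out), tolerance = 1e-12)
  expect_error(fuse(am, ap[1:3, ], p1), "mismatch")
  expect_error(fusion_init(4, lambda_fusion = -1), ">= 0")
})

test_that("the softmax head is shift-invariant and matches the formula", {
  W <- matrix(c(1, -1, 0.5, 2), 2, 2); b <- c(0.1, -0.2)
  x <- c(0.3, -0.7)
  pred <- classify(x, W, b)
  logits <- as.numeric(x %*% W + b)
  expect_equal(pred$y_hat, exp(logits) / sum(exp(logits)), tolerance = 1e-9)
  expect_equal(sum(pred$y_hat), 1, tolerance = 1e-9)
  pred2 <- classify(x, W, b + 5)  # constant shift of all logits
  expect_equal(pred$y_hat, pred2$y_hat, tolerance = 1e-9)
  # equal logits -> uniform; saturated logits -> near-certainty
  expect_equal(classify(0, matrix(0, 1, 2), c(2, 2))$y_hat, c(0.5, 0.5))
  expect_gt(classify(0, matrix(0, 1, 2), c(10, -10))$y_hat[1], 0.9999)
})

test_that("cross-entropy evaluates the negative log-likelihood", {
  expect_equal(cross_entropy(c(1, 0), 0), 0, tolerance = 1e-10)
  expect_equal(cross_entropy(c(0.5, 0.5), 0), log(2))
  expect_equal(cross_entropy(c(0.5, 0.5), 1), log(2))
  yh <- rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.6, 0.4))
  y <- c(0, 1, 1)
  expect_equal(cross_entropy(yh, y),
               mean(-log(c(0.9, 0.8, 0.4))), tolerance = 1e-12)
  # class weights reweight the mean
  expect_equal(cross_entropy(yh, y, class_weights = c(2, 1)),
               sum(c(2, 1, 1) * -log(c(0.9, 0.8, 0.4))) / 4,
               tolerance = 1e-12)
  expect_warning(cross_entropy(c(1, 0), 1), "clamping")
})

test_that("full forward pass is deterministic and honors ablation flags", {
  model <- tiny_classifier(seed = 3)
  s <- tiny_sample(1)
  p1 <- forward_full(model, s)
  p2 <- forward_full(model, s)
  expect_identical(p1$y_hat, p2$y_hat)
  expect_equal(sum(p1$y_hat), 1, tolerance = 1e-6)

  # w/o PET reference flag is exactly lambda_fusion = 0
  m_flag <- tiny_classifier(seed = 3, ablation = "wo_pet_reference")
  m_hand <- tiny_classifier(seed = 3)
  m_hand$params$fusion$lambda_fusion <- 0
  expect_identical(forward_full(m_flag, s)$y_hat,
                   forward_full(m_hand, s)$y_hat)
  s_pet <- s; s_pet$pet <- array(0.9, dim(s$pet))

  # w/o PL-Bi-cross: mean-pooled Mamba output, invariant to both image banks
  m_nobc <- tiny_classifier(seed = 3, ablation = c("wo_pl_bicross",
                                                   "wo_image"))
  s_mri <- s; s_mri$mri <- array(0.1, dim(s$mri)); s_mri$pet <- s_pet$pet
  expect_identical(forward_full(m_nobc, s)$y_hat,
                   forward_full(m_nobc, s_mri)$y_hat)

  # all streams ablated at once is rejected
  expect_error(tiny_classifier(ablation = c("wo_table", "wo_image")),
               "all input streams")
})

test_that("analytic gradient agrees with central finite differences", {
  model <- tiny_classifier(seed = 3)
  samples <- lapply(1:2, tiny_sample)
  gr <- petdiffuse:::classifier_grad(model, samples, c(1.1, 0.9))
  flat <- petdiffuse:::flatten_params(model$params)
  lossf <- function(fl) {
    m <- model
    m$params <- petdiffuse:::relist_params(m$params, fl)
    classifier_loss(m, samples, c(1.1, 0.9))
  }
  set.seed(10)
  num <- c(); ana <- c()
  for (nm in names(gr$grads)) {
    g <- gr$grads[[nm]]
    for (i in sample(length(g), min(3, length(g)))) {
      e <- 1e-5
      f2 <- flat; f2[[nm]][i] <- f2[[nm]][i] + e; lp <- lossf(f2)
      f2[[nm]][i] <- f2[[nm]][i] - 2 * e; lm <- lossf(f2)
      num <- c(num, (lp - lm) / (2 * e))
      ana <- c(ana, g[i])
    }
  }
  expect_lt(sqrt(sum((num - ana)^2)) / max(sqrt(sum(num^2)), 1e-12), 1e-4)
})
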