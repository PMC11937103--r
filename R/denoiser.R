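# Conditional denoiser for MRI->PET diffusion. A compact from-scratch network
# with one dual-prompt cross-attention site: queries come from MRI patches
# plus a per-step embedding, the base ("text") path attends to a learned null
# prompt token per class through frozen base projections, and the image path
# attends to MRI-encoder tokens through adapter projections initialized from
# the base projections. The network predicts epsilon via the standard
# x0-parameterization: it forms an estimate x0_hat of the clean PET from the
# MRI-conditioned features (voxelwise affine + learned spatial bias + decoded
# attention tokens) and converts it to a noise prediction at step t with the
# schedule, eps_hat = (x_t - sqrt(ab_t) x0_hat) / sqrt(1 - ab_t). Training
# minimizes epsilon-prediction mean-squared error.

#' Initialize a conditional diffusion denoiser
#'
#' @param shape volume shape (each dimension divisible by `patch_size`).
#' @param schedule a `pd_schedule` (supplies the number of step embeddings).
#' @param d_attn attention/token dimension.
#' @param patch_size patch shape for the attention tokens.
#' @param lambda_prompt image-prompt weight in the dual-prompt attention.
#' @param n_class number of class-conditioned null prompt tokens.
#' @param seed integer seed for weight initialization.
#' @return object of class `pd_denoiser`.
#' @export
denoiser_init <- function(shape, schedule, d_attn = 32L,
                          patch_size = c(8L, 8L, 8L), lambda_prompt = 1,
                          n_class = 1L, seed = 1L) {
  plen <- prod(patch_size)
  params <- with_seed(seed, {
    W_K_src <- rand_mat(d_attn, d_attn)
    W_V_src <- rand_mat(d_attn, d_attn)
    ad <- init_adapter(W_K_src, W_V_src)
    list(s = 0.5, u = 0,
         beta_field = array(0, dim = shape),
         P_base = rand_mat(n_class, d_attn),
         W_K_src = W_K_src, W_V_src = W_V_src,
         W_K_i = ad$W_K_i, W_V_i = ad$W_V_i,
         W_enc = rand_mat(plen, d_attn),
         W_q = rand_mat(plen, d_attn),
         E_t = rand_mat(schedule$T, d_attn, scale = 0.1),
         W_dec = rand_mat(d_attn, plen, scale = 0.01))
  })
  structure(list(params = params,
                 config = list(shape = shape, d_attn = d_attn,
                               patch_size = patch_size,
                               lambda_prompt = lambda_prompt,
                               n_class = n_class),
                 schedule = schedule,
                 frozen = c("W_K_src", "W_V_src")),
            class = "pd_denoiser")
}

# Forward pass. Returns eps_hat; with cache=TRUE also every intermediate
# needed by denoiser_backward().
denoiser_forward <- function(dn, x_t, t, mri, class_id = 1L, cache = FALSE) {
  p <- dn$params; cf <- dn$config; sch <- dn$schedule
  ab <- sch$alpha_bar[t]
  P_mri <- patchify(mri, cf$patch_size)
  X_img <- P_mri %*% p$W_enc
  Pb <- p$P_base[class_id, , drop = FALSE]
  K_t <- Pb %*% p$W_K_src; V_t <- Pb %*% p$W_V_src
  K_i <- X_img %*% p$W_K_i; V_i <- X_img %*% p$W_V_i
  Q <- P_mri %*% p$W_q + matrix(p$E_t[t, ], nrow(P_mri), cf$d_attn, byrow = TRUE)
  sc <- 1 / sqrt(cf$d_attn)
  S1 <- softmax_rows(Q %*% t(K_t) * sc)
  S2 <- softmax_rows(Q %*% t(K_i) * sc)
  Z <- S1 %*% V_t + cf$lambda_prompt * (S2 %*% V_i)
  Dp <- Z %*% p$W_dec
  x0_hat <- p$s * mri + p$u + p$beta_field +
    unpatchify(Dp, cf$shape, cf$patch_size)
  eps_hat <- (x_t - sqrt(ab) * x0_hat) / sqrt(1 - ab)
  if (!cache) return(eps_hat)
  list(eps_hat = eps_hat, x0_hat = x0_hat, ab = ab, P_mri = P_mri,
       X_img = X_img, Pb = Pb, K_t = K_t, V_t = V_t, K_i = K_i, V_i = V_i,
       Q = Q, S1 = S1, S2 = S2, Z = Z, sc = sc, t = t, class_id = class_id,
       mri = mri)
}

# Backward pass of the epsilon MSE loss for one sample. `fw` is the cache
# from denoiser_forward(..., cache = TRUE); `eps` the true injected noise.
# Returns list(loss, grads).
denoiser_backward <- function(dn, fw, eps) {
  p <- dn$params; cf <- dn$config
  n_vox <- length(eps)
  resid <- fw$eps_hat - eps
  loss <- mean(resid^2)
  d_eps_hat <- 2 * resid / n_vox
  d_x0 <- -sqrt(fw$ab) / sqrt(1 - fw$ab) * d_eps_hat

  g <- list()
  g$s <- sum(d_x0 * fw$mri)
  g$u <- sum(d_x0)
  g$beta_field <- d_x0
  dDp <- patchify(d_x0, cf$patch_size)
  g$W_dec <- t(fw$Z) %*% dDp
  dZ <- dDp %*% t(p$W_dec)

  bw_attn <- function(dZk, S, K, V, Q, sc) {
    dV <- t(S) %*% dZk
    dS <- dZk %*% t(V)
    dA <- (dS - rowSums(dS * S)) * S * sc
    list(dQ = dA %*% K, dK = t(dA) %*% Q, dV = dV)
  }
  a1 <- bw_attn(dZ, fw$S1, fw$K_t, fw$V_t, fw$Q, fw$sc)
  a2 <- bw_attn(cf$lambda_prompt * dZ, fw$S2, fw$K_i, fw$V_i, fw$Q, fw$sc)

  dQ <- a1$dQ + a2$dQ
  g$W_q <- t(fw$P_mri) %*% dQ
  g$E_t <- p$E_t * 0
  g$E_t[fw$t, ] <- colSums(dQ)

  # base path
  g$W_K_src <- t(fw$Pb) %*% a1$dK
  g$W_V_src <- t(fw$Pb) %*% a1$dV
  dPb <- a1$dK %*% t(p$W_K_src) + a1$dV %*% t(p$W_V_src)
  g$P_base <- p$P_base * 0
  g$P_base[fw$class_id, ] <- dPb

  # image (adapter) path
  g$W_K_i <- t(fw$X_img) %*% a2$dK
  g$W_V_i <- t(fw$X_img) %*% a2$dV
  dX <- a2$dK %*% t(p$W_K_i) + a2$dV %*% t(p$W_V_i)
  g$W_enc <- t(fw$P_mri) %*% dX

  list(loss = loss, grads = g)
}

sum_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

#' Train the conditional denoiser by epsilon-prediction MSE
#'
#' Each step draws a minibatch of (volume pair, step t, noise) triples, noises
#' the PET with the closed-form forward marginal, and takes an AdamW step on
#' the epsilon MSE. The base-path projections stay frozen; the adapter,
#' encoder, query, decoder and prompt parameters train. The returned loss
#' trace is deterministic given (inputs, seed, initialization).
#'
#' @param pairs list of `pd_volume_pair` (or lists with `mri`, `pet`).
#' @param schedule a `pd_schedule`.
#' @param steps number of optimization steps.
#' @param batch_size minibatch size.
#' @param lr initial learning rate.
#' @param weight_decay decoupled weight decay.
#' @param lr_schedule `"cosine_annealing"` or `"constant"`.
#' @param d_attn,patch_size,lambda_prompt,n_class denoiser architecture knobs.
#' @param class_ids optional integer class per pair (conditions the null
#'   prompt token); defaults to 1.
#' @param seed integer seed.
#' @param init optional pre-initialized `pd_denoiser` to continue training.
#' @return the trained `pd_denoiser` with an added `loss_trace` element.
#' @export
train_denoiser <- function(pairs, schedule, steps = 300L, batch_size = 4L,
                           lr = 1e-4, weight_decay = 0.01,
                           lr_schedule = c("cosine_annealing", "constant"),
                           d_attn = 32L, patch_size = c(8L, 8L, 8L),
                           lambda_prompt = 1, n_class = 1L,
                           class_ids = NULL, seed = 1L, init = NULL) {
  assert_that(length(pairs) >= 2, "need at least 2 paired volumes")
  lr_schedule <- match.arg(lr_schedule)
  shape <- dim(pairs[[1]]$mri)
  for (pr in pairs)
    assert_that(identical(dim(pr$mri), dim(pr$pet)) &&
                  identical(dim(pr$mri), shape), "unpaired/mismatched volumes")
  if (is.null(class_ids)) class_ids <- rep(1L, length(pairs))

  dn <- if (is.null(init)) {
    denoiser_init(shape, schedule, d_attn, patch_size, lambda_prompt,
                  n_class, seed = seed)
  } else init
  state <- adam_init(dn$params)
  trace <- numeric(steps)

  with_seed(seed + 1L, {
    for (st in seq_len(steps)) {
      idx <- sample.int(length(pairs), batch_size, replace = TRUE)
      ts <- sample.int(schedule$T, batch_size, replace = TRUE)
      acc <- NULL; lsum <- 0
      for (b in seq_len(batch_size)) {
        pr <- pairs[[idx[b]]]
        eps <- array(stats::rnorm(prod(shape)), dim = shape)
        x_t <- forward_diffuse(pr$pet, ts[b], eps, schedule)
        fw <- denoiser_forward(dn, x_t, ts[b], pr$mri,
                               class_id = class_ids[idx[b]], cache = TRUE)
        bw <- denoiser_backward(dn, fw, eps)
        assert_that(is.finite(bw$loss), "non-finite training loss; aborting")
        lsum <- lsum + bw$loss
        acc <- sum_grads(acc, bw$grads)
      }
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / batch_size
      for (nm in dn$frozen) acc[[nm]] <- NULL
      lr_t <- if (lr_schedule == "cosine_annealing")
        cosine_lr(lr, st, steps) else lr
      upd <- adam_step(dn$params, acc, state, lr_t,
                       weight_decay = weight_decay)
      dn$params <- upd$params; state <- upd$state
      trace[st] <- lsum / batch_size
    }
  })
  dn$loss_trace <- trace
  dn
}

#' One-step clean-signal estimate from a noise prediction
#'
#' Inverts the forward marginal: `x0 = (x_t - sqrt(1 - ab_t) * eps) /
#' sqrt(ab_t)`.
#'
#' @param x_t noised signal at step `t`.
#' @param t step index.
#' @param eps noise estimate.
#' @param schedule a `pd_schedule`.
#' @return estimate of the clean signal.
#' @export
x0_from_eps <- function(x_t, t, eps, schedule) {
  ab <- schedule$alpha_bar[t]
  (x_t - sqrt(1 - ab) * eps) / sqrt(ab)
}

#' Sample a PET volume from MRI by reverse diffusion
#'
#' Runs the ancestral reverse chain from seeded Gaussian noise, conditioning
#' on the MRI through the denoiser. With `n_candidates > 1` and a reference
#' `Z_GT`, the candidate maximizing SSIM against the reference is returned
#' (validation-time selection; at deployment no reference exists and
#' `n_candidates = 1` is the sensible setting).
#'
#' @param mri conditioning MRI volume.
#' @param denoiser a `pd_denoiser`, or a function `(x_t, t, mri) -> eps_hat`
#'   (oracle injection).
#' @param schedule a `pd_schedule`.
#' @param n_candidates number of independent reverse chains (>= 1).
#' @param seed integer seed.
#' @param Z_GT optional ground-truth PET for SSIM scoring/selection.
#' @param class_id class index for the null prompt token.
#' @return list of class `pd_generated` with `pet`, `ssim_score` (NA without
#'   `Z_GT`), `candidate_scores`.
#' @export
sample_pet <- function(mri, denoiser, schedule, n_candidates = 1L, seed = 1L,
                       Z_GT = NULL, class_id = 1L) {
  assert_that(n_candidates >= 1, "`n_candidates` must be >= 1")
  if (inherits(denoiser, "pd_denoiser"))
    assert_that(denoiser$schedule$T == schedule$T,
                "schedule/denoiser step-count mismatch")
  eps_fn <- if (is.function(denoiser)) denoiser else
    function(x_t, t, mri) denoiser_forward(denoiser, x_t, t, mri,
                                           class_id = class_id)
  shape <- dim(mri)
  run_chain <- function() {
    x <- array(stats::rnorm(prod(shape)), dim = shape)
    for (t in seq(schedule$T, 1L)) {
      ab <- schedule$alpha_bar[t]
      ab_prev <- if (t > 1L) schedule$alpha_bar[t - 1L] else 1
      beta_t <- schedule$beta[t]; alpha_t <- schedule$alpha[t]
      eps_hat <- eps_fn(x, t, mri)
      assert_finite(eps_hat, "eps_hat")
      x0 <- clip01(x0_from_eps(x, t, eps_hat, schedule))
      mean_t <- (sqrt(ab_prev) * beta_t / (1 - ab)) * x0 +
        (sqrt(alpha_t) * (1 - ab_prev) / (1 - ab)) * x
      if (t > 1L) {
        sigma <- sqrt(beta_t * (1 - ab_prev) / (1 - ab))
        x <- mean_t + sigma * array(stats::rnorm(prod(shape)), dim = shape)
      } else {
        x <- mean_t
      }
    }
    clip01(x)
  }
  with_seed(seed, {
    cands <- lapply(seq_len(n_candidates), function(i) run_chain())
    scores <- if (!is.null(Z_GT))
      vapply(cands, function(c) ssim(c, Z_GT), numeric(1)) else
        rep(NA_real_, n_candidates)
    best <- if (!is.null(Z_GT)) which.max(scores) else 1L
    structure(list(pet = cands[[best]],
                   ssim_score = scores[best],
                   candidate_scores = scores),
              class = "pd_generated")
  })
}
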