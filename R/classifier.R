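# Full multimodal classifier: token assembly -> Mamba stack -> pixel-level
# bi-cross attention -> FFN fusion -> softmax head, with analytic gradients
# end to end and ablation switches that each bypass exactly one component.

# ---- nested parameter <-> flat list plumbing (for the optimizer) ----------

is_leaf <- function(x) is.numeric(x)

flatten_params <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    path <- if (prefix == "") nm else paste(prefix, nm, sep = "|")
    if (is_leaf(x[[nm]])) out[[path]] <- x[[nm]]
    else out <- c(out, flatten_params(x[[nm]], path))
  }
  out
}

relist_params <- function(skel, flat, prefix = "") {
  for (nm in names(skel)) {
    path <- if (prefix == "") nm else paste(prefix, nm, sep = "|")
    if (is_leaf(skel[[nm]])) {
      if (!is.null(flat[[path]])) skel[[nm]] <- flat[[path]]
    } else {
      skel[[nm]] <- relist_params(skel[[nm]], flat, path)
    }
  }
  skel
}

#' Initialize the multimodal conversion classifier
#'
#' @param cat_levels integer vector: number of levels of each categorical
#'   feature (p features).
#' @param q number of numeric features.
#' @param shape volume shape.
#' @param d_model token dimension of the assembly and Mamba stack.
#' @param n_blocks number of Mamba blocks.
#' @param d_state SSM state dimension.
#' @param d_k bi-cross attention key dimension.
#' @param patch_size image patch shape (on the original volume grid).
#' @param pool fixed average-pooling factor applied to the volumes before
#'   patch tokenization; the planted signal lives at coarse scale, so
#'   pooling shrinks the patch projectors without losing it.
#' @param lambda_fusion PET-branch balance factor.
#' @param gate_mode Mamba gating variant, see [mamba_block_init()].
#' @param ablation character vector among `"wo_table"`, `"wo_image"`,
#'   `"wo_pl_bicross"`, `"wo_pet_reference"`; each bypasses exactly its
#'   component (`"wo_pet_reference"` sets `lambda_fusion = 0`).
#' @param seed integer seed.
#' @return object of class `pd_classifier`.
#' @export
classifier_init <- function(cat_levels = c(2L, 3L), q = 3L,
                            shape = c(16L, 16L, 16L), d_model = 32L,
                            n_blocks = 2L, d_state = 8L, d_k = 32L,
                            patch_size = c(8L, 8L, 8L), pool = 2L,
                            lambda_fusion = 1,
                            gate_mode = "self", ablation = character(0),
                            seed = 1L) {
  ok_flags <- c("wo_table", "wo_image", "wo_pl_bicross", "wo_pet_reference",
                "wo_addiffusion")
  assert_that(all(ablation %in% ok_flags),
              paste("unknown ablation flag; use", paste(ok_flags, collapse = ", ")))
  assert_that(!("wo_table" %in% ablation && "wo_image" %in% ablation),
              "cannot ablate all input streams simultaneously")
  if ("wo_pet_reference" %in% ablation) lambda_fusion <- 0
  assert_that(all(patch_size %% pool == 0) && all(shape %% pool == 0),
              "`pool` must divide patch_size and shape")
  plen <- prod(patch_size %/% pool)
  head_dim <- if ("wo_pl_bicross" %in% ablation) d_model else d_k

  params <- with_seed(seed, {
    p <- list()
    for (j in seq_along(cat_levels))
      p[[paste0("emb", j)]] <- rand_mat(cat_levels[j] + 1L, d_model)
    p$W_num <- rand_mat(q, d_model)
    p$b_num <- matrix(0, q, d_model)
    p$W_img_tok <- rand_mat(plen, d_model)      # MRI assembly tokens
    p$W_img_tok_pet <- rand_mat(plen, d_model)  # PET assembly tokens
    p$W_qf <- rand_mat(d_model, d_k)
    p$W_K_mri <- rand_mat(plen, d_k); p$W_V_mri <- rand_mat(plen, d_k)
    p$W_K_pet <- rand_mat(plen, d_k); p$W_V_pet <- rand_mat(plen, d_k)
    p
  })
  params$blocks <- lapply(seq_len(n_blocks), function(i)
    mamba_block_init(d_model, d_state = d_state, gate_mode = gate_mode,
                     seed = seed + 100L * i))
  names(params$blocks) <- paste0("b", seq_len(n_blocks))
  params$fusion <- fusion_init(head_dim, lambda_fusion = lambda_fusion,
                               seed = seed + 7L)

  structure(list(params = params,
                 config = list(cat_levels = cat_levels, q = q, shape = shape,
                               d_model = d_model, n_blocks = n_blocks,
                               d_state = d_state, d_k = d_k,
                               patch_size = patch_size, pool = pool,
                               gate_mode = gate_mode, ablation = ablation),
                 frozen = "fusion|lambda_fusion"),
            class = "pd_classifier")
}

# Forward pass for one sample. `sample` is a list with x_cat (integer p-vector,
# NA = missing), x_num (standardized q-vector), mri, pet (arrays).
clf_forward <- function(model, sample, cache = FALSE) {
  p <- model$params; cf <- model$config
  abl <- cf$ablation
  blocks_cat <- NULL; blocks_num <- NULL; blocks_img <- NULL
  ps <- cf$patch_size %/% cf$pool
  P_mri <- patchify(downsample_volume(sample$mri, cf$pool), ps)
  P_pet <- patchify(downsample_volume(sample$pet, cf$pool), ps)
  if (!is.null(model$img_stats)) {
    # fixed intensity normalization with training-split statistics
    P_mri <- (P_mri - model$img_stats$mean_mri) / model$img_stats$sd_mri
    P_pet <- (P_pet - model$img_stats$mean_pet) / model$img_stats$sd_pet
  }
  if (!("wo_table" %in% abl)) {
    blocks_cat <- do.call(rbind, lapply(seq_along(cf$cat_levels), function(j)
      embed_categorical(sample$x_cat[j], p[[paste0("emb", j)]])))
    blocks_num <- transform_numeric(sample$x_num, p$W_num, p$b_num)
  }
  if (!("wo_image" %in% abl))
    blocks_img <- rbind(P_mri %*% p$W_img_tok, P_pet %*% p$W_img_tok_pet)
  z <- assemble_multimodal(blocks_cat, blocks_num, blocks_img)

  st <- mamba_stack_fw(unclass_matrix(z), p$blocks)
  X <- st$out; L <- nrow(X)

  if ("wo_pl_bicross" %in% abl) {
    x_final <- colMeans(X)
    pred <- classify(x_final, p$fusion$W_out, p$fusion$b_out)
    if (!cache) return(pred)
    return(list(pred = pred, z = z, st = st, X = X, P_mri = P_mri,
                P_pet = P_pet, mode = "pooled"))
  }

  Q <- X %*% p$W_qf
  sc <- 1 / sqrt(cf$d_k)
  K_m <- P_mri %*% p$W_K_mri; V_m <- P_mri %*% p$W_V_mri
  S_m <- softmax_rows(Q %*% t(K_m) * sc); A_m <- S_m %*% V_m
  lam <- p$fusion$lambda_fusion
  if (lam != 0) {
    K_p <- P_pet %*% p$W_K_pet; V_p <- P_pet %*% p$W_V_pet
    S_p <- softmax_rows(Q %*% t(K_p) * sc); A_p <- S_p %*% V_p
    Fsum <- A_m + lam * A_p
  } else {
    K_p <- NULL; V_p <- NULL; S_p <- NULL; A_p <- NULL
    Fsum <- A_m
  }
  ff <- ffn_fw(Fsum, p$fusion)
  x_final <- colMeans(ff$out)
  pred <- classify(x_final, p$fusion$W_out, p$fusion$b_out)
  if (!cache) return(pred)
  list(pred = pred, z = z, st = st, X = X, P_mri = P_mri, P_pet = P_pet,
       Q = Q, sc = sc, K_m = K_m, V_m = V_m, S_m = S_m, A_m = A_m,
       K_p = K_p, V_p = V_p, S_p = S_p, A_p = A_p, ff = ff, mode = "bicross")
}

unclass_matrix <- function(z) {
  attributes(z) <- list(dim = dim(z))
  z
}

# Backward for one sample; returns list(loss, grads) with grads in the nested
# layout of model$params. `w` is the sample's class weight.
clf_backward <- function(model, sample, fw, y, w = 1) {
  p <- model$params; cf <- model$config
  abl <- cf$ablation
  y_hat <- fw$pred$y_hat
  loss <- w * (-log(max(y_hat[y + 1L], 1e-12)))
  dlogits <- w * y_hat
  dlogits[y + 1L] <- dlogits[y + 1L] - w

  g <- list(fusion = list())
  x_final <- fw$pred$x_final
  g$fusion$W_out <- outer(x_final, dlogits)
  g$fusion$b_out <- dlogits
  dx_final <- as.numeric(p$fusion$W_out %*% dlogits)

  if (fw$mode == "pooled") {
    L <- nrow(fw$X)
    dX <- matrix(dx_final, L, length(dx_final), byrow = TRUE) / L
  } else {
    L <- nrow(fw$ff$out)
    dG <- matrix(dx_final, L, length(dx_final), byrow = TRUE) / L
    fb <- ffn_bw(p$fusion, fw$ff, dG)
    g$fusion$W1 <- fb$grads$W1; g$fusion$b1 <- fb$grads$b1
    g$fusion$W2 <- fb$grads$W2; g$fusion$b2 <- fb$grads$b2
    dF <- fb$dx
    lam <- p$fusion$lambda_fusion

    bw_attn <- function(dA, S, K, V, Q, sc) {
      dV <- t(S) %*% dA
      dS <- dA %*% t(V)
      dAl <- (dS - rowSums(dS * S)) * S * sc
      list(dQ = dAl %*% K, dK = t(dAl) %*% Q, dV = dV)
    }
    am <- bw_attn(dF, fw$S_m, fw$K_m, fw$V_m, fw$Q, fw$sc)
    g$W_K_mri <- t(fw$P_mri) %*% am$dK
    g$W_V_mri <- t(fw$P_mri) %*% am$dV
    dQ <- am$dQ
    if (lam != 0) {
      ap <- bw_attn(lam * dF, fw$S_p, fw$K_p, fw$V_p, fw$Q, fw$sc)
      g$W_K_pet <- t(fw$P_pet) %*% ap$dK
      g$W_V_pet <- t(fw$P_pet) %*% ap$dV
      dQ <- dQ + ap$dQ
    }
    g$W_qf <- t(fw$X) %*% dQ
    dX <- dQ %*% t(p$W_qf)
  }

  sb <- mamba_stack_bw(p$blocks, fw$st$caches, dX)
  g$blocks <- sb$grads
  names(g$blocks) <- names(p$blocks)
  dz <- sb$dx

  # split the assembly gradient back into streams
  np <- attr(fw$z, "p"); nq <- attr(fw$z, "q")
  row0 <- 0L
  if (!("wo_table" %in% abl)) {
    for (j in seq_along(cf$cat_levels)) {
      tab <- p[[paste0("emb", j)]]
      gt <- tab * 0
      idx <- ifelse(is.na(sample$x_cat[j]), 0L, sample$x_cat[j]) + 1L
      gt[idx, ] <- dz[row0 + j, ]
      g[[paste0("emb", j)]] <- gt
    }
    row0 <- row0 + np
    dznum <- dz[row0 + seq_len(nq), , drop = FALSE]
    g$W_num <- as.numeric(sample$x_num) * dznum
    g$b_num <- dznum
    row0 <- row0 + nq
  }
  if (!("wo_image" %in% abl)) {
    r <- nrow(dz) - row0
    rh <- r %/% 2L
    g$W_img_tok <- t(fw$P_mri) %*% dz[row0 + seq_len(rh), , drop = FALSE]
    g$W_img_tok_pet <-
      t(fw$P_pet) %*% dz[row0 + rh + seq_len(rh), , drop = FALSE]
  }
  list(loss = loss, grads = g)
}

#' Full multimodal forward pass
#'
#' Runs the token assembly through the Mamba stack, the pixel-level bi-cross
#' attention fusion, and the softmax head. Each ablation flag configured in
#' [classifier_init()] bypasses exactly its component.
#'
#' @param model a `pd_classifier`.
#' @param sample list with `x_cat` (integer indices, `NA` = missing), `x_num`
#'   (standardized numeric vector), `mri`, `pet` (3-D arrays).
#' @return a `pd_prediction`.
#' @export
forward_full <- function(model, sample) {
  clf_forward(model, sample, cache = FALSE)
}

#' Mean cross-entropy of the classifier over samples (optionally weighted)
#' @param model a `pd_classifier`.
#' @param samples list of samples (see [forward_full()]); each must carry `y`.
#' @param class_weights optional length-2 weights.
#' @return scalar loss.
#' @export
classifier_loss <- function(model, samples, class_weights = NULL) {
  tot <- 0; wtot <- 0
  for (s in samples) {
    pred <- clf_forward(model, s)
    w <- if (is.null(class_weights)) 1 else class_weights[s$y + 1L]
    tot <- tot + w * (-log(max(pred$y_hat[s$y + 1L], 1e-12)))
    wtot <- wtot + w
  }
  tot / wtot
}

# Analytic gradient of classifier_loss in flat layout (used by the
# gradient-sanity check and the trainer).
classifier_grad <- function(model, samples, class_weights = NULL) {
  acc <- NULL; wtot <- 0; ltot <- 0
  for (s in samples) {
    fw <- clf_forward(model, s, cache = TRUE)
    w <- if (is.null(class_weights)) 1 else class_weights[s$y + 1L]
    bw <- clf_backward(model, s, fw, s$y, w)
    ltot <- ltot + bw$loss; wtot <- wtot + w
    flat <- flatten_params(bw$grads)
    acc <- if (is.null(acc)) flat else {
      for (nm in names(flat)) acc[[nm]] <-
          if (is.null(acc[[nm]])) flat[[nm]] else acc[[nm]] + flat[[nm]]
      acc
    }
  }
  for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / wtot
  list(loss = ltot / wtot, grads = acc)
}

#' Train the multimodal conversion classifier
#'
#' Minibatch AdamW on the class-weighted cross-entropy; weights are inverse
#' prevalence on the training split (on by default).
#'
#' @param samples list of training samples, each with `x_cat`, `x_num`,
#'   `mri`, `pet`, `y`.
#' @param model a `pd_classifier` from [classifier_init()].
#' @param epochs passes over the training set.
#' @param batch_size minibatch size.
#' @param lr initial learning rate.
#' @param weight_decay decoupled weight decay.
#' @param lr_schedule `"cosine_annealing"` or `"constant"`.
#' @param class_weighting use inverse-prevalence class weights.
#' @param val_samples optional held-out samples; validation accuracy is
#'   recorded per epoch.
#' @param average_tail number of final epochs over which to average the
#'   weights (Polyak-style tail averaging; 0 disables). Averaged weights
#'   replace the final iterate and typically generalize better.
#' @param seed integer seed for shuffling.
#' @return the trained `pd_classifier` with `history` (per-epoch mean train
#'   loss and validation accuracy).
#' @export
train_classifier <- function(samples, model, epochs = 20L, batch_size = 32L,
                             lr = 1e-4, weight_decay = 0.01,
                             lr_schedule = c("cosine_annealing", "constant"),
                             class_weighting = TRUE, val_samples = NULL,
                             average_tail = 10L, seed = 1L) {
  lr_schedule <- match.arg(lr_schedule)
  ys <- vapply(samples, `[[`, numeric(1), "y")
  if (is.null(model$img_stats)) {
    cf <- model$config
    ps <- cf$patch_size %/% cf$pool
    pm <- lapply(samples, function(s)
      patchify(downsample_volume(s$mri, cf$pool), ps))
    pp <- lapply(samples, function(s)
      patchify(downsample_volume(s$pet, cf$pool), ps))
    Am <- do.call(rbind, pm); Ap <- do.call(rbind, pp)
    model$img_stats <- list(
      mean_mri = mean(Am), sd_mri = max(stats::sd(Am), 1e-8),
      mean_pet = mean(Ap), sd_pet = max(stats::sd(Ap), 1e-8))
  }
  cw <- if (class_weighting) {
    n <- length(ys)
    c(n / (2 * max(sum(ys == 0), 1)), n / (2 * max(sum(ys == 1), 1)))
  } else NULL

  flat <- flatten_params(model$params)
  state <- adam_init(flat)
  n_steps_total <- epochs * ceiling(length(samples) / batch_size)
  step <- 0L
  avg <- NULL; n_avg <- 0L
  tail_from <- epochs - min(average_tail, epochs) + 1L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_accuracy = numeric(0))
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(samples))
      ep_loss <- 0; n_batch <- 0L
      for (b0 in seq(1, length(ord), by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1L, length(ord))]
        gr <- classifier_grad(model, samples[idx], cw)
        for (nm in model$frozen) gr$grads[[nm]] <- NULL
        step <- step + 1L
        lr_t <- if (lr_schedule == "cosine_annealing")
          cosine_lr(lr, step, n_steps_total) else lr
        upd <- adam_step(flat, gr$grads, state, lr_t,
                         weight_decay = weight_decay)
        flat <- upd$params; state <- upd$state
        model$params <- relist_params(model$params, flat)
        ep_loss <- ep_loss + gr$loss; n_batch <- n_batch + 1L
      }
      if (average_tail > 0L && ep >= tail_from) {
        n_avg <- n_avg + 1L
        avg <- if (is.null(avg)) flat else
          mapply(function(a, b) a + (b - a) / n_avg, avg, flat,
                 SIMPLIFY = FALSE)
      }
      vacc <- if (!is.null(val_samples))
        classifier_accuracy(model, val_samples) else NA_real_
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / n_batch,
                                     val_accuracy = vacc))
    }
  })
  if (!is.null(avg)) {
    model$params <- relist_params(model$params, avg)
    if (!is.null(val_samples)) {
      hist <- rbind(hist, data.frame(epoch = NA_integer_,
                                     train_loss = NA_real_,
                                     val_accuracy =
                                       classifier_accuracy(model,
                                                           val_samples)))
    }
  }
  model$history <- hist
  model$class_weights <- cw
  model
}

#' Hard-label accuracy of the classifier on a sample set
#' @param model a `pd_classifier`.
#' @param samples list of samples with `y`.
#' @return fraction correctly classified.
#' @export
classifier_accuracy <- function(model, samples) {
  pred <- vapply(samples, function(s)
    which.max(clf_forward(model, s)$y_hat) - 1L, integer(1))
  mean(pred == vapply(samples, `[[`, numeric(1), "y"))
}

#' Per-subject prediction table
#'
#' @param model a `pd_classifier`.
#' @param samples list of samples (need `subject_id`; `y` and `pet_source`
#'   used when present).
#' @param horizon_days horizon annotation for the output table.
#' @return data.frame `subject_id, horizon_days, p_convert, label_pred,
#'   label_true, pet_source`.
#' @export
predict_classifier <- function(model, samples, horizon_days = NA_integer_) {
  rows <- lapply(samples, function(s) {
    pr <- clf_forward(model, s)
    data.frame(subject_id = if (!is.null(s$subject_id)) s$subject_id else NA,
               horizon_days = horizon_days,
               p_convert = pr$y_hat[2],
               label_pred = which.max(pr$y_hat) - 1L,
               label_true = if (!is.null(s$y)) s$y else NA_integer_,
               pet_source = if (!is.null(s$pet_source)) s$pet_source else "real",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
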