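# Pixel-level bi-cross attention fusion, feed-forward head, softmax
# classifier and cross-entropy objective.

#' Patch-token bank from a volume
#'
#' Non-overlapping patches are flattened and linearly projected into key and
#' value tokens of dimension `d_k`.
#'
#' @param volume 3-D array.
#' @param patch_size integer triple dividing the volume shape.
#' @param projector list with matrices `W_K`, `W_V` (`prod(patch_size) x d_k`).
#' @return list with `K`, `V` (`n_patches x d_k`) and `patches`.
#' @export
pixel_tokens <- function(volume, patch_size, projector) {
  assert_that(all(patch_size <= dim(volume)), "patch larger than volume")
  P <- patchify(volume, patch_size)
  list(K = P %*% projector$W_K, V = P %*% projector$W_V, patches = P)
}

#' Cross-attention between query tokens and a key/value bank
#'
#' `softmax(Q K^T / sqrt(d_k)) V` with the softmax over keys per query row.
#'
#' @param Q query tokens.
#' @param K,V key/value tokens (row-aligned).
#' @param d_k scaling dimension (default `ncol(K)`).
#' @return attended tokens, one row per query.
#' @export
cross_attention <- function(Q, K, V, d_k = ncol(K)) {
  attention(Q, K, V, d_attn = d_k)
}

#' Initialize feed-forward + head fusion parameters
#'
#' @param d_k token dimension entering the FFN.
#' @param lambda_fusion PET-branch balance factor (>= 0).
#' @param hidden FFN hidden width (default `4 * d_k`).
#' @param n_class number of output classes.
#' @param seed integer seed.
#' @return named parameter list of class `pd_fusion`.
#' @export
fusion_init <- function(d_k, lambda_fusion = 1, hidden = 4L * d_k,
                        n_class = 2L, seed = 1L) {
  assert_that(lambda_fusion >= 0 && is.finite(lambda_fusion),
              "`lambda_fusion` must be finite and >= 0")
  p <- with_seed(seed, list(
    W1 = rand_mat(d_k, hidden), b1 = rep(0, hidden),
    W2 = rand_mat(hidden, d_k), b2 = rep(0, d_k),
    W_out = rand_mat(d_k, n_class), b_out = rep(0, n_class)))
  p$lambda_fusion <- lambda_fusion
  structure(p, class = "pd_fusion")
}

ffn_fw <- function(x, params) {
  L <- nrow(x)
  pre <- x %*% params$W1 + matrix(params$b1, L, length(params$b1), byrow = TRUE)
  hid <- silu(pre)
  out <- hid %*% params$W2 + matrix(params$b2, L, length(params$b2),
                                    byrow = TRUE)
  list(out = out, pre = pre, hid = hid, x = x)
}

ffn_bw <- function(params, cc, dout) {
  g <- list(W2 = t(cc$hid) %*% dout, b2 = colSums(dout))
  dhid <- dout %*% t(params$W2)
  dpre <- dhid * silu_grad(cc$pre)
  g$W1 <- t(cc$x) %*% dpre
  g$b1 <- colSums(dpre)
  list(dx = dpre %*% t(params$W1), grads = g)
}

#' Fuse MRI and PET attention outputs
#'
#' `x_final = pool(FFN(attn_mri + lambda * attn_pet))`, where pooling is the
#' arithmetic mean over token rows. With `lambda_fusion = 0` the result is
#' bit-independent of the PET branch.
#'
#' @param attn_mri,attn_pet attended token matrices of equal shape.
#' @param params a `pd_fusion`.
#' @return fused feature vector of length `d_k`.
#' @export
fuse <- function(attn_mri, attn_pet, params) {
  lam <- params$lambda_fusion
  x <- if (lam == 0) attn_mri else {
    assert_that(all(dim(attn_mri) == dim(attn_pet)),
                "attn_mri/attn_pet shape mismatch")
    attn_mri + lam * attn_pet
  }
  colMeans(ffn_fw(x, params)$out)
}

#' Linear classification head
#'
#' `logits = W_out^T x_final + b_out`, `y_hat = softmax(logits)`; invariant to
#' adding a constant to all logits.
#'
#' @param x_final fused feature vector.
#' @param W_out `d x n_class` weight matrix.
#' @param b_out length-`n_class` bias.
#' @return list of class `pd_prediction` with `y_hat`, `logits`, `x_final`.
#' @export
classify <- function(x_final, W_out, b_out) {
  logits <- as.numeric(matrix(x_final, 1) %*% W_out + b_out)
  assert_finite(logits)
  structure(list(y_hat = as.numeric(softmax_rows(matrix(logits, 1))),
                 logits = logits, x_final = x_final),
            class = "pd_prediction")
}

#' Cross-entropy loss
#'
#' `-log y_hat[y + 1]` averaged over a batch, with optional per-class weights
#' for imbalance. Probabilities are clamped at `1e-12` (a clamp is warned
#' about).
#'
#' @param y_hat probability vector, or matrix with one row per sample.
#' @param y labels in `{0, 1, ...}` (class 1 = converter is the positive
#'   class by convention).
#' @param class_weights optional per-class weights.
#' @return scalar mean loss (>= 0).
#' @export
cross_entropy <- function(y_hat, y, class_weights = NULL) {
  y_hat <- if (is.matrix(y_hat)) y_hat else matrix(y_hat, nrow = 1)
  p <- y_hat[cbind(seq_along(y), as.integer(y) + 1L)]
  if (any(p < 1e-12)) {
    warning("cross_entropy: clamping zero predicted probability")
    p <- pmax(p, 1e-12)
  }
  w <- if (is.null(class_weights)) rep(1, length(y)) else
    class_weights[as.integer(y) + 1L]
  sum(w * (-log(p))) / sum(w)
}
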