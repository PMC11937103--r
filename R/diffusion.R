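# Denoising-diffusion primitives: noise schedules, closed-form forward
# marginal, dual text/image-prompt cross-attention and adapter initialization.

#' Build a diffusion noise schedule
#'
#' `linear` interpolates beta from `beta_start` to `beta_end`; `cosine` is the
#' squared-cosine alpha-bar schedule with the customary 0.008 offset, with
#' per-step betas clipped to (0, 0.999].
#'
#' @param T_steps number of diffusion steps (>= 2). The full-scale default in
#'   [default_config()] is 1000; toy profiles use 50.
#' @param kind `"linear"` or `"cosine"`.
#' @param beta_start,beta_end linear schedule endpoints.
#' @return object of class `pd_schedule`: list with `T`, `beta`, `alpha`,
#'   `alpha_bar` (cumulative product, strictly decreasing).
#' @export
make_schedule <- function(T_steps, kind = c("linear", "cosine"),
                          beta_start = 1e-4, beta_end = 0.02) {
  kind <- match.arg(kind)
  assert_that(T_steps >= 2, "`T_steps` must be >= 2")
  T_steps <- as.integer(T_steps)
  if (kind == "linear") {
    beta <- seq(beta_start, beta_end, length.out = T_steps)
  } else {
    s <- 0.008
    f <- function(t) cos((t / T_steps + s) / (1 + s) * pi / 2)^2
    ab <- f(0:T_steps) / f(0)
    beta <- pmin(pmax(1 - ab[-1] / ab[-(T_steps + 1)], 1e-8), 0.999)
  }
  alpha <- 1 - beta
  structure(list(T = T_steps, beta = beta, alpha = alpha,
                 alpha_bar = cumprod(alpha)),
            class = "pd_schedule")
}

#' Closed-form forward diffusion marginal
#'
#' `x_t = sqrt(alpha_bar[t]) * x0 + sqrt(1 - alpha_bar[t]) * noise`.
#'
#' @param x0 clean signal (any array).
#' @param t step index in `1..T`.
#' @param noise array of the same shape as `x0`.
#' @param schedule a `pd_schedule`.
#' @return noised signal of the same shape.
#' @export
forward_diffuse <- function(x0, t, noise, schedule) {
  assert_that(identical(dim(x0), dim(noise)) && length(x0) == length(noise),
              "`x0` and `noise` shapes differ")
  assert_that(t >= 1 && t <= schedule$T, "`t` out of range")
  ab <- schedule$alpha_bar[t]
  sqrt(ab) * x0 + sqrt(1 - ab) * noise
}

#' Scaled dot-product attention (single head)
#'
#' `softmax(Q K^T / sqrt(d_attn)) V`, softmax taken row-wise over keys.
#'
#' @param Q queries (n_q x d).
#' @param K keys (n_k x d).
#' @param V values (n_k x d_v).
#' @param d_attn scaling dimension; defaults to `ncol(K)`.
#' @return n_q x d_v matrix.
#' @export
attention <- function(Q, K, V, d_attn = ncol(K)) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  assert_that(nrow(K) > 0, "empty key set")
  assert_that(nrow(K) == nrow(V), "K and V row counts differ")
  assert_finite(Q); assert_finite(K); assert_finite(V)
  softmax_rows(Q %*% t(K) / sqrt(d_attn)) %*% V
}

#' Dual text/image-prompt cross-attention
#'
#' Combines a base (text/temporal) prompt path and an image-prompt path:
#' `Z = Attention(Q, K_t, V_t) + lambda * Attention(Q, K_i, V_i)`, where
#' `lambda` balances the image-prompt contribution.
#'
#' @param Q queries.
#' @param K_t,V_t base-path keys/values.
#' @param K_i,V_i image-path keys/values.
#' @param lambda_prompt image-path weight (>= 0).
#' @param d_attn attention scaling dimension.
#' @return token matrix `Z`.
#' @export
dual_prompt_attention <- function(Q, K_t, V_t, K_i, V_i, lambda_prompt = 1,
                                  d_attn = ncol(K_t)) {
  assert_that(lambda_prompt >= 0, "`lambda_prompt` must be >= 0")
  Z <- attention(Q, K_t, V_t, d_attn)
  if (lambda_prompt != 0)
    Z <- Z + lambda_prompt * attention(Q, K_i, V_i, d_attn)
  Z
}

#' Initialize image-path adapter projections from source projections
#'
#' The adapter starts as an element-wise copy of the base model's key/value
#' projections and is trainable independently afterwards (the returned
#' matrices are copies, not references).
#'
#' @param source_W_K,source_W_V base projection matrices.
#' @return list of class `pd_adapter` with `W_K_i`, `W_V_i` plus the retained
#'   `source_W_K`, `source_W_V`.
#' @export
init_adapter <- function(source_W_K, source_W_V) {
  source_W_K <- as.matrix(source_W_K); source_W_V <- as.matrix(source_W_V)
  assert_finite(source_W_K); assert_finite(source_W_V)
  assert_that(ncol(source_W_K) == ncol(source_W_V),
              "K and V projections disagree on attention dimension")
  structure(list(W_K_i = source_W_K + 0, W_V_i = source_W_V + 0,
                 source_W_K = source_W_K, source_W_V = source_W_V),
            class = "pd_adapter")
}
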