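# Selective state-space (Mamba) block: input projection, depthwise causal
# Conv1D along the token axis, SiLU, selective scan with input-dependent
# zero-order-hold discretization, gating, output projection, RMSNorm, and a
# per-block residual. Forward passes optionally cache intermediates; matching
# *_backward functions implement the analytic gradients used for training.
#
# SSM parameterization (canonical selective-scan form; the diagonal state
# matrix A is stored as A = -exp(A_log) so it stays strictly negative):
#   delta_t = softplus(u_t W_delta + b_delta)          (per-channel step size)
#   B_t = u_t W_B,  C_t = u_t W_C                      (input-dependent)
#   Abar_t[c,s] = exp(delta_t[c] A[c,s])               (ZOH)
#   Bbar_t[c,s] = (Abar_t[c,s] - 1) / A[c,s]           (exact ZOH integral)
#   h_t = Abar_t * h_{t-1} + Bbar_t * B_t[s] * u_t[c],  h_0 = 0
#   y_t[c] = sum_s C_t[s] h_t[c,s] + D[c] u_t[c]

#' Root-mean-square normalization
#'
#' Each token row is divided by `sqrt(mean(row^2) + eps)` and scaled
#' element-wise by `gain`.
#'
#' @param x token matrix (rows are tokens) or a single vector.
#' @param gain scale vector of length `ncol(x)`.
#' @param eps stabilizer (> 0).
#' @return normalized matrix of the same shape.
#' @export
rmsnorm <- function(x, gain = rep(1, ncol(as.matrix(x))), eps = 1e-6) {
  assert_that(eps > 0, "`eps` must be > 0")
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  assert_finite(x)
  rms <- sqrt(rowMeans(x^2) + eps)
  (x / rms) * rep(gain, each = nrow(x))
}

rmsnorm_fw <- function(x, gain, eps = 1e-6) {
  rms <- sqrt(rowMeans(x^2) + eps)
  list(y = (x / rms) * rep(gain, each = nrow(x)), x = x, rms = rms,
       gain = gain)
}

rmsnorm_bw <- function(cache, dy) {
  x <- cache$x; rms <- cache$rms; g <- cache$gain
  d <- ncol(x)
  gm <- rep(g, each = nrow(x))
  dgain <- colSums(dy * x / rms)
  inner <- rowSums(dy * gm * x)          # per-row sum dy_i g_i x_i
  dx <- dy * gm / rms - x * inner / (d * rms^3)
  list(dx = dx, dgain = dgain)
}

#' Initialize selective-scan (SSM) parameters
#'
#' @param d_inner number of channels entering the scan.
#' @param d_state state dimension per channel.
#' @param seed integer seed.
#' @return named list of SSM parameter arrays.
#' @export
ssm_init <- function(d_inner, d_state = 8L, seed = 1L) {
  with_seed(seed, list(
    # A = -exp(A_log); initialized near the usual -(1..d_state) ladder
    A_log = matrix(log(matrix(seq_len(d_state), d_inner, d_state,
                              byrow = TRUE)), d_inner, d_state),
    W_B = rand_mat(d_inner, d_state),
    W_C = rand_mat(d_inner, d_state),
    W_delta = rand_mat(d_inner, d_inner, scale = 0.05),
    b_delta = rep(0.5, d_inner),
    D = rep(1, d_inner)))
}

#' Selective state-space scan
#'
#' Runs the discretized input-dependent recurrence documented in the source
#' header over a token sequence, independently per channel; exactly equal to
#' the naive per-timestep loop (it is one).
#'
#' @param u `L x d_inner` input sequence.
#' @param ssm parameter list from [ssm_init()].
#' @param cache return intermediates for the backward pass.
#' @return `L x d_inner` output (or a list with cache when `cache = TRUE`).
#' @export
selective_scan <- function(u, ssm, cache = FALSE) {
  u <- as.matrix(u)
  assert_finite(u)
  L <- nrow(u); d <- ncol(u); ds <- ncol(ssm$A_log)
  A <- -exp(ssm$A_log)
  pre <- u %*% ssm$W_delta + matrix(ssm$b_delta, L, d, byrow = TRUE)
  delta <- softplus(pre)
  B <- u %*% ssm$W_B                      # L x d_state
  C <- u %*% ssm$W_C
  y <- matrix(0, L, d)
  h <- matrix(0, d, ds)
  H <- if (cache) array(0, dim = c(L, d, ds))
  E <- if (cache) array(0, dim = c(L, d, ds))
  for (t in seq_len(L)) {
    Et <- exp(delta[t, ] * A)             # d x d_state (delta recycled by col)
    Ft <- (Et - 1) / A
    h <- Et * h + (Ft * u[t, ]) %*% diag(B[t, ], ds)
    y[t, ] <- h %*% C[t, ] + ssm$D * u[t, ]
    if (cache) { H[t, , ] <- h; E[t, , ] <- Et }
  }
  if (!cache) return(y)
  list(y = y, u = u, A = A, pre = pre, delta = delta, B = B, C = C,
       H = H, E = E)
}

selective_scan_bw <- function(ssm, cc, dy) {
  u <- cc$u; A <- cc$A; delta <- cc$delta; B <- cc$B; C <- cc$C
  L <- nrow(u); d <- ncol(u); ds <- ncol(A)
  du <- matrix(0, L, d)
  dB <- matrix(0, L, ds); dC <- matrix(0, L, ds)
  ddelta <- matrix(0, L, d)
  dA <- matrix(0, d, ds); dD <- rep(0, d)
  dh <- matrix(0, d, ds)
  for (t in seq(L, 1L)) {
    ht <- matrix(cc$H[t, , ], d, ds)
    Et <- matrix(cc$E[t, , ], d, ds)
    Ft <- (Et - 1) / A
    # y_t = h_t C_t + D u_t
    dC[t, ] <- t(ht) %*% dy[t, ]
    dD <- dD + dy[t, ] * u[t, ]
    du[t, ] <- du[t, ] + dy[t, ] * ssm$D
    dh <- dh + outer(dy[t, ], C[t, ])
    # recurrence h_t = Et*h_{t-1} + Ft * B_t[s] * u_t[c]
    hprev <- if (t > 1L) matrix(cc$H[t - 1L, , ], d, ds) else matrix(0, d, ds)
    dE <- dh * hprev
    Bu <- outer(u[t, ], B[t, ])           # d x ds
    dF <- dh * Bu
    dB[t, ] <- dB[t, ] + colSums(dh * Ft * u[t, ])
    du[t, ] <- du[t, ] + rowSums(dh * Ft * matrix(B[t, ], d, ds, byrow = TRUE))
    # dE/ddelta = A*E ; dF/ddelta = E ; dE/dA = delta*E ;
    # dF/dA = (delta*E*A - E + 1)/A^2
    ddelta[t, ] <- rowSums(dE * A * Et + dF * Et)
    dA <- dA + dE * delta[t, ] * Et + dF * (delta[t, ] * Et * A - Et + 1) / A^2
    dh <- dh * Et
  }
  dpre <- ddelta * softplus_grad(cc$pre)
  grads <- list(
    A_log = dA * A,                        # chain through A = -exp(A_log)
    W_B = t(u) %*% dB,
    W_C = t(u) %*% dC,
    W_delta = t(u) %*% dpre,
    b_delta = colSums(dpre),
    D = dD)
  du <- du + dpre %*% t(ssm$W_delta) + dB %*% t(ssm$W_B) + dC %*% t(ssm$W_C)
  list(du = du, grads = grads)
}

#' Initialize one Mamba block
#'
#' @param d_model token dimension entering/leaving the block.
#' @param d_inner expanded channel count (default `2 * d_model`).
#' @param d_state SSM state dimension.
#' @param conv_width depthwise causal Conv1D kernel width.
#' @param gate_mode `"self"` gates the scan output with `SiLU(z)` itself;
#'   `"separate"` uses a distinct linear gate branch from the block input.
#' @param seed integer seed.
#' @return named parameter list of class `pd_mamba_block`.
#' @export
mamba_block_init <- function(d_model, d_inner = 2L * d_model, d_state = 8L,
                             conv_width = 4L, gate_mode = c("self", "separate"),
                             seed = 1L) {
  gate_mode <- match.arg(gate_mode)
  assert_that(conv_width >= 1, "`conv_width` must be >= 1")
  p <- with_seed(seed, {
    out <- list(W_in = rand_mat(d_model, d_inner), b_in = rep(0, d_inner),
                conv_kernel = rand_mat(conv_width, d_inner,
                                       scale = 1 / sqrt(conv_width)),
                b_conv = rep(0, d_inner),
                W_out = rand_mat(d_inner, d_model), b_out = rep(0, d_model),
                gain = rep(1, d_model))
    if (gate_mode == "separate") {
      out$W_gate <- rand_mat(d_model, d_inner)
      out$b_gate <- rep(0, d_inner)
    }
    out
  })
  p$ssm <- ssm_init(d_inner, d_state, seed = seed + 1L)
  structure(p, gate_mode = gate_mode, class = "pd_mamba_block")
}

# depthwise causal conv along token axis; x: L x d, kernel: k x d
causal_conv1d <- function(x, kernel, bias) {
  L <- nrow(x); k <- nrow(kernel)
  out <- matrix(rep(bias, each = L), L, ncol(x))
  for (j in seq_len(k)) {
    # kernel row j multiplies tokens lagged by j-1
    if (j == 1L) {
      out <- out + x * rep(kernel[1, ], each = L)
    } else if (L > j - 1L) {
      rows <- seq_len(L - j + 1L)
      out[rows + j - 1L, ] <- out[rows + j - 1L, ] +
        x[rows, , drop = FALSE] * rep(kernel[j, ], each = L - j + 1L)
    }
  }
  out
}

causal_conv1d_bw <- function(x, kernel, dout) {
  L <- nrow(x); k <- nrow(kernel)
  dx <- matrix(0, L, ncol(x))
  dkern <- kernel * 0
  for (j in seq_len(k)) {
    if (j == 1L) {
      dx <- dx + dout * rep(kernel[1, ], each = L)
      dkern[1, ] <- colSums(dout * x)
    } else if (L > j - 1L) {
      rows <- seq_len(L - j + 1L)
      dx[rows, ] <- dx[rows, ] +
        dout[rows + j - 1L, , drop = FALSE] * rep(kernel[j, ], each = L - j + 1L)
      dkern[j, ] <- colSums(dout[rows + j - 1L, , drop = FALSE] *
                              x[rows, , drop = FALSE])
    }
  }
  list(dx = dx, dkernel = dkern, dbias = colSums(dout))
}

#' Apply one Mamba block
#'
#' `z = SiLU(Conv1D(x W_in + b_in))`; `z_out = SSM(z) * gate` with
#' `gate = SiLU(z)` (self mode, the literal equation) or the SiLU of a
#' separate linear branch of the block input; the gated output is projected
#' back to `d_model`, RMS-normalized, and added to the block input
#' (pre-norm residual). Shape is preserved: `L x d` in, `L x d` out.
#'
#' @param x `L x d_model` token matrix.
#' @param params a `pd_mamba_block`.
#' @param cache return intermediates for the backward pass.
#' @return `L x d_model` matrix (or list with cache).
#' @export
mamba_block <- function(x, params, cache = FALSE) {
  x <- as.matrix(x)
  gate_mode <- attr(params, "gate_mode")
  L <- nrow(x)
  pre_in <- x %*% params$W_in + matrix(params$b_in, L, length(params$b_in),
                                       byrow = TRUE)
  assert_that(nrow(params$conv_kernel) >= 1, "empty conv kernel")
  conv <- causal_conv1d(pre_in, params$conv_kernel, params$b_conv)
  z <- silu(conv)
  sc <- selective_scan(z, params$ssm, cache = TRUE)
  if (identical(gate_mode, "separate")) {
    gpre <- x %*% params$W_gate + matrix(params$b_gate, L,
                                         length(params$b_gate), byrow = TRUE)
    gate <- silu(gpre)
  } else {
    gpre <- z
    gate <- silu(z)
  }
  zout <- sc$y * gate
  proj <- zout %*% params$W_out + matrix(params$b_out, L,
                                         length(params$b_out), byrow = TRUE)
  nrm <- rmsnorm_fw(proj, params$gain)
  out <- x + nrm$y
  if (!cache) return(out)
  list(out = out, x = x, pre_in = pre_in, conv = conv, z = z, sc = sc,
       gpre = gpre, gate = gate, zout = zout, proj = proj, nrm = nrm,
       gate_mode = gate_mode)
}

mamba_block_bw <- function(params, cc, dout) {
  # residual: out = x + norm(proj)
  dx <- dout
  nb <- rmsnorm_bw(cc$nrm, dout)
  dproj <- nb$dx
  g <- list(gain = nb$dgain,
            W_out = t(cc$zout) %*% dproj, b_out = colSums(dproj))
  dzout <- dproj %*% t(params$W_out)
  dy_scan <- dzout * cc$gate
  dgate <- dzout * cc$sc$y
  sb <- selective_scan_bw(params$ssm, cc$sc, dy_scan)
  g$ssm <- sb$grads
  dz <- sb$du
  if (identical(cc$gate_mode, "separate")) {
    dgpre <- dgate * silu_grad(cc$gpre)
    g$W_gate <- t(cc$x) %*% dgpre
    g$b_gate <- colSums(dgpre)
    dx <- dx + dgpre %*% t(params$W_gate)
  } else {
    dz <- dz + dgate * silu_grad(cc$z)
  }
  dconv <- dz * silu_grad(cc$conv)
  cb <- causal_conv1d_bw(cc$pre_in, params$conv_kernel, dconv)
  g$conv_kernel <- cb$dkernel
  g$b_conv <- cb$dbias
  dpre_in <- cb$dx
  g$W_in <- t(cc$x) %*% dpre_in
  g$b_in <- colSums(dpre_in)
  dx <- dx + dpre_in %*% t(params$W_in)
  list(dx = dx, grads = g)
}

#' Apply a stack of Mamba blocks
#'
#' n-fold left-to-right composition; `n = 0` (empty list) is the identity.
#'
#' @param x `L x d_model` token matrix.
#' @param blocks list of `pd_mamba_block` parameter sets.
#' @return `L x d_model` matrix.
#' @export
mamba_stack <- function(x, blocks) {
  for (b in blocks) x <- mamba_block(x, b)
  x
}

mamba_stack_fw <- function(x, blocks) {
  caches <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    caches[[i]] <- mamba_block(x, blocks[[i]], cache = TRUE)
    x <- caches[[i]]$out
  }
  list(out = x, caches = caches)
}

mamba_stack_bw <- function(blocks, caches, dout) {
  grads <- vector("list", length(blocks))
  for (i in rev(seq_along(blocks))) {
    bb <- mamba_block_bw(blocks[[i]], caches[[i]], dout)
    grads[[i]] <- bb$grads
    dout <- bb$dx
  }
  list(dx = dout, grads = grads)
}
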