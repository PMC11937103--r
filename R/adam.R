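# Adam optimizer with decoupled weight decay and optional cosine-annealing
# learning rate, operating on arbitrary nested-free named lists of arrays.

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) +
                                           weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}

# Cosine-annealed learning rate at step `t` of `t_max` (1-based).
cosine_lr <- function(lr0, t, t_max, lr_min = 0) {
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * (t - 1) / max(t_max - 1, 1)))
}
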