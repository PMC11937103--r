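# Independent oracles and small fixture builders shared across tests. The
# oracles deliberately use naive elementwise loops, not the package's own
# vectorized paths.

# naive per-timestep selective-scan recurrence
naive_scan <- function(u, ssm) {
  L <- nrow(u); d <- ncol(u); ds <- ncol(ssm$A_log)
  A <- -exp(ssm$A_log)
  y <- matrix(0, L, d)
  h <- matrix(0, d, ds)
  for (t in seq_len(L)) {
    pre <- as.numeric(u[t, ] %*% ssm$W_delta) + ssm$b_delta
    delta <- log1p(exp(pre))
    B <- as.numeric(u[t, ] %*% ssm$W_B)
    C <- as.numeric(u[t, ] %*% ssm$W_C)
    for (cc in seq_len(d)) {
      for (s in seq_len(ds)) {
        E <- exp(delta[cc] * A[cc, s])
        Fv <- (E - 1) / A[cc, s]
        h[cc, s] <- E * h[cc, s] + Fv * B[s] * u[t, cc]
      }
      y[t, cc] <- sum(C * h[cc, ]) + ssm$D[cc] * u[t, cc]
    }
  }
  y
}

# brute-force scaled dot-product attention, scalar loops
naive_attention <- function(Q, K, V, d_attn) {
  nq <- nrow(Q); nk <- nrow(K)
  out <- matrix(0, nq, ncol(V))
  for (i in seq_len(nq)) {
    sc <- numeric(nk)
    for (j in seq_len(nk)) sc[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d_attn)
    w <- exp(sc - max(sc)); w <- w / sum(w)
    for (j in seq_len(nk)) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

# brute-force uniform-window SSIM over all full windows (2-D)
naive_ssim_2d <- function(a, b, w = 7, C1 = 1e-4, C2 = 9e-4) {
  n1 <- nrow(a) - w + 1; n2 <- ncol(a) - w + 1
  vals <- numeric(0)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    wa <- a[i:(i + w - 1), j:(j + w - 1)]
    wb <- b[i:(i + w - 1), j:(j + w - 1)]
    mu1 <- mean(wa); mu2 <- mean(wb)
    v1 <- mean(wa^2) - mu1^2; v2 <- mean(wb^2) - mu2^2
    cv <- mean(wa * wb) - mu1 * mu2
    vals <- c(vals, ((2 * mu1 * mu2 + C1) * (2 * cv + C2)) /
                ((mu1^2 + mu2^2 + C1) * (v1 + v2 + C2)))
  }
  mean(vals)
}

# tiny classifier + matching random sample, for gradient and ablation tests
tiny_classifier <- function(seed = 3, ablation = character(0),
                            gate_mode = "self") {
  classifier_init(cat_levels = c(2L, 3L), q = 3L, shape = c(8L, 8L, 8L),
                  d_model = 6L, n_blocks = 2L, d_state = 2L, d_k = 6L,
                  patch_size = c(4L, 4L, 4L), gate_mode = gate_mode,
                  ablation = ablation, seed = seed)
}

tiny_sample <- function(seed = 1) {
  set.seed(seed)
  list(subject_id = sprintf("T%03d", seed),
       x_cat = c(sample(1:2, 1), sample(1:3, 1)),
       x_num = rnorm(3),
       mri = array(runif(512), c(8, 8, 8)),
       pet = array(runif(512), c(8, 8, 8)),
       y = sample(0:1, 1))
}

# three-subject toy visit table: conversions at 100 and 400 days, one
# censored at 250 days
toy_visits <- function() {
  rbind(
    data.frame(subject_id = "A", visit_date = c("2020-01-01", "2020-04-10"),
               diagnosis = c("MCI", "AD"), mmse = c(26, 20), cdr = c(0.5, 1)),
    data.frame(subject_id = "B",
               visit_date = c("2020-01-01", "2020-06-01", "2021-02-04"),
               diagnosis = c("MCI", "MCI", "AD"), mmse = c(27, 25, 19),
               cdr = c(0.5, 0.5, 1)),
    data.frame(subject_id = "C", visit_date = c("2020-01-01", "2020-09-07"),
               diagnosis = c("MCI", "MCI"), mmse = c(28, 27),
               cdr = c(0.5, 0.5)))
}
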