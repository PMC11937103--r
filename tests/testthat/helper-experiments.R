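# Heavier shared experiments, memoized so related tests reuse one run.

.exp_cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (!exists(key, envir = .exp_cache)) assign(key, fn(), envir = .exp_cache)
  get(key, envir = .exp_cache)
}

# strong-effect planted-signal experiment: 400 training subjects, fresh
# 200-subject validation cohort, horizon 365; arms: full model, permuted
# labels, and the tabular-stream ablation
planted_arm <- function(arm = c("full", "permuted", "wo_table"),
                        seed = 101L) {
  arm <- match.arg(arm)
  memo(paste0("planted_", arm, "_", seed), function() {
    coh <- generate_cohort(400, effect_profile("strong"), seed = seed)
    built <- build_samples(coh, 365)
    cohv <- generate_cohort(200, effect_profile("strong"), seed = seed + 1L)
    builtv <- build_samples(cohv, 365)
    st <- fit_standardizer(built$numeric)
    xs <- apply_standardizer(built$numeric, st)
    xv <- apply_standardizer(builtv$numeric, st)
    for (i in seq_along(built$samples))
      built$samples[[i]]$x_num <- as.numeric(xs[i, ])
    for (i in seq_along(builtv$samples))
      builtv$samples[[i]]$x_num <- as.numeric(xv[i, ])
    if (arm == "permuted") {
      ys <- vapply(built$samples, `[[`, numeric(1), "y")
      yp <- petdiffuse:::with_seed(seed + 2L, sample(ys))
      for (i in seq_along(built$samples)) built$samples[[i]]$y <- yp[i]
    }
    ablation <- if (arm == "wo_table") "wo_table" else character(0)
    model <- classifier_init(cat_levels = c(2L, 3L), q = 3L,
                             shape = c(16L, 16L, 16L), d_model = 32L,
                             n_blocks = 2L, d_state = 8L, d_k = 32L,
                             ablation = ablation, seed = seed)
    model <- train_classifier(built$samples, model, epochs = 30L,
                              batch_size = 32L, lr = 3e-3,
                              weight_decay = 0.05,
                              val_samples = builtv$samples, seed = seed + 3L)
    list(model = model,
         val_accuracy = utils::tail(model$history$val_accuracy, 1))
  })
}

# toy diffusion experiment: 8 training pairs, 2 held-out pairs, T = 50
diffusion_experiment <- function(seed = 202L) {
  memo(paste0("diffusion_", seed), function() {
    coh <- generate_cohort(10, effect_profile("strong"), seed = seed)
    pairs <- unname(coh$volumes[1:8])
    held <- unname(coh$volumes[9:10])
    sch <- make_schedule(50, "linear")
    dn <- train_denoiser(pairs, sch, steps = 6000L, batch_size = 4L,
                         lr = 1e-2, lr_schedule = "cosine_annealing",
                         d_attn = 32L, seed = seed)
    gains <- vapply(seq_along(held), function(i) {
      vp <- held[[i]]
      gen <- sample_pet(vp$mri, dn, sch, n_candidates = 3L,
                        seed = seed + i, Z_GT = vp$pet)
      c(gen = gen$ssim_score, base = ssim(vp$mri, vp$pet))
    }, numeric(2))
    list(denoiser = dn, schedule = sch, gains = gains)
  })
}
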