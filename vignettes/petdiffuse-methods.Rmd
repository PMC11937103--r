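---
title: "Cross-modality PET synthesis and conversion-horizon classification: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modality PET synthesis and conversion-horizon classification: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Amyloid/FDG PET is the imaging modality most directly tied to the metabolic
signature of Alzheimer's disease, but it is expensive, radioactive and often
unavailable, while structural MRI is routine. `petdiffuse` implements a
two-stage pipeline for the mild-cognitive-impairment (MCI) population:

1. **MRI-to-PET translation** by a conditional denoising diffusion model, so
   that a PET-like volume is available for every subject with an MRI;
2. **Fixed-horizon conversion prediction** — will this MCI patient be
   diagnosed with AD within 180 / 365 / 730 days of their first MCI visit? —
   by a multimodal classifier that fuses imaging tokens and tabular clinical
   features (MMSE, CDR, demographics) through a selective state-space (Mamba)
   stack and pixel-level bi-cross attention.

Real cohorts of this kind (ADNI, OASIS) are access-controlled. The package
therefore ships a seeded synthetic cohort generator that emulates their
*structure* — paired volumes whose PET is a noisy deterministic function of
the MRI plus a disease-linked focal deficit, and longitudinal visit tables
whose conversion hazard is driven by the planted image and cognitive
severities — so every stage of the pipeline is testable end to end on a
desk.

# Diffusion translator

## Forward process and schedule

The forward process is the standard variance-preserving Gaussian noising
over `T` steps with increments `beta_t`: writing `alpha_t = 1 - beta_t` and
`abar_t = prod(alpha_1..alpha_t)`, the marginal at step `t` is

```
x_t = sqrt(abar_t) x_0 + sqrt(1 - abar_t) eps,   eps ~ N(0, I).
```

`make_schedule()` supports a linear beta ramp (1e-4 to 0.02, the default)
and the squared-cosine `abar` schedule. The full-scale default is `T = 1000`
steps; the toy profile uses `T = 50`, which at the bundled 16^3 volumes is
enough for the reverse chain to converge to its conditional mode while
keeping a full training run in tens of seconds on one CPU.

## Conditioning: dual-prompt attention and adapter initialization

The denoiser conditions on the MRI through one cross-attention site with two
key/value paths, combined as

```
Z = Attention(Q, K_t, V_t) + lambda * Attention(Q, K_i, V_i),
```

where the base path (`K_t`, `V_t`) attends over a learned null prompt token
per class (a stand-in for a text/temporal prompt encoder — the package does
not ship a language model) and the image path (`K_i`, `V_i`) attends over
tokens produced by a small learned encoder of MRI patches. The image-path
projections are initialized as element-wise copies of the base-path
projections and then trained independently while the base projections stay
frozen; `init_adapter()` exposes the copy-then-decouple contract on its own.
`lambda` (default 1) balances the image prompt against the base prompt.

## Parameterization and loss

Training minimizes epsilon-prediction mean squared error. Internally the
network uses the x0-parameterization: it forms an estimate of the clean PET

```
x0_hat = s * mri + u + beta_field + decode(Z)
```

(a voxelwise affine in the MRI, a learned spatial bias field, and a linear
decode of the attention tokens back onto patches) and converts it to a noise
prediction with the schedule, `eps_hat = (x_t - sqrt(abar_t) x0_hat) /
sqrt(1 - abar_t)`. This is the standard reparameterization of a DDPM
denoiser; it keeps the learnable map shared across all steps, which at desk
scale trains far more stably than a per-step noise regressor while leaving
the loss exactly the epsilon MSE. A consequence worth knowing: the epsilon
loss weights the x0 error by `abar_t / (1 - abar_t)`, which is large at
small `t`, so raw loss traces are dominated by low-noise steps and look
noisy even while the underlying estimate converges — judge convergence by
the smoothed trace (as the tests do) or by held-out SSIM.

## Sampling and SSIM selection

`sample_pet()` runs the ancestral reverse chain from seeded Gaussian noise,
clipping the intermediate x0 estimate to `[0, 1]` (the volume value range).
When a ground-truth PET is available — a validation-time situation only —
`n_candidates > 1` draws several independent chains and returns the
candidate maximizing SSIM against the reference. The argmax-SSIM
reconstruction rule cannot be the deployment-time rule (the reference is
unknown then), so at deployment `n_candidates = 1` and the SSIM machinery is
purely an evaluation device.

SSIM itself (`ssim()`) uses a uniform 7-wide window over all full windows,
biased (population) window moments, and constants `C1 = (0.01 r)^2`,
`C2 = (0.03 r)^2` for data range `r`; these choices are fixed so that scores
are bit-stable across runs and platforms.

# Multimodal classifier

## Token assembly

Tabular features are tokenized per feature: each categorical feature is a
row lookup in a learned embedding table whose first row is reserved for
missing values; each numeric feature `x_i` (standardized with
training-split statistics only) becomes the d-vector `x_i * W_i + b_i` — a
"column embedding", one token per numeric feature. Image tokens are linear
projections of non-overlapping patches of *both* volumes — MRI and
(generated or acquired) PET each contribute their own projected patch
tokens, since the disease-linked metabolic deficit is visible only in PET.
Inside the classifier the patches are first reduced by a fixed 2x
block-average pooling before the learned projection: the bundled volumes
are smooth at that scale, and the pooling cuts the patch-projector
parameter count eight-fold, which at a few hundred training subjects is
the difference between learning the image pathway and memorizing it. The
assembly is the vertical concatenation `z = [cat; num; img]` of shape
`(p + q + r) x d`, and stream ablations simply drop their block.

## Mamba stack

Each block applies, along the token axis:

```
z      = SiLU(Conv1D(W_in x + b_in))        # depthwise causal, width 4
z_out  = SSM(z) * SiLU(z)                   # selective scan, self-gated
out    = x + RMSNorm(W_out z_out + b_out)   # projection, norm, residual
```

The SSM is the canonical selective scan: a diagonal state matrix
`A = -exp(A_log)` (strictly negative), input-dependent `B_t`, `C_t` and
per-channel step sizes `delta_t = softplus(...)`, discretized by zero-order
hold (`Abar = exp(delta A)`, `Bbar = (Abar - 1)/A * B`), with a direct
feed-through `D`. The scan is implemented as the literal sequential
recurrence — at desk scale (L of order 10–100 tokens) a hardware-aware
parallel scan buys nothing.

Two gating variants exist because the self-gated form (`SSM(z) * SiLU(z)`,
the literal equation) differs from the common two-branch gate
(`SSM(z) * SiLU(W_g x)`); both are available via `gate_mode`, the self-gated
form is the default. The residual is placed per block, around the normalized
projection.

## Bi-cross fusion and head

Queries are the full Mamba output token sequence projected to the key
dimension; keys/values are linear projections of MRI patches and of
(generated or acquired) PET patches. Two cross-attention passes are fused
as `attn_MRI + lambda * attn_PET` (`lambda_fusion`, default 1, independent
of the prompt-side lambda), passed through a two-layer SiLU feed-forward
network, mean-pooled over tokens, and classified by a softmax head trained
with (optionally class-weighted) cross-entropy. Equal patch grids are
enforced for the two modalities so the fusion sum is well-defined.

Each ablation flag bypasses exactly one component: `wo_pl_bicross` replaces
the fusion by mean-pooling the Mamba output (the head is then sized to the
model dimension), `wo_pet_reference` forces `lambda_fusion = 0`, `wo_table`
and `wo_image` drop assembly blocks, and `wo_addiffusion` is a data-level
choice (acquired PET only) recorded per sample in the `pet_source` flag.

## Gradients

No automatic differentiation exists in this stack: every backward pass
(selective scan, causal depthwise convolution, RMSNorm, attention, FFN,
embeddings) is derived and implemented analytically, and the test suite
checks the assembled end-to-end gradient against central finite differences
at relative error 1e-4. The scan backward runs the recurrence in reverse,
accumulating through the zero-order-hold discretization.

# Label construction

From a longitudinal visit table, the baseline is the first MCI visit;
the interval is days from baseline to the first AD diagnosis at or after
baseline; follow-up is days to the last visit. At horizon `h`: conversion
within `h` (inclusive — "within h days") is 1; no conversion with follow-up
covering `h` is 0; anything else is censored and excluded (a converted
subject is a definite 0 at earlier horizons, since the conversion itself
documents follow-up). Subjects whose first AD diagnosis precedes any MCI
visit are excluded and reported. Interval binning uses the short range
150–365 and the long range 365–1095 days; the two ranges share day 365 and
the tie goes to the short bin by declared convention. Both the 180/365/730
horizon set and the 365/1095 framing appear in configuration; neither is
privileged.

# Synthetic cohort: what it emulates, what it does not

Each subject has latent severities: `atrophy` (shrinks the MRI foreground),
`metabolic_deficit` (deepens a fixed centered Gaussian depression in the
PET), and an independent cognitive latent driving the baseline MMSE. The
MRI is a smooth ellipsoid with a Gaussian-profile boundary; the PET is
`clip(0.9 * mri - deficit * bump + noise, 0, 1)`. Controllability, not
anatomy, is the goal: the fixed transfer makes SSIM targets stable, and the
monotone atrophy-to-volume link makes planted effects verifiable by
counting voxels.

Conversion times follow a discrete-time geometric hazard with a logistic
link: per 30-day period,

```
p = plogis(intercept + image_effect * (atrophy + deficit - 1)
           + tabular_effect * (24 - mmse) / 6)
```

Visits occur every 183 days (about the 6-month cadence of real cohorts);
AD is diagnosed at the first visit on/after the latent conversion day, so
observed intervals are visit-grid quantized, exactly as in real registries.
MMSE declines with time and drops after conversion, with measurement noise.

The named profiles fix the study conditions: `null` (no planted signal —
converter and non-converter features exchangeable), `weak` (both effects
1), and `strong` (both effects 16, intercept -5, visit-level MMSE noise
0.3). The strong profile is deliberately calibrated so that the planted
signal is close to deterministic: under it the Bayes-style accuracy ceiling
of the 365-day label given the *observable* features (measured MMSE, MRI
foreground, PET focal depression) is about 0.95, with the converter
fraction near 0.45 (declared band 0.30–0.60). Both knobs matter: the link
must be steep relative to the geometric hazard's intrinsic randomness, and
the visit-level MMSE measurement must be quiet relative to its hazard
coefficient — with the default measurement noise of 1 point the ceiling
drops to about 0.91, and "recovering the planted signal" becomes an
ill-posed demand on *any* classifier. The calibration was checked with
generator-side oracles (logistic fits on the true latent severities and on
matched-filter image summaries), not with the classifier itself.

What the generator does **not** emulate — and hence what green tests do not
show about real data: anatomy and registration error, scanner/site effects,
missing visits and irregular cadence, label noise in clinical diagnoses,
and any preprocessing of raw volumes (the generator emits already
registered, already normalized pairs).

# Numerical and design choices

* **Optimizer.** AdamW (decoupled weight decay) with cosine annealing.
  The full-scale defaults follow the configuration block
  (`lr = 1e-4`, weight decay 0.01, batch 32, 100 epochs, latent 256,
  `T = 1000`). The toy profiles used by the tests and the bundled
  experiments are scaled-down conditions chosen once: diffusion `T = 50`,
  width 32, 6000 steps at `lr = 1e-2` for the 8-pair translator run; 30
  epochs at `lr = 3e-3`, weight decay 0.05 for the 400-subject classifier
  run. The heavier classifier decay reflects the parameter-to-sample ratio
  of the patch projectors at n = 400; with the full-scale data volumes the
  0.01 default is the appropriate setting. The classifier trainer also
  averages the weights over the final ten epochs (Polyak-style tail
  averaging, `average_tail`), which smooths the minibatch-level wander of
  the late cosine-annealed iterates.
* **Image intensity normalization.** The classifier normalizes patch
  features with scalar mean/SD statistics computed on the training samples
  (stored in the model, applied identically at prediction time), analogous
  to the intensity normalization every neuroimaging pipeline applies before
  modelling; without it the common DC component of the patches dominates
  the projections and slows the image pathway's learning.
* **Class imbalance.** Inverse-prevalence class weights are available and on
  by default in the trainer; note that argmax predictions from a
  weight-trained model implement the balanced-error threshold, not the
  accuracy-optimal one. The planted-signal experiment uses a near-balanced
  profile, where the distinction is immaterial.
* **Determinism.** Every stochastic function takes a seed and runs under a
  save/restore RNG scope (`with_seed`); nothing touches global RNG state.
  Identical inputs and seeds reproduce volumes, cohorts, loss traces and
  samples bit-wise on fixed hardware.
* **Degenerate inputs.** Softmax is computed with row-max subtraction;
  zero-denominator metrics return 0 with a warning; cross-entropy clamps
  probabilities at 1e-12 with a warning; RMSNorm divides by
  `sqrt(mean(x^2) + eps)` with `eps > 0` required; the SSM state matrix is
  parameterized as `-exp(A_log)` so it can never reach zero or change sign.
* **Configs.** Strict YAML: unknown keys are rejected, because silent typos
  are the classic failure mode of ablation studies. Every artifact embeds
  an FNV-1a hash of its resolved config, and checkpoints refuse to load
  under a mismatching configuration.
* **Problem sizes.** Bundled experiments run at 16^3 volumes, 8-patch
  tokenizations, d = 32, 2 Mamba blocks, 400/200 train/validation subjects
  — sizes chosen so the full suite runs on one CPU in minutes while every
  mechanism (dual-prompt conditioning, scan, fusion, censoring, ablations)
  is exercised at full fidelity.

# Known limitations

* The denoiser's x0 path does not condition on `x_t` beyond the analytic
  term, so the reverse chain converges to the conditional mean rather than
  sampling the conditional distribution of PET given MRI; best-of-n SSIM
  selection therefore saturates quickly in n. This matches the evaluation
  use of the translator, but the model would need an x_t-dependent denoiser
  to act as a genuine generative sampler.
* The sequential scan and per-sample training loop are R-level; they are
  fast at desk scale but not a route to full-scale cohorts.
* Single-head attention everywhere; head count is a config knob left at 1.
* Censoring is handled by exclusion, matching the per-horizon binary
  framing; no survival-style partial credit for censored follow-up.
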