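# Synthetic cohort generator: paired MRI/PET volumes plus longitudinal visit
# tables with a planted, tunable MCI-to-AD conversion signal. The generator is
# the study bench for every downstream stage: its defaults define the test
# conditions, and truth columns are prefixed "sim_" so the modelling pipeline
# can be forbidden from reading them.

#' Effect configuration for the synthetic cohort generator
#'
#' Controls the strength of the planted disease signal. Conversion times follow
#' a discrete-time geometric hazard with a logistic link on the latent subject
#' state: per `period_days`-day period,
#' `p = plogis(hazard_intercept + image_effect * (atrophy + metabolic_deficit - 1)
#'  + tabular_effect * (24 - baseline_mmse) / 6)`.
#'
#' @param image_effect strength of the imaging-latent (atrophy + metabolic
#'   deficit) contribution to the conversion hazard; in `[0, 20]`.
#' @param tabular_effect strength of the cognitive-score (MMSE) contribution;
#'   in `[0, 20]`.
#' @param noise_sd voxel noise standard deviation added to PET volumes (>= 0).
#' @param hazard_intercept baseline log-odds of conversion per period.
#' @param period_days hazard period length in days.
#' @param visit_interval_days spacing between follow-up visits.
#' @param mmse_noise per-visit MMSE measurement noise SD.
#' @return a named list of class `pd_effect_config`.
#' @export
effect_config <- function(image_effect = 1.5,
                          tabular_effect = 1.5,
                          noise_sd = 0.02,
                          hazard_intercept = -3.2,
                          period_days = 30L,
                          visit_interval_days = 183L,
                          mmse_noise = 1.0) {
  assert_that(image_effect >= 0 && image_effect <= 20,
              "`image_effect` must be in [0, 20]")
  assert_that(tabular_effect >= 0 && tabular_effect <= 20,
              "`tabular_effect` must be in [0, 20]")
  assert_that(noise_sd >= 0, "`noise_sd` must be >= 0")
  assert_that(period_days >= 1, "`period_days` must be >= 1")
  structure(list(image_effect = image_effect,
                 tabular_effect = tabular_effect,
                 noise_sd = noise_sd,
                 hazard_intercept = hazard_intercept,
                 period_days = as.integer(period_days),
                 visit_interval_days = as.integer(visit_interval_days),
                 mmse_noise = mmse_noise),
            class = "pd_effect_config")
}

#' Named effect profiles
#'
#' `null` plants no signal (both effects 0), `weak` a mild signal, `strong` a
#' near-deterministic signal intended for planted-signal recovery experiments.
#' The declared converter-fraction band at the 365-day horizon for the strong
#' profile is `[0.30, 0.60]`.
#'
#' @param name one of `"null"`, `"weak"`, `"strong"`.
#' @return a `pd_effect_config`.
#' @export
effect_profile <- function(name = c("null", "weak", "strong")) {
  name <- match.arg(name)
  switch(name,
    null   = effect_config(image_effect = 0, tabular_effect = 0),
    weak   = effect_config(image_effect = 1, tabular_effect = 1),
    strong = effect_config(image_effect = 16, tabular_effect = 16,
                           hazard_intercept = -5, mmse_noise = 0.3))
}

#' Generate one paired MRI/PET volume
#'
#' The MRI is a smooth axis-aligned ellipsoid "brain" whose radii shrink
#' linearly with `atrophy`, with a Gaussian-profile boundary; the PET is a
#' fixed deterministic transfer of the MRI (`0.9 * mri`) minus a
#' `metabolic_deficit`-scaled centered Gaussian focal depression, plus
#' zero-mean Gaussian voxel noise, clipped to `[0, 1]`.
#'
#' @param atrophy brain-shrinkage severity in `[0, 1]`.
#' @param metabolic_deficit PET hypo-signal severity in `[0, 1]`.
#' @param shape integer triple, each dimension >= 8.
#' @param noise_sd PET voxel noise SD, >= 0.
#' @param seed integer seed.
#' @return an object of class `pd_volume_pair` with elements `mri`, `pet`
#'   (3-D arrays in `[0, 1]`), `shape`, `voxel_spacing`, `affine`.
#' @export
generate_volume_pair <- function(atrophy, metabolic_deficit,
                                 shape = c(16L, 16L, 16L),
                                 noise_sd = 0.02, seed = 1L) {
  assert_that(length(shape) == 3 && all(shape >= 8),
              "each `shape` dimension must be >= 8")
  assert_that(noise_sd >= 0, "`noise_sd` must be >= 0")
  assert_that(atrophy >= 0 && atrophy <= 1, "`atrophy` must be in [0, 1]")
  assert_that(metabolic_deficit >= 0 && metabolic_deficit <= 1,
              "`metabolic_deficit` must be in [0, 1]")
  shape <- as.integer(shape)

  # normalized coordinates in [-1, 1] per axis
  ax <- lapply(shape, function(n) (seq_len(n) - (n + 1) / 2) / (n / 2))
  cx <- array(rep(ax[[1]], times = shape[2] * shape[3]), dim = shape)
  cy <- array(rep(rep(ax[[2]], each = shape[1]), times = shape[3]), dim = shape)
  cz <- array(rep(ax[[3]], each = shape[1] * shape[2]), dim = shape)

  radii <- c(0.85, 0.75, 0.80) * (1 - 0.35 * atrophy)
  d <- sqrt((cx / radii[1])^2 + (cy / radii[2])^2 + (cz / radii[3])^2)
  mri <- 0.85 * stats::pnorm((1 - d) / 0.15)

  bump <- 0.5 * exp(-((cx / 0.35)^2 + (cy / 0.35)^2 + (cz / 0.35)^2))
  pet_clean <- pet_transfer(mri) - metabolic_deficit * bump
  noise <- if (noise_sd > 0) {
    with_seed(seed, array(stats::rnorm(prod(shape), sd = noise_sd), dim = shape))
  } else {
    array(0, dim = shape)
  }
  pet <- clip01(pet_clean + noise)

  structure(list(mri = mri, pet = clip01(pet),
                 shape = shape,
                 voxel_spacing = c(1, 1, 1),
                 affine = diag(4)),
            class = "pd_volume_pair")
}

#' Deterministic MRI-to-PET intensity transfer used by the generator
#'
#' @param mri MRI array.
#' @return the noiseless, deficit-free PET signal `0.9 * mri`.
#' @export
pet_transfer <- function(mri) 0.9 * mri

#' Generate a seeded synthetic cohort
#'
#' Each subject receives latent severities (`atrophy`, `metabolic_deficit`),
#' an independent cognitive latent driving the baseline MMSE, demographics, a
#' conversion day drawn from the geometric hazard of [effect_config()], one
#' paired MRI/PET volume, and a longitudinal visit table (first visit MCI at
#' day 0; AD diagnosed at the first visit on/after the conversion day).
#'
#' @param n_subjects number of subjects (>= 1).
#' @param config a `pd_effect_config`; defaults to `effect_config()`.
#' @param seed integer seed; identical `(n_subjects, config, seed)` give
#'   bit-identical cohorts.
#' @param shape volume grid shape.
#' @return an object of class `pd_cohort`: list with `subjects` (one row per
#'   subject, generator-truth columns prefixed `sim_`), `visits` (long visit
#'   table), `volumes` (named list of `pd_volume_pair`), `config`, `seed`.
#' @export
generate_cohort <- function(n_subjects, config = effect_config(), seed = 1L,
                            shape = c(16L, 16L, 16L)) {
  assert_that(is.numeric(n_subjects) && n_subjects >= 1,
              "`n_subjects` must be a positive integer")
  assert_that(inherits(config, "pd_effect_config"),
              "`config` must be created by effect_config()")
  n <- as.integer(n_subjects)

  with_seed(seed, {
    ids <- sprintf("S%04d", seq_len(n))
    atrophy <- stats::runif(n)
    deficit <- stats::runif(n)
    cog <- stats::runif(n)  # cognitive latent, independent of imaging latents
    baseline_mmse <- pmin(30, pmax(10, round(28 - 9 * cog + stats::rnorm(n, sd = 0.5))))
    age <- round(stats::runif(n, 60, 85))
    sex <- sample(c("F", "M"), n, replace = TRUE)
    education <- sample(8:20, n, replace = TRUE)
    n_visits <- sample(3:9, n, replace = TRUE)
    followup_day <- (n_visits - 1L) * config$visit_interval_days
    base_date <- as.Date("2020-01-01") + sample(0:365, n, replace = TRUE)

    eta <- config$hazard_intercept +
      config$image_effect * (atrophy + deficit - 1) +
      config$tabular_effect * (24 - baseline_mmse) / 6
    p_period <- stats::plogis(eta)
    # geometric first-success period; day at the end of that period. The
    # hazard floor keeps the geometric mean finite; doubles avoid int32
    # overflow for near-immortal subjects (who are censored regardless).
    k <- as.numeric(stats::rgeom(n, pmax(p_period, 1e-8))) + 1
    conv_day_raw <- k * as.numeric(config$period_days)
    conversion_day <- as.integer(ifelse(
      !is.na(conv_day_raw) & conv_day_raw <= followup_day,
      conv_day_raw, NA_real_))

    vol_seeds <- sample.int(.Machine$integer.max - 1L, n)
    volumes <- vector("list", n)
    names(volumes) <- ids
    for (i in seq_len(n)) {
      volumes[[i]] <- generate_volume_pair(atrophy[i], deficit[i], shape,
                                           noise_sd = config$noise_sd,
                                           seed = vol_seeds[i])
    }

    visit_rows <- vector("list", n)
    for (i in seq_len(n)) {
      days <- seq(0L, followup_day[i], by = config$visit_interval_days)
      diag <- rep("MCI", length(days))
      if (!is.na(conversion_day[i])) diag[days >= conversion_day[i]] <- "AD"
      decline <- 1.5 * days / 365 + ifelse(diag == "AD", 3, 0)
      mmse <- pmin(30, pmax(0, round(baseline_mmse[i] - decline +
                                       stats::rnorm(length(days), sd = config$mmse_noise))))
      cdr <- ifelse(diag == "AD", 1, 0.5)
      visit_rows[[i]] <- data.frame(
        subject_id = ids[i],
        visit_date = format(base_date[i] + days, "%Y-%m-%d"),
        diagnosis = diag,
        mmse = mmse,
        cdr = cdr,
        stringsAsFactors = FALSE)
    }

    subjects <- data.frame(
      subject_id = ids,
      age = age,
      sex = sex,
      education = education,
      baseline_mmse = baseline_mmse,
      baseline_cdr = rep(0.5, n),
      sim_atrophy = atrophy,
      sim_metabolic_deficit = deficit,
      sim_conversion_day = conversion_day,
      sim_followup_day = followup_day,
      stringsAsFactors = FALSE)

    structure(list(subjects = subjects,
                   visits = do.call(rbind, visit_rows),
                   volumes = volumes,
                   config = config,
                   seed = as.integer(seed)),
              class = "pd_cohort")
  })
}

#' @export
print.pd_cohort <- function(x, ...) {
  cat(sprintf("<pd_cohort> %d subjects, %d visits, volumes %s, seed %d\n",
              nrow(x$subjects), nrow(x$visits),
              paste(x$volumes[[1]]$shape, collapse = "x"), x$seed))
  invisible(x)
}
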