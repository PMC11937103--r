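# Glue between the cohort tables/volumes and the classifier: feature
# construction (with a hard guard against reading generator-truth columns),
# train/validation splitting, and end-to-end convenience wrappers.

#' Build classifier samples from a cohort
#'
#' Features are taken from the visit table and the non-truth subject columns
#' only: any `sim_`-prefixed generator-truth column is explicitly dropped
#' before feature construction (leakage guard). Categorical features: sex,
#' education tertile. Numeric features: baseline-visit MMSE, baseline-visit
#' CDR, age. Numeric standardization statistics must come from the training
#' split (fit them with [fit_standardizer()] on the training subjects and
#' pass them here).
#'
#' @param cohort a `pd_cohort`.
#' @param horizon_days label horizon; censored subjects are dropped.
#' @param standardizer output of [fit_standardizer()] on training-split
#'   numeric features, or `NULL` to return raw numerics (fit-then-apply
#'   workflows).
#' @param generated_pet optional named list (by subject id) of generated PET
#'   volumes to use instead of the cohort's acquired PET; samples carry a
#'   `pet_source` flag.
#' @return list with `samples` (list of per-subject sample lists), `numeric`
#'   (raw numeric feature matrix), `y`, `subject_ids`.
#' @export
build_samples <- function(cohort, horizon_days = 365L, standardizer = NULL,
                          generated_pet = NULL) {
  subj <- cohort$subjects
  subj <- subj[, !grepl("^sim_", names(subj)), drop = FALSE]  # leakage guard
  labels <- extract_intervals(cohort$visits)
  lab <- label_at_horizon(labels$interval_days, labels$followup_days,
                          horizon_days)
  keep <- labels$subject_id[!is.na(lab)]
  y <- lab[!is.na(lab)]
  names(y) <- keep

  first_visit <- cohort$visits[!duplicated(cohort$visits$subject_id), ]
  rownames(first_visit) <- first_visit$subject_id
  rownames(subj) <- subj$subject_id

  num <- cbind(mmse = first_visit[keep, "mmse"],
               cdr = first_visit[keep, "cdr"],
               age = subj[keep, "age"])
  edu <- subj[keep, "education"]
  edu_ter <- as.integer(cut(edu, breaks = c(-Inf, 12, 16, Inf)))
  sex <- ifelse(subj[keep, "sex"] == "F", 1L, 2L)

  xs <- if (is.null(standardizer)) num else apply_standardizer(num, standardizer)
  samples <- lapply(seq_along(keep), function(i) {
    id <- keep[i]
    pet <- if (!is.null(generated_pet)) generated_pet[[id]] else
      cohort$volumes[[id]]$pet
    list(subject_id = id,
         x_cat = c(sex[i], edu_ter[i]),
         x_num = as.numeric(xs[i, ]),
         mri = cohort$volumes[[id]]$mri,
         pet = pet,
         y = as.integer(y[i]),
         pet_source = if (is.null(generated_pet)) "real" else "generated")
  })
  list(samples = samples, numeric = num, y = as.integer(y),
       subject_ids = keep)
}

#' Deterministic train/validation split of sample indices
#' @param n number of samples.
#' @param val_frac validation fraction.
#' @param seed integer seed.
#' @return list with `train`, `val` integer index vectors.
#' @export
split_train_val <- function(n, val_frac = 0.25, seed = 1L) {
  with_seed(seed, {
    idx <- sample(n)
    n_val <- max(1L, round(val_frac * n))
    list(val = sort(idx[seq_len(n_val)]), train = sort(idx[-seq_len(n_val)]))
  })
}

#' Standardize samples with training-split statistics
#'
#' @param built output of [build_samples()] with `standardizer = NULL`.
#' @param train_idx indices of the training split.
#' @return `built` with standardized `x_num` in every sample and the fitted
#'   `standardizer` attached.
#' @export
standardize_samples <- function(built, train_idx) {
  st <- fit_standardizer(built$numeric[train_idx, , drop = FALSE])
  xs <- apply_standardizer(built$numeric, st)
  for (i in seq_along(built$samples))
    built$samples[[i]]$x_num <- as.numeric(xs[i, ])
  built$standardizer <- st
  built
}
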