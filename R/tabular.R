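# Longitudinal visit tables -> per-horizon conversion labels, and tabular
# features -> embedded tokens for the multimodal assembly.
#
# Conventions fixed here: a conversion exactly at the horizon counts as
# positive ("within h days"); subjects with neither conversion nor follow-up
# reaching the horizon are censored and excluded from training/evaluation.

#' Reduce a longitudinal visit table to progression labels
#'
#' For every subject with at least one MCI visit: baseline is the first MCI
#' visit date; `interval_days` is days from baseline to the first AD diagnosis
#' on/after baseline (`NA` when no conversion is observed); `followup_days` is
#' days from baseline to the last visit. Subjects whose first AD diagnosis
#' precedes any MCI visit are excluded and reported via the
#' `excluded_subjects` attribute.
#'
#' @param visits data.frame with columns `subject_id`, `visit_date`
#'   (ISO-8601), `diagnosis` in `{CN, MCI, AD}`, `mmse`, `cdr`.
#' @return data.frame with columns `subject_id`, `baseline_date`,
#'   `interval_days`, `followup_days`; attribute `excluded_subjects` lists ids
#'   with AD before any MCI visit. Row order is independent of the input row
#'   order (sorted by subject id).
#' @export
extract_intervals <- function(visits) {
  assert_that(nrow(visits) > 0, "empty visit table")
  req <- c("subject_id", "visit_date", "diagnosis")
  assert_that(all(req %in% names(visits)),
              "visits must have subject_id, visit_date, diagnosis columns")
  dates <- as.Date(visits$visit_date, format = "%Y-%m-%d")
  assert_that(!anyNA(dates), "unparseable visit dates")
  key <- paste(visits$subject_id, visits$visit_date)
  assert_that(!anyDuplicated(key), "duplicate (subject_id, visit_date) rows")

  out <- list(); excluded <- character(0)
  for (id in sort(unique(visits$subject_id))) {
    vs <- visits[visits$subject_id == id, , drop = FALSE]
    d <- as.Date(vs$visit_date, format = "%Y-%m-%d")
    o <- order(d); vs <- vs[o, , drop = FALSE]; d <- d[o]
    mci <- which(vs$diagnosis == "MCI")
    ad <- which(vs$diagnosis == "AD")
    if (length(mci) == 0) next
    if (length(ad) > 0 && d[ad[1]] < d[mci[1]]) {
      excluded <- c(excluded, id)
      next
    }
    baseline <- d[mci[1]]
    ad_after <- ad[d[ad] >= baseline]
    interval <- if (length(ad_after) > 0)
      as.integer(d[ad_after[1]] - baseline) else NA_integer_
    followup <- as.integer(max(d) - baseline)
    out[[id]] <- data.frame(subject_id = id,
                            baseline_date = format(baseline, "%Y-%m-%d"),
                            interval_days = interval,
                            followup_days = followup,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "excluded_subjects") <- excluded
  res
}

#' Binary conversion label at a fixed horizon
#'
#' Vectorized over subjects. Returns `1` when conversion occurred within the
#' horizon (conversion exactly at the horizon counts), `0` when no conversion
#' was observed and follow-up covers the horizon, and `NA` (censored)
#' otherwise. A converted subject is a definite `0` at horizons before the
#' conversion day, since conversion itself documents follow-up to that day.
#'
#' @param interval_days integer days to conversion, `NA` if none observed.
#' @param followup_days integer days of follow-up from baseline.
#' @param horizon_days horizon in days (>= 1).
#' @return integer vector in `{0, 1, NA}`; `NA` means censored.
#' @export
label_at_horizon <- function(interval_days, followup_days, horizon_days) {
  assert_that(all(horizon_days >= 1), "`horizon_days` must be >= 1")
  converted <- !is.na(interval_days) & interval_days <= horizon_days
  not_yet <- !is.na(interval_days) & interval_days > horizon_days
  observed_neg <- (is.na(interval_days) & followup_days >= horizon_days) | not_yet
  ifelse(converted, 1L, ifelse(observed_neg, 0L, NA_integer_))
}

#' Horizon label table for a set of progression labels
#'
#' @param labels output of [extract_intervals()].
#' @param horizons integer vector of horizons in days.
#' @return long data.frame `subject_id, horizon_days, label` with censored
#'   rows omitted; the number of censored subject-horizon pairs is recorded in
#'   attribute `n_censored`.
#' @export
horizon_label_table <- function(labels, horizons = c(180L, 365L, 730L)) {
  rows <- lapply(horizons, function(h) {
    lab <- label_at_horizon(labels$interval_days, labels$followup_days, h)
    data.frame(subject_id = labels$subject_id, horizon_days = h, label = lab,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  n_cens <- sum(is.na(res$label))
  res <- res[!is.na(res$label), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_censored") <- n_cens
  res
}

#' Bin a conversion interval into short/long progression ranges
#'
#' Short covers 150-365 days, long covers 365-1095 days; the shared boundary
#' day 365 is assigned to the short bin. Anything else is `out_of_range`.
#'
#' @param interval_days integer vector of intervals (>= 0).
#' @return character vector in `{"short", "long", "out_of_range"}`.
#' @export
bin_interval <- function(interval_days) {
  assert_that(all(interval_days >= 0, na.rm = TRUE),
              "`interval_days` must be >= 0")
  ifelse(is.na(interval_days), "out_of_range",
    ifelse(interval_days >= 150 & interval_days <= 365, "short",
      ifelse(interval_days > 365 & interval_days <= 1095, "long",
             "out_of_range")))
}

# feature tokenization ---------------------------------------------------

#' Fit standardization statistics on a training split
#'
#' @param x numeric matrix (subjects x features), training split only.
#' @return list with `mean` and `sd` per feature (sd floored at 1e-8).
#' @export
fit_standardizer <- function(x) {
  x <- as.matrix(x)
  list(mean = colMeans(x), sd = pmax(apply(x, 2, stats::sd), 1e-8))
}

#' Apply standardization statistics
#' @param x numeric matrix.
#' @param stats list from [fit_standardizer()].
#' @return standardized matrix.
#' @export
apply_standardizer <- function(x, stats) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, stats$mean, "-"), 2, stats$sd, "/")
}

#' Linear transform of numeric features into tokens
#'
#' Realizes the per-feature learned affine map ("column embedding"): feature
#' `i` with scalar value `x[i]` becomes the d-vector `x[i] * W_num[i, ] +
#' b_num[i, ]`, so q numeric features yield q tokens of dimension d.
#'
#' @param x_num numeric q-vector (standardized).
#' @param W_num q x d weight matrix.
#' @param b_num q x d bias matrix.
#' @return q x d token matrix.
#' @export
transform_numeric <- function(x_num, W_num, b_num) {
  assert_finite(x_num); assert_finite(W_num); assert_finite(b_num)
  W_num <- as.matrix(W_num); b_num <- as.matrix(b_num)
  assert_that(length(x_num) == nrow(W_num) && all(dim(W_num) == dim(b_num)),
              "shape mismatch between x_num, W_num, b_num")
  as.numeric(x_num) * W_num + b_num
}

#' Build a categorical embedding table
#'
#' Row 1 is the reserved "missing" embedding; rows `1 + j` hold category `j`.
#'
#' @param n_levels number of category levels.
#' @param d embedding dimension.
#' @param seed integer seed.
#' @return `(n_levels + 1) x d` matrix.
#' @export
make_embedding_table <- function(n_levels, d, seed = 1L) {
  with_seed(seed, rand_mat(n_levels + 1L, d))
}

#' Embed categorical indices by table lookup
#'
#' @param x_cat integer vector of category indices (1-based); `NA` maps to the
#'   reserved missing row.
#' @param table embedding table from [make_embedding_table()].
#' @return `length(x_cat) x d` token matrix.
#' @export
embed_categorical <- function(x_cat, table) {
  table <- as.matrix(table)
  idx <- ifelse(is.na(x_cat), 0L, as.integer(x_cat)) + 1L
  assert_that(all(idx >= 1 & idx <= nrow(table)),
              "categorical index out of vocabulary and no missing fallback")
  table[idx, , drop = FALSE]
}

#' Concatenate token streams into the multimodal assembly
#'
#' Vertical concatenation in fixed order (categorical, numeric, image) giving
#' a `(p + q + r) x d` token matrix. Any stream may be empty (0 rows), which
#' is how stream ablations are expressed.
#'
#' @param cat_tokens p x d matrix (or NULL).
#' @param num_tokens q x d matrix (or NULL).
#' @param img_tokens r x d matrix (or NULL).
#' @return matrix of class `pd_assembly` with attributes `p`, `q`, `r`.
#' @export
assemble_multimodal <- function(cat_tokens = NULL, num_tokens = NULL,
                                img_tokens = NULL) {
  blocks <- Filter(Negate(is.null), list(cat_tokens, num_tokens, img_tokens))
  assert_that(length(blocks) > 0, "all streams empty")
  dims <- unique(vapply(blocks, ncol, integer(1)))
  assert_that(length(dims) == 1, "token streams disagree on dimension d")
  p <- if (is.null(cat_tokens)) 0L else nrow(cat_tokens)
  q <- if (is.null(num_tokens)) 0L else nrow(num_tokens)
  r <- if (is.null(img_tokens)) 0L else nrow(img_tokens)
  z <- do.call(rbind, blocks)
  structure(z, p = p, q = q, r = r, class = c("pd_assembly", class(z)))
}
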