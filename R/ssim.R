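# Structural similarity index with a uniform sliding window, for 2-D or 3-D
# grids. Constants follow the conventional C1 = (0.01 * data_range)^2,
# C2 = (0.03 * data_range)^2 so scores are bit-stable across runs.

# Uniform (box) filter over all full windows of side `w`, any dimensionality.
# Returns the array of window means (size dim - w + 1 per axis).
box_filter <- function(x, w) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  nd <- length(d)
  out_dim <- d - w + 1L
  assert_that(all(out_dim >= 1), "window larger than a grid dimension")
  acc <- array(0, dim = out_dim)
  # sum over all w^nd offsets; each term is a vectorized subarray extraction
  offsets <- as.matrix(expand.grid(rep(list(seq_len(w) - 1L), nd)))
  for (k in seq_len(nrow(offsets))) {
    idx <- lapply(seq_len(nd), function(j) offsets[k, j] + seq_len(out_dim[j]))
    acc <- acc + do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  }
  acc / w^nd
}

#' Structural similarity index (SSIM)
#'
#' Mean of the standard SSIM map computed with a uniform window over all full
#' windows. Symmetric in its two arguments; 1 for identical inputs; values lie
#' in `[-1, 1]`.
#'
#' @param a,b arrays of identical shape (2-D or 3-D).
#' @param window window side length (default 7).
#' @param data_range value range of the data (default 1 for `[0, 1]` grids).
#' @param C1,C2 stability constants; default `(0.01 * data_range)^2` and
#'   `(0.03 * data_range)^2`.
#' @return scalar SSIM.
#' @export
ssim <- function(a, b, window = 7L, data_range = 1,
                 C1 = (0.01 * data_range)^2, C2 = (0.03 * data_range)^2) {
  assert_that(identical(dim(a), dim(b)), "shape mismatch")
  assert_that(data_range > 0, "`data_range` must be > 0")
  a <- a * 1.0; b <- b * 1.0
  mu_a <- box_filter(a, window)
  mu_b <- box_filter(b, window)
  # window (biased) variances/covariance via E[x^2] - E[x]^2
  var_a <- box_filter(a * a, window) - mu_a^2
  var_b <- box_filter(b * b, window) - mu_b^2
  cov_ab <- box_filter(a * b, window) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + C1) * (2 * cov_ab + C2)
  den <- (mu_a^2 + mu_b^2 + C1) * (var_a + var_b + C2)
  mean(num / den)
}
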