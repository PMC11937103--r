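# Internal numerical helpers shared across modules. All randomness in the
# package flows through with_seed() so no function touches global RNG state
# except inside an explicit save/restore scope.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's `.Random.seed`, seeds the generator, evaluates `code`,
#' and restores the previous state on exit. Every stochastic operation in the
#' package runs through this, so outputs are pure functions of (inputs, seed).
#'
#' @param seed integer scalar seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  code
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' SiLU activation x * sigmoid(x)
#' @param x numeric array.
#' @return same shape as `x`.
#' @keywords internal
silu <- function(x) x * sigmoid(x)

# d/dx silu(x) = sigmoid(x) * (1 + x * (1 - sigmoid(x)))
silu_grad <- function(x) {
  s <- sigmoid(x)
  s * (1 + x * (1 - s))
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
}

softplus_grad <- function(x) sigmoid(x)

#' Row-wise softmax
#'
#' Shift-invariant softmax over the columns of each row.
#' @param x numeric matrix.
#' @return matrix of the same shape; each row sums to 1.
#' @keywords internal
softmax_rows <- function(x) {
  x <- as.matrix(x)
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# consistent argument checking -------------------------------------------

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

assert_finite <- function(x, name = deparse(substitute(x))) {
  assert_that(all(is.finite(x)), sprintf("`%s` contains non-finite values", name))
}

# Xavier/Glorot-style init used by every learnable matrix in the package.
rand_mat <- function(nr, nc, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(2 / (nr + nc))
  matrix(stats::rnorm(nr * nc, sd = scale), nr, nc)
}
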