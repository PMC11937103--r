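# Non-overlapping patch extraction / reassembly for 3-D volumes. Patches are
# enumerated in column-major (x fastest) order of the patch grid; voxels
# within a patch are flattened in R's native column-major order.

#' Split a volume into flattened non-overlapping patches
#'
#' @param vol 3-D array.
#' @param patch_size integer triple dividing `dim(vol)` exactly.
#' @return `n_patches x prod(patch_size)` matrix.
#' @export
patchify <- function(vol, patch_size = c(8L, 8L, 8L)) {
  d <- dim(vol)
  assert_that(length(d) == 3 && all(d %% patch_size == 0),
              "`patch_size` must divide the volume shape")
  g <- d %/% patch_size
  n <- prod(g)
  out <- matrix(0, n, prod(patch_size))
  pidx <- 0L
  for (k in seq_len(g[3])) for (j in seq_len(g[2])) for (i in seq_len(g[1])) {
    pidx <- pidx + 1L
    out[pidx, ] <- as.numeric(vol[(i - 1L) * patch_size[1] + seq_len(patch_size[1]),
                                  (j - 1L) * patch_size[2] + seq_len(patch_size[2]),
                                  (k - 1L) * patch_size[3] + seq_len(patch_size[3])])
  }
  out
}

#' Downsample a volume by block averaging
#'
#' @param vol 3-D array.
#' @param f integer factor dividing every dimension.
#' @return array of dimension `dim(vol) / f`, each cell the mean of an
#'   `f^3` block.
#' @export
downsample_volume <- function(vol, f = 2L) {
  d <- dim(vol)
  assert_that(length(d) == 3 && all(d %% f == 0),
              "`f` must divide every volume dimension")
  if (f == 1L) return(vol)
  a <- array(vol, c(f, d[1] %/% f, f, d[2] %/% f, f, d[3] %/% f))
  apply(a, c(2, 4, 6), mean)
}

#' Reassemble a volume from flattened patches (inverse of [patchify()])
#' @param mat `n_patches x prod(patch_size)` matrix.
#' @param shape full volume shape.
#' @param patch_size patch shape.
#' @return 3-D array of dimension `shape`.
#' @export
unpatchify <- function(mat, shape, patch_size = c(8L, 8L, 8L)) {
  g <- shape %/% patch_size
  vol <- array(0, dim = shape)
  pidx <- 0L
  for (k in seq_len(g[3])) for (j in seq_len(g[2])) for (i in seq_len(g[1])) {
    pidx <- pidx + 1L
    vol[(i - 1L) * patch_size[1] + seq_len(patch_size[1]),
        (j - 1L) * patch_size[2] + seq_len(patch_size[2]),
        (k - 1L) * patch_size[3] + seq_len(patch_size[3])] <-
      array(mat[pidx, ], dim = patch_size)
  }
  vol
}
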