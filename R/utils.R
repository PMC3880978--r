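# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so seeded operations do not perturb the global stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# All 0-based voxel indices of a grid, one row per voxel, in column-major
# (R array) order. Rows align with the flattened array.
grid_indices <- function(shape) {
  cbind(
    rep.int(seq_len(shape[1]) - 1, shape[2] * shape[3]),
    rep.int(rep(seq_len(shape[2]) - 1, each = shape[1]), shape[3]),
    rep(seq_len(shape[3]) - 1, each = shape[1] * shape[2])
  )
}

# Shift a 3D array by an integer offset along one axis, filling vacated
# entries with `fill`. Positive offsets move content toward higher indices.
shift_array <- function(a, offset, axis, fill = 0) {
  offset <- as.integer(offset)
  if (offset == 0L) return(a)
  d <- dim(a)
  out <- array(fill, d)
  n <- d[axis]
  if (abs(offset) >= n) return(out)
  src <- dst <- lapply(d, seq_len)
  if (offset > 0L) {
    dst[[axis]] <- (offset + 1L):n
    src[[axis]] <- 1L:(n - offset)
  } else {
    dst[[axis]] <- 1L:(n + offset)
    src[[axis]] <- (1L - offset):n
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Separable Gaussian blur with per-axis sigma given in voxels. The kernel
# is truncated at 4 sigma and renormalized to unit sum, so total intensity
# is conserved for signal with sufficient margin to the grid edge.
gaussian_blur <- function(a, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s < 1e-8) next
    r <- max(1L, as.integer(ceiling(4 * s)))
    w <- dnorm(-r:r, sd = s)
    w <- w / sum(w)
    out <- array(0, dim(a))
    for (o in -r:r) {
      out <- out + w[o + r + 1L] * shift_array(a, o, axis, fill = 0)
    }
    a <- out
  }
  a
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
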