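#' Configuration for mutual-information rigid registration
#'
#' The "fast" and "slow" registration modes differ only in the fraction
#' of target voxels sampled when building the joint histogram, mirroring
#' commercial implementations whose fast/slow variants differ in the
#' number of samples used for the similarity function.
#'
#' @param n_bins joint-histogram bins per modality (>= 8).
#' @param sample_fraction_fast,sample_fraction_slow fraction of fixed-grid
#'   voxels sampled (0 < fast < slow <= 1).
#' @param tol_mm,tol_deg parameter convergence tolerances.
#' @param max_sweeps maximum direction-set sweeps per optimization round.
#' @param trans_span_mm,rot_span_deg half-width of the rigid search
#'   range around the identity start.
#' @param seed RNG seed for voxel sampling.
#' @return An object of class `mi_config`.
#' @export
mi_config <- function(n_bins = 64L, sample_fraction_fast = 0.05,
                      sample_fraction_slow = 0.5, tol_mm = 1e-3,
                      tol_deg = 1e-3, max_sweeps = 8L,
                      trans_span_mm = 10, rot_span_deg = 4, seed = 1L) {
  if (n_bins < 8L) stopf("`n_bins` must be >= 8")
  if (!(sample_fraction_fast > 0 && sample_fraction_slow <= 1 &&
        sample_fraction_fast < sample_fraction_slow))
    stopf("need 0 < sample_fraction_fast < sample_fraction_slow <= 1")
  structure(
    list(n_bins = as.integer(n_bins),
         sample_fraction_fast = sample_fraction_fast,
         sample_fraction_slow = sample_fraction_slow,
         tol_mm = tol_mm, tol_deg = tol_deg,
         max_sweeps = as.integer(max_sweeps),
         trans_span_mm = trans_span_mm, rot_span_deg = rot_span_deg,
         seed = as.integer(seed)),
    class = "mi_config"
  )
}

# Equal-width binning of values into 1..n_bins over `rng`; degenerate
# ranges collapse to bin 1.
bin_values <- function(x, n_bins, rng = range(x)) {
  w <- rng[2] - rng[1]
  if (w <= 0) return(rep(1L, length(x)))
  b <- floor((x - rng[1]) / w * n_bins) + 1L
  pmin(pmax(b, 1L), n_bins)
}

#' Joint intensity histogram of two volumes under a candidate transform
#'
#' Samples voxel centers of `fixed` (all of them, or a seeded random
#' fraction without replacement), maps them through the inverse candidate
#' transform, samples `moving` trilinearly at the mapped points, and
#' accumulates counts over `n_bins` x `n_bins` equal-width bins spanning
#' each image's sampled min-max. Samples mapping outside the moving
#' volume are discarded; the total count equals the number of in-bounds
#' samples.
#'
#' @param fixed,moving [volume3d()] objects.
#' @param transform candidate [rigid_transform()] mapping moving space to
#'   fixed space.
#' @param cfg an [mi_config()].
#' @param sample_fraction fraction of fixed voxels to sample (default:
#'   all).
#' @return Integer matrix of counts (fixed bins in rows).
#' @export
joint_histogram <- function(fixed, moving, transform = rt_identity(),
                            cfg = mi_config(), sample_fraction = 1) {
  n <- prod(fixed$geometry$shape)
  take <- if (sample_fraction < 1) {
    with_seed(cfg$seed, sort(sample.int(n, max(1L, ceiling(sample_fraction * n)))))
  } else {
    seq_len(n)
  }
  idx <- grid_indices(fixed$geometry$shape)[take, , drop = FALSE]
  a_vals <- as.vector(fixed$values)[take]
  pts <- voxel_to_world(fixed$geometry, idx)
  mpts <- rt_apply(rt_invert(transform), pts)
  midx <- world_to_voxel(moving$geometry, mpts)
  sh <- moving$geometry$shape
  inb <- midx[, 1] >= 0 & midx[, 1] <= sh[1] - 1 &
    midx[, 2] >= 0 & midx[, 2] <= sh[2] - 1 &
    midx[, 3] >= 0 & midx[, 3] <= sh[3] - 1
  if (!any(inb)) stopf("volumes do not overlap under this transform")
  b_vals <- c_trilinear(as.vector(moving$values), sh,
                        midx[inb, , drop = FALSE], 0)
  count_histogram(a_vals[inb], b_vals, cfg$n_bins)
}

count_histogram <- function(a_vals, b_vals, n_bins,
                            a_range = range(a_vals),
                            b_range = range(b_vals)) {
  ai <- bin_values(a_vals, n_bins, a_range)
  bi <- bin_values(b_vals, n_bins, b_range)
  counts <- tabulate((bi - 1L) * n_bins + ai, nbins = n_bins * n_bins)
  matrix(counts, n_bins, n_bins)
}

#' Mutual information of a joint histogram, in bits
#'
#' `MI = sum p(i,j) log2( p(i,j) / (p(i) p(j)) )` with zero-count cells
#' contributing 0. Non-negative, and bounded above by the marginal
#' entropies.
#'
#' @param h count matrix from [joint_histogram()].
#' @return MI in bits.
#' @export
mutual_information <- function(h) {
  tot <- sum(h)
  if (tot <= 0) stopf("histogram has no counts")
  p <- h / tot
  px <- rowSums(p)
  py <- colSums(p)
  nz <- which(p > 0, arr.ind = TRUE)
  v <- p[nz]
  mi <- sum(v * log2(v / (px[nz[, 1]] * py[nz[, 2]])))
  max(mi, 0)
}

marginal_entropy <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Pre-sampled MI objective: the sample positions and histogram ranges
# are frozen once so the similarity surface is a deterministic,
# reasonably smooth function of the transform parameters. Two measures
# keep the estimator artifact-free: samples are drawn at random
# continuous positions (off-grid sampling suppresses the well-known
# mutual-information artifact that favours grid-aligned transforms),
# and the sampling region is eroded by the worst-case displacement of
# the search range, so the sample population stays inside the moving
# volume for every candidate transform (a varying population biases MI
# toward transforms that keep boring border samples in view).
make_mi_objective <- function(fixed, moving, cfg, sample_fraction,
                              center, translation_only) {
  n <- prod(fixed$geometry$shape)
  n_take <- max(1L, ceiling(sample_fraction * n))
  sh <- fixed$geometry$shape
  sp <- fixed$geometry$spacing
  half_mm <- (sh - 1) * sp / 2
  lever <- sqrt(sum(half_mm^2))
  margin_mm <- cfg$trans_span_mm +
    if (translation_only) 0 else sin(cfg$rot_span_deg * pi / 180) * lever
  margin_vox <- pmin(margin_mm / sp, 0.8 * (sh - 1) / 2)
  idx <- with_seed(cfg$seed,
                   cbind(runif(n_take, margin_vox[1], sh[1] - 1 - margin_vox[1]),
                         runif(n_take, margin_vox[2], sh[2] - 1 - margin_vox[2]),
                         runif(n_take, margin_vox[3], sh[3] - 1 - margin_vox[3])))
  a_vals <- c_trilinear(as.vector(fixed$values), sh, idx, 0)
  pts <- voxel_to_world(fixed$geometry, idx)
  a_bins <- bin_values(a_vals, cfg$n_bins, range(fixed$values))
  b_range <- range(moving$values)
  mvals <- as.vector(moving$values)
  msh <- moving$geometry$shape
  mg <- moving$geometry
  # world -> continuous moving index, as a 3x4 affine
  w2v <- cbind(diag(1 / mg$spacing) %*% t(mg$orientation),
               -as.vector(diag(1 / mg$spacing) %*% t(mg$orientation) %*%
                            mg$origin))

  par_to_transform <- function(par) {
    if (translation_only) {
      rigid_transform(c(0, 0, 0), par, center)
    } else {
      rigid_transform(par[1:3], par[4:6], center)
    }
  }

  objective <- function(par) {
    tr <- par_to_transform(par)
    Ainv <- rt_invert(tr)$matrix
    map <- w2v %*% Ainv
    c_mi_objective(mvals, msh, pts, map, a_bins, cfg$n_bins,
                   b_range[1], b_range[2], fill = 0)
  }
  list(objective = objective, par_to_transform = par_to_transform)
}

# Derivative-free direction-set maximization: cyclic line searches along
# the coordinate directions with bracket expansion and golden-section
# refinement, repeated with shrinking initial steps (a restart round
# guards against premature convergence). Parameters are confined to
# [lower, upper] -- the registration search range.
direction_set_maximize <- function(f, par, steps, tol, max_sweeps,
                                   lower, upper, rounds = 2L,
                                   order = NULL) {
  best <- f(par)
  n_eval <- 1L
  line_search <- function(par, i, step) {
    g <- function(x) {
      p <- par
      p[i] <- x
      f(p)
    }
    x0 <- par[i]
    f0 <- best
    # bracket by expansion, clamped to the search range
    lo <- max(x0 - step, lower[i])
    hi <- min(x0 + step, upper[i])
    flo <- g(lo); fhi <- g(hi); n_eval <<- n_eval + 2L
    for (k in 1:5) {
      if (flo > f0 && flo >= fhi) {
        hi <- x0; fhi <- f0
        x0 <- lo; f0 <- flo
        if (lo <= lower[i]) break
        lo <- max(lo - 2^k * step, lower[i])
        flo <- g(lo); n_eval <<- n_eval + 1L
      } else if (fhi > f0) {
        lo <- x0; flo <- f0
        x0 <- hi; f0 <- fhi
        if (hi >= upper[i]) break
        hi <- min(hi + 2^k * step, upper[i])
        fhi <- g(hi); n_eval <<- n_eval + 1L
      } else break
    }
    opt <- optimize(g, lower = lo, upper = hi, maximum = TRUE,
                    tol = tol[i] / 2)
    n_eval <<- n_eval + 30L  # optimize() evaluation budget, approximate
    if (opt$objective > best) {
      best <<- opt$objective
      par[i] <- opt$maximum
    }
    par
  }

  converged <- FALSE
  order <- order %||% seq_along(par)
  for (round in seq_len(rounds)) {
    step <- steps / round
    for (sweep in seq_len(max_sweeps)) {
      old_par <- par
      for (i in order) par <- line_search(par, i, step[i])
      step <- pmax(step / 2, tol)
      if (all(abs(par - old_par) < tol)) {
        converged <- TRUE
        break
      }
    }
  }
  list(par = par, value = best, converged = converged, n_eval = n_eval)
}

#' Rigid registration by mutual-information maximization
#'
#' Derivative-free maximization of the mutual information between the
#' fixed image and the moving image sampled through the candidate
#' transform, over 6 rigid parameters (3 Euler angles, 3 translations)
#' starting from the identity. The `"fast"` and `"slow"` modes use the
#' configured small and large sampling fractions of the fixed grid.
#'
#' @param moving [volume3d()] to be aligned (e.g. the PET).
#' @param fixed [volume3d()] reference (e.g. the CT).
#' @param mode `"fast"` or `"slow"`.
#' @param cfg an [mi_config()].
#' @param translation_only if `TRUE`, rotations are fixed at 0 (useful
#'   for controlled shift experiments).
#' @param center rotation center; defaults to the fixed volume's world
#'   center.
#' @return An object of class `registration_result`: list with
#'   `transform` (mapping moving into fixed space), `mi` (bits),
#'   `n_eval`, `converged`, `mode`.
#' @export
register_rigid <- function(moving, fixed, mode = c("fast", "slow"),
                           cfg = mi_config(), translation_only = FALSE,
                           center = NULL) {
  mode <- match.arg(mode)
  frac <- switch(mode, fast = cfg$sample_fraction_fast,
                 slow = cfg$sample_fraction_slow)
  center <- center %||% world_center(fixed$geometry)
  obj <- make_mi_objective(fixed, moving, cfg, frac, center,
                           translation_only)
  if (translation_only) {
    par0 <- c(0, 0, 0)
    steps <- pmax(fixed$geometry$spacing, 2)
    tol <- rep(cfg$tol_mm, 3)
    lower <- rep(-cfg$trans_span_mm, 3)
    upper <- rep(cfg$trans_span_mm, 3)
  } else {
    par0 <- rep(0, 6)
    steps <- c(rep(1.5, 3), pmax(fixed$geometry$spacing, 2))
    tol <- c(rep(cfg$tol_deg, 3), rep(cfg$tol_mm, 3))
    lower <- c(rep(-cfg$rot_span_deg, 3), rep(-cfg$trans_span_mm, 3))
    upper <- c(rep(cfg$rot_span_deg, 3), rep(cfg$trans_span_mm, 3))
  }
  # translations are searched before rotations within each sweep: they
  # are far better conditioned from the identity start, and resolving
  # them first removes the local rotation/translation trade-off around
  # any single dominant structure
  order <- if (translation_only) 1:3 else c(4:6, 1:3)
  res <- direction_set_maximize(obj$objective, par0, steps, tol,
                                cfg$max_sweeps, lower, upper,
                                order = order)
  structure(
    list(transform = obj$par_to_transform(res$par), mi = res$value,
         n_eval = res$n_eval, converged = res$converged, mode = mode),
    class = "registration_result"
  )
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result [%s]: MI = %.4f bits, %s (%d evaluations)\n",
              x$mode, x$mi,
              if (x$converged) "converged" else "NOT converged", x$n_eval))
  print(x$transform)
  invisible(x)
}
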