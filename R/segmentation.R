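#' Volume of interest around one lesion
#'
#' A rectangular index box enclosing a single lesion plus margin, with a
#' seed point at the lesion maximum. "Measured maximum activity" for the
#' threshold methods is always the maximum inside this box, evaluated on
#' the image being segmented. Box bounds are 1-based R array indices,
#' clamped to the grid; ties for the maximum are broken by lowest linear
#' index.
#'
#' @param v a [volume3d()].
#' @param center_world lesion center, world mm.
#' @param radius_mm lesion radius (max semi-axis), mm.
#' @param margin_mm margin added around the lesion (must leave room for
#'   the background shell), mm.
#' @return An object of class `lesion_voi`: `lo`, `hi` (1-based index
#'   triples) and `seed` (1-based index triple of the box maximum).
#' @export
lesion_voi <- function(v, center_world, radius_mm, margin_mm = 12) {
  g <- v$geometry
  half <- radius_mm + margin_mm
  corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) * half
  corners <- sweep(corners, 2L, as.numeric(center_world), `+`)
  idx <- world_to_voxel(g, corners)
  lo <- pmax(1L, as.integer(floor(apply(idx, 2, min))) + 1L)
  hi <- pmin(g$shape, as.integer(ceiling(apply(idx, 2, max))) + 1L)
  if (any(lo > hi)) stopf("VOI does not intersect the grid")
  sub <- v$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  rel <- arrayInd(which.max(sub), dim(sub))
  structure(list(lo = lo, hi = hi, seed = as.integer(rel) + lo - 1L),
            class = "lesion_voi")
}

voi_values <- function(v, voi) {
  v$values[voi$lo[1]:voi$hi[1], voi$lo[2]:voi$hi[2], voi$lo[3]:voi$hi[3],
           drop = FALSE]
}

voi_max <- function(v, voi) max(voi_values(v, voi))

new_lesion_mask <- function(mask, geometry, method, threshold, voi,
                            converged = TRUE, background = NA_real_,
                            iterations = NA_integer_, f = NA_real_) {
  structure(
    list(mask = mask, geometry = geometry, method = method,
         threshold = threshold, voi = voi, converged = converged,
         background = background, iterations = iterations, f = f),
    class = "lesion_mask"
  )
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("lesion_mask [%s]: %d voxels, threshold %.4g SUV%s\n",
              x$method, sum(x$mask), x$threshold,
              if (isTRUE(x$converged)) "" else " (NOT converged)"))
  invisible(x)
}

# Segment at an absolute threshold inside the VOI and keep the
# 26-connected component containing the seed. Returns a full-grid
# logical array.
threshold_component <- function(v, voi, threshold) {
  sub <- voi_values(v, voi)
  cand <- sub >= threshold
  seed_rel <- voi$seed - voi$lo + 1L
  if (!cand[seed_rel[1], seed_rel[2], seed_rel[3]])
    return(array(FALSE, v$geometry$shape))
  comp <- c_component26(cand, dim(cand), seed_rel)
  mask <- array(FALSE, v$geometry$shape)
  mask[voi$lo[1]:voi$hi[1], voi$lo[2]:voi$hi[2], voi$lo[3]:voi$hi[3]] <- comp
  mask
}

#' Fixed-threshold segmentation (T40 / T50 / T60)
#'
#' Delineates all VOI voxels with a value of at least
#' `fraction x (maximum inside the VOI)` -- the `>=` semantics means a
#' voxel exactly at the threshold is included -- reduced to the
#' 26-connected component containing the seed.
#'
#' @param v a [volume3d()].
#' @param voi a [lesion_voi()].
#' @param fraction threshold fraction of the VOI maximum (0.40, 0.50 and
#'   0.60 give the standard T40/T50/T60 methods).
#' @return A `lesion_mask`.
#' @export
fixed_threshold_segment <- function(v, voi, fraction = 0.40) {
  if (fraction <= 0 || fraction >= 1) stopf("`fraction` must be in (0, 1)")
  mx <- voi_max(v, voi)
  if (mx <= 0) stopf("VOI maximum must be positive")
  thr <- fraction * mx
  mask <- threshold_component(v, voi, thr)
  if (!any(mask)) stopf("empty segmentation")
  new_lesion_mask(mask, v$geometry,
                  method = sprintf("T%.0f", 100 * fraction),
                  threshold = thr, voi = voi)
}

#' Local background estimate around a lesion mask
#'
#' Mean value over a shell of voxels lying between 1 and 3 morphological
#' dilation steps (26-connectivity) outside the mask, restricted to the
#' VOI. This makes "local background" concrete for the
#' background-adapted threshold.
#'
#' @param v a [volume3d()].
#' @param mask a `lesion_mask` (or logical array on the same grid).
#' @param voi the [lesion_voi()]; defaults to the mask's own VOI.
#' @return Background value, SUV.
#' @export
estimate_background <- function(v, mask, voi = NULL) {
  if (inherits(mask, "lesion_mask")) {
    voi <- voi %||% mask$voi
    mask <- mask$mask
  }
  if (is.null(voi)) stopf("`voi` is required when `mask` is a plain array")
  if (!any(mask)) stopf("mask is empty")
  sub_mask <- mask[voi$lo[1]:voi$hi[1], voi$lo[2]:voi$hi[2],
                   voi$lo[3]:voi$hi[3], drop = FALSE]
  dil <- c_dilate26(sub_mask, dim(sub_mask), 3L)
  shell <- dil & !sub_mask
  if (!any(shell)) stopf("background shell is empty")
  sub <- voi_values(v, voi)
  mean(sub[shell])
}

#' Background-adapted volume-reproducing adaptive threshold (AT)
#'
#' Applies a volume-reproducing threshold after subtraction of local
#' background, as a fixed-point iteration: starting from the T40 mask,
#' each step estimates the local background `B` ([estimate_background()]),
#' sets the threshold `T = B + f (max_VOI - B)` and re-segments at `T`;
#' iteration stops when the mask repeats. With zero background the
#' method reduces exactly to a fixed threshold at `f x max`, and the
#' resulting mask is invariant under adding a constant to the entire
#' volume, which distinguishes it from the fixed-threshold methods.
#'
#' @param v a [volume3d()].
#' @param voi a [lesion_voi()].
#' @param f volume-reproducing fraction (default 0.41; see
#'   [calibrate_volume_reproducing_fraction()]).
#' @param max_iter iteration cap; a 2-cycle oscillation returns the last
#'   mask with `converged = FALSE`.
#' @return A `lesion_mask` with fields `background`, `iterations`,
#'   `converged`.
#' @export
adaptive_threshold_segment <- function(v, voi, f = 0.41, max_iter = 40L) {
  if (f <= 0 || f >= 1) stopf("`f` must be in (0, 1)")
  mx <- voi_max(v, voi)
  if (mx <= 0) stopf("VOI maximum must be positive")
  mask <- fixed_threshold_segment(v, voi, 0.40)$mask
  prev <- NULL
  thr <- NA_real_
  bg <- NA_real_
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    bg <- estimate_background(v, mask, voi)
    if (mx <= bg) stopf("VOI maximum does not exceed local background")
    thr <- bg + f * (mx - bg)
    new_mask <- threshold_component(v, voi, thr)
    if (!any(new_mask)) stopf("adaptive threshold produced an empty mask")
    if (identical(new_mask, mask)) {
      converged <- TRUE
      mask <- new_mask
      break
    }
    if (!is.null(prev) && identical(new_mask, prev)) {
      mask <- new_mask  # 2-cycle: keep the latest mask, flag it
      break
    }
    prev <- mask
    mask <- new_mask
  }
  new_lesion_mask(mask, v$geometry, method = "AT", threshold = thr,
                  voi = voi, converged = converged, background = bg,
                  iterations = iter, f = f)
}

#' Segment a lesion with a named method
#'
#' Convenience dispatcher over the four delineation methods.
#'
#' @param v a [volume3d()].
#' @param voi a [lesion_voi()].
#' @param method one of `"AT"`, `"T40"`, `"T50"`, `"T60"`.
#' @param f volume-reproducing fraction for `"AT"`.
#' @return A `lesion_mask`.
#' @export
segment_lesion <- function(v, voi, method = c("AT", "T40", "T50", "T60"),
                           f = 0.41) {
  method <- match.arg(method)
  switch(method,
    AT = adaptive_threshold_segment(v, voi, f = f),
    T40 = fixed_threshold_segment(v, voi, 0.40),
    T50 = fixed_threshold_segment(v, voi, 0.50),
    T60 = fixed_threshold_segment(v, voi, 0.60)
  )
}

#' Calibrate the volume-reproducing fraction of the adaptive threshold
#'
#' Finds the fraction `f` minimizing the mean squared relative volume
#' error of the adaptive threshold over a set of phantoms with known
#' true volumes. Requires at least 3 phantoms spanning at least one
#' decade of volume; the minimizer must lie strictly inside (0.2, 0.8).
#'
#' @param phantoms list of `pet_phantom` objects (see
#'   [generate_phantom()]).
#' @param margin_mm VOI margin used during calibration.
#' @param f_range search interval for `f`.
#' @return The calibrated fraction `f`.
#' @export
calibrate_volume_reproducing_fraction <- function(phantoms,
                                                  margin_mm = 12,
                                                  f_range = c(0.2, 0.8)) {
  if (length(phantoms) < 3L)
    stopf("calibration requires at least 3 phantoms")
  vols <- vapply(phantoms, function(p) p$truth$volume_ml, numeric(1))
  if (max(vols) / min(vols) < 10)
    stopf("calibration phantoms must span at least one decade of volume")
  vois <- lapply(phantoms, function(p)
    lesion_voi(p$volume, p$truth$center, max(p$truth$radii_mm), margin_mm))
  objective <- function(f) {
    err <- vapply(seq_along(phantoms), function(i) {
      m <- adaptive_threshold_segment(phantoms[[i]]$volume, vois[[i]], f = f)
      mtv <- sum(m$mask) * voxel_volume_mm3(phantoms[[i]]$volume$geometry) / 1000
      (mtv - vols[i]) / vols[i]
    }, numeric(1))
    mean(err^2)
  }
  opt <- optimize(objective, lower = f_range[1], upper = f_range[2],
                  tol = 1e-3)
  if (opt$minimum < f_range[1] + 5e-3 || opt$minimum > f_range[2] - 5e-3)
    stopf("no interior minimizer in (%.2f, %.2f)", f_range[1], f_range[2])
  opt$minimum
}
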