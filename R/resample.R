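#' Trilinear sampling of a volume at world points
#'
#' The value at an off-grid point is the convex combination of the 8
#' surrounding voxel values. Points whose continuous voxel index falls
#' outside `[0, shape - 1]` on any axis return `fill` (the out-of-field
#' value; 0 SUV by default, matching the near-zero uptake of air).
#'
#' @param v a [volume3d()].
#' @param points world point (mm) triple or N x 3 matrix.
#' @param fill value returned outside the grid.
#' @return Numeric vector of sampled values.
#' @export
trilinear_sample <- function(v, points, fill = 0) {
  idx <- world_to_voxel(v$geometry, as_point_matrix(points))
  c_trilinear(as.vector(v$values), v$geometry$shape, idx, fill)
}

#' Resample a volume through a rigid transform onto a target grid
#'
#' For each target voxel center `x`, the output value is the trilinear
#' sample of `src` at `transform^-1(x)`; this is the "save the PET in the
#' CT geometry and pixel size" step of rigid coregistration. Because
#' trilinear interpolation is a convex combination, the output maximum
#' never exceeds `max(max(src), fill)`; a transform whose translation is
#' an exact multiple of the voxel size (onto a same-spacing grid) incurs
#' no interpolation at all.
#'
#' @param src a [volume3d()] to resample.
#' @param transform a [rigid_transform()] mapping source space to target
#'   space (identity = the grids are already aligned).
#' @param target an [image_geometry()] to sample onto; defaults to the
#'   source geometry.
#' @param fill out-of-field value.
#' @return A [volume3d()] on `target`.
#' @export
resample_volume <- function(src, transform = rt_identity(), target = NULL,
                            fill = 0) {
  target <- target %||% src$geometry
  inv <- rt_invert(transform)
  idx_t <- grid_indices(target$shape)
  world <- voxel_to_world(target, idx_t)
  src_pts <- rt_apply(inv, world)
  idx_s <- world_to_voxel(src$geometry, src_pts)
  # snap continuous indices that are within rounding error of a grid
  # node onto it, so grid-aligned transforms are exactly
  # interpolation-free instead of bit-noisy
  snapped <- round(idx_s)
  near <- abs(idx_s - snapped) < 1e-9
  idx_s[near] <- snapped[near]
  vals <- c_trilinear(as.vector(src$values), src$geometry$shape, idx_s, fill)
  volume3d(array(vals, target$shape), target, label = src$label)
}
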