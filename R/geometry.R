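#' Image geometry: voxel grid to world (mm) mapping
#'
#' An `image_geometry` describes how a 3D voxel array is embedded in
#' world (scanner) space: the world position of voxel index
#' `v` (0-based, continuous) is `origin + orientation %*% (v * spacing)`.
#' `origin` addresses the *center* of voxel `(0, 0, 0)`; all resampling in
#' this package samples at voxel centers, which is what makes
#' integer-voxel translations onto an identical grid interpolation-free.
#'
#' @param shape integer triple, voxels per axis.
#' @param spacing positive mm triple, voxel size per axis.
#' @param origin mm triple, world position of the center of voxel
#'   `(0,0,0)`. Defaults to placing the grid center at the world origin.
#' @param orientation 3x3 direction matrix; must be orthonormal with
#'   determinant +1.
#' @param label free-text description.
#' @return An object of class `image_geometry`.
#' @export
#' @examples
#' g <- image_geometry(c(168, 168, 40), c(4.1, 4.1, 5.0))
#' voxel_to_world(g, c(0, 0, 0))
image_geometry <- function(shape, spacing, origin = NULL,
                           orientation = diag(3), label = "") {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (length(shape) != 3L || any(shape < 1L))
    stopf("`shape` must be a positive integer triple")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("`spacing` must be a positive mm triple")
  orientation <- as.matrix(orientation)
  if (!all(dim(orientation) == c(3L, 3L)) ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-8 ||
      abs(det(orientation) - 1) > 1e-8)
    stopf("`orientation` must be orthonormal with determinant +1")
  if (is.null(origin)) {
    origin <- -as.vector(orientation %*% ((shape - 1) * spacing / 2))
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stopf("`origin` must be a finite mm triple")
  structure(
    list(shape = shape, spacing = spacing, origin = origin,
         orientation = orientation, label = label),
    class = "image_geometry"
  )
}

#' Scanner grid presets
#'
#' Returns the voxel geometries of the simulated acquisition: the PET
#' reconstruction grid (4.1 x 4.1 x 5.0 mm), the diagnostic CT with 1 mm
#' slices ("ct1", 1.4 x 1.4 x 1.0 mm), and the low-dose CT with 5 mm
#' slices ("ct5", 1.4 x 1.4 x 5.0 mm). The field of view is configurable;
#' the default is a lesion-centered thoracic sub-volume rather than the
#' full scanner matrix, which keeps per-lesion experiments tractable
#' without changing voxel sizes. All presets are centered on the world
#' origin so that the grids are mutually aligned.
#'
#' @param name one of `"pet"`, `"ct1"`, `"ct5"`.
#' @param fov_mm mm triple, approximate field of view per axis.
#' @return An [image_geometry()].
#' @export
geometry_preset <- function(name = c("pet", "ct1", "ct5"),
                            fov_mm = c(131.2, 131.2, 100)) {
  name <- match.arg(name)
  spacing <- switch(name,
    pet = c(4.1, 4.1, 5.0),
    ct1 = c(1.4, 1.4, 1.0),
    ct5 = c(1.4, 1.4, 5.0)
  )
  shape <- pmax(1L, as.integer(round(fov_mm / spacing)))
  image_geometry(shape, spacing, label = name)
}

#' @export
print.image_geometry <- function(x, ...) {
  cat(sprintf("image_geometry%s: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (mm): %.2f %.2f %.2f\n",
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

as_point_matrix <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) != 3L) stopf("points must have 3 columns")
    p
  } else {
    if (length(p) != 3L) stopf("a point must have 3 components")
    matrix(as.numeric(p), 1L, 3L)
  }
}

#' Map continuous voxel indices to world coordinates (and back)
#'
#' Indices are 0-based and continuous; `voxel_to_world()` and
#' [world_to_voxel()] are exact inverses.
#'
#' @param g an [image_geometry()].
#' @param idx continuous 0-based index triple, or an N x 3 matrix.
#' @return World point(s) in mm, same shape as the input.
#' @export
voxel_to_world <- function(g, idx) {
  m <- as_point_matrix(idx)
  out <- sweep(m, 2L, g$spacing, `*`) %*% t(g$orientation)
  out <- sweep(out, 2L, g$origin, `+`)
  if (is.matrix(idx)) out else as.vector(out)
}

#' @param p world point (mm) triple, or an N x 3 matrix.
#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(g, p) {
  m <- as_point_matrix(p)
  out <- sweep(m, 2L, g$origin, `-`) %*% g$orientation  # R^-1 = t(R); x A = t(t(A) x)
  out <- sweep(out, 2L, g$spacing, `/`)
  if (is.matrix(p)) out else as.vector(out)
}

#' Voxel volume of a grid in cubic millimeters
#' @param g an [image_geometry()].
#' @return Scalar, mm^3.
#' @export
voxel_volume_mm3 <- function(g) prod(g$spacing)

#' World position of the grid center
#' @param g an [image_geometry()].
#' @return mm triple.
#' @export
world_center <- function(g) voxel_to_world(g, (g$shape - 1) / 2)

geometry_equal <- function(a, b, tol = 1e-9) {
  all(a$shape == b$shape) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$orientation - b$orientation)) < tol
}

#' A 3D scalar field bound to an image geometry
#'
#' @param values 3D numeric array with dimensions equal to
#'   `geometry$shape`; SUV for PET volumes, arbitrary intensity for CT.
#' @param geometry an [image_geometry()].
#' @param label free-text description.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(values, geometry, label = "") {
  if (!inherits(geometry, "image_geometry"))
    stopf("`geometry` must be an image_geometry")
  if (is.null(dim(values)) || length(dim(values)) != 3L ||
      !all(dim(values) == geometry$shape))
    stopf("`values` must be a 3D array matching geometry$shape")
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values)))
    stopf("`values` must be finite")
  structure(list(values = values, geometry = geometry, label = label),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("volume3d%s: range [%.4g, %.4g]\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              min(x$values), max(x$values)))
  print(x$geometry)
  invisible(x)
}

#' @export
as.array.volume3d <- function(x, ...) x$values
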