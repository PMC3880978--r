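#' Read and write volumes as NIfTI-1
#'
#' The geometry is mapped to and from the NIfTI affine under the
#' voxel-center convention used throughout the package (the affine maps
#' 0-based voxel indices to the world position of the voxel center).
#' Only orthonormal direction matrices with determinant +1 are accepted
#' on read.
#'
#' @param v a [volume3d()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_volume()` returns `path` invisibly; `read_volume()`
#'   returns a [volume3d()].
#' @export
write_volume <- function(v, path) {
  g <- v$geometry
  img <- RNifti::asNifti(v$values)
  RNifti::pixdim(img) <- g$spacing
  aff <- rbind(cbind(g$orientation %*% diag(g$spacing), g$origin),
               c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param label free-text label for the volume read.
#' @export
read_volume <- function(path, label = "") {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stopf("expected a 3D NIfTI volume, got %dD", length(d))
  aff <- RNifti::xform(img)
  M <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(M^2))
  orientation <- M %*% diag(1 / spacing)
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-4)
    stopf("NIfTI affine is not orthonormal; oblique/sheared grids are unsupported")
  if (det(orientation) < 0)
    stopf("NIfTI affine has negative determinant; flipped grids are unsupported")
  g <- image_geometry(d, spacing, origin = aff[1:3, 4],
                      orientation = orientation, label = label)
  volume3d(array(as.numeric(img), d), g, label = label)
}

#' Write a rigid transform to a JSON file (and read it back)
#'
#' @param t a [rigid_transform()].
#' @param path file path.
#' @export
write_transform <- function(t, path) {
  jsonlite::write_json(rt_parameters(t), path, auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(p$rotation_deg, p$translation_mm, p$center_mm)
}
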