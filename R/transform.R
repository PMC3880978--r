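#' Rigid (6-DOF) world-space transforms
#'
#' A rigid transform is parameterized by three Euler angles in degrees
#' (intrinsic Z-Y-X convention: the rotation matrix is
#' `Rz(rz) %*% Ry(ry) %*% Rx(rx)`), a translation in mm, and an explicit
#' rotation center in mm: `x -> R (x - center) + center + translation`.
#'
#' @param rotation angles `c(rx, ry, rz)` in degrees.
#' @param translation mm triple.
#' @param center rotation center, mm triple.
#' @return An object of class `rigid_transform`.
#' @export
#' @examples
#' t <- rigid_transform(rotation = c(0, 0, 10), translation = c(1, 2, 3))
#' rt_apply(rt_compose(t, rt_invert(t)), c(5, 5, 5))
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  rotation <- as.numeric(rotation)
  translation <- as.numeric(translation)
  center <- as.numeric(center)
  if (length(rotation) != 3L || length(translation) != 3L ||
      length(center) != 3L ||
      any(!is.finite(c(rotation, translation, center))))
    stopf("rotation, translation and center must be finite triples")
  R <- euler_to_matrix(rotation)
  t_eff <- center + translation - as.vector(R %*% center)
  A <- rbind(cbind(R, t_eff), c(0, 0, 0, 1))
  dimnames(A) <- NULL
  structure(
    list(matrix = A, rotation = rotation, translation = translation,
         center = center),
    class = "rigid_transform"
  )
}

#' @rdname rigid_transform
#' @export
rt_identity <- function() rigid_transform()

euler_to_matrix <- function(deg) {
  a <- deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

matrix_to_euler <- function(R) {
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  ry <- asin(sy)
  if (abs(cos(ry)) > 1e-9) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {
    rx <- 0  # gimbal lock: fold the x rotation into z
    rz <- atan2(-R[1, 2], R[2, 2])
  }
  c(rx, ry, rz) * 180 / pi
}

# Build a rigid_transform from a homogeneous matrix, expressing the
# translation parameter about the requested center.
rt_from_matrix <- function(A, center = c(0, 0, 0)) {
  R <- A[1:3, 1:3]
  rotation <- matrix_to_euler(R)
  translation <- A[1:3, 4] + as.vector(R %*% center) - center
  out <- rigid_transform(rotation, translation, center)
  out$matrix <- A  # keep the exact matrix, not the re-derived one
  out
}

#' Apply, compose and invert rigid transforms
#'
#' `rt_compose(a, b)` returns the transform mapping `x` to `a(b(x))`;
#' `rt_invert(t)` returns the exact inverse; `rt_apply(t, pts)` maps
#' world points.
#'
#' @param a,b,t `rigid_transform` objects.
#' @param pts world point triple or N x 3 matrix, mm.
#' @return A `rigid_transform`, or transformed points for `rt_apply`.
#' @export
rt_compose <- function(a, b) {
  rt_from_matrix(a$matrix %*% b$matrix, center = b$center)
}

#' @rdname rt_compose
#' @export
rt_invert <- function(t) {
  R <- t$matrix[1:3, 1:3]
  tr <- t$matrix[1:3, 4]
  A <- rbind(cbind(t(R), -as.vector(t(R) %*% tr)), c(0, 0, 0, 1))
  dimnames(A) <- NULL
  rt_from_matrix(A, center = t$center)
}

#' @rdname rt_compose
#' @export
rt_apply <- function(t, pts) {
  m <- as_point_matrix(pts)
  out <- m %*% t(t$matrix[1:3, 1:3])
  out <- sweep(out, 2L, t$matrix[1:3, 4], `+`)
  if (is.matrix(pts)) out else as.vector(out)
}

#' Parameters of a rigid transform
#'
#' @param t a `rigid_transform`.
#' @return List with `rotation_deg`, `translation_mm` and `center_mm`.
#' @export
rt_parameters <- function(t) {
  list(rotation_deg = t$rotation, translation_mm = t$translation,
       center_mm = t$center)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: rot (deg) %.4g %.4g %.4g | trans (mm) %.4g %.4g %.4g\n",
              x$rotation[1], x$rotation[2], x$rotation[3],
              x$translation[1], x$translation[2], x$translation[3]))
  cat(sprintf("  center (mm): %.4g %.4g %.4g\n",
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}
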