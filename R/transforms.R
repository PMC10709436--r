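#' Rigid transforms: 4x4 homogeneous matrices and their 6-parameter form
#'
#' A rigid transform is stored as a plain 4x4 homogeneous matrix
#' (rotation in SO(3), translation in mm) of class `rigid_transform`.
#' The parameter form is `(tx, ty, tz, phix, phiy, phiz)` with angles in
#' degrees and rotation composition sequence y, x, z about the fixed axes
#' of the frame: `R = Rz(phiz) %*% Rx(phix) %*% Ry(phiy)`, i.e. the
#' y-rotation is applied first, then x, then z.
#'
#' @param p numeric length-6 parameter vector `(tx, ty, tz, phix, phiy, phiz)`,
#'   translations in mm, rotations in degrees.
#' @return `params_to_matrix` returns a `rigid_transform` (4x4 matrix);
#'   `matrix_to_params` returns the length-6 parameter vector.
#' @examples
#' M <- params_to_matrix(c(1, 2, 3, 10, -5, 20))
#' max(abs(matrix_to_params(M) - c(1, 2, 3, 10, -5, 20)))
#' @export
params_to_matrix <- function(p) {
  stopifnot(is.numeric(p), length(p) == 6, all(is.finite(p)))
  a <- p[4:6] * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  # R = Rz %*% Rx %*% Ry (sequence y, x, z about fixed axes)
  R <- matrix(c(
    cz * cy - sz * sx * sy, -sz * cx, cz * sy + sz * sx * cy,
    sz * cy + cz * sx * sy,  cz * cx, sz * sy - cz * sx * cy,
    -cx * sy,                sx,      cx * cy), 3, 3, byrow = TRUE)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- p[1:3]
  class(M) <- c("rigid_transform", "matrix", "array")
  M
}

#' @rdname params_to_matrix
#' @param M a 4x4 rigid transform matrix.
#' @export
matrix_to_params <- function(M) {
  assert_rigid(M)
  R <- M[1:3, 1:3]
  sx <- max(-1, min(1, R[3, 2]))
  phix <- asin(sx)
  gimbal <- abs(cos(phix)) < 1e-8
  if (gimbal) {
    # phiy absorbed into phiz by convention; flag the degeneracy
    phiy <- 0
    phiz <- atan2(R[2, 1], R[1, 1])
  } else {
    phiy <- atan2(-R[3, 1], R[3, 3])
    phiz <- atan2(-R[1, 2], R[2, 2])
  }
  p <- c(M[1:3, 4], c(phix, phiy, phiz) * 180 / pi)
  names(p) <- c("tx", "ty", "tz", "phix", "phiy", "phiz")
  if (gimbal) attr(p, "gimbal") <- TRUE
  p
}

#' @rdname params_to_matrix
#' @export
rigid_identity <- function() {
  M <- diag(4)
  class(M) <- c("rigid_transform", "matrix", "array")
  M
}

#' Compose and invert rigid transforms
#'
#' `rigid_compose(A, B, ...)` returns `A %*% B %*% ...` (the rightmost
#' transform is applied to points first); `rigid_invert` is the exact
#' closed-form inverse (transposed rotation, back-rotated translation).
#'
#' @param ... rigid 4x4 matrices.
#' @return a `rigid_transform`.
#' @export
rigid_compose <- function(...) {
  ms <- list(...)
  M <- Reduce(`%*%`, ms)
  class(M) <- c("rigid_transform", "matrix", "array")
  M
}

#' @rdname rigid_compose
#' @param M a rigid 4x4 matrix.
#' @export
rigid_invert <- function(M) {
  assert_rigid(M)
  R <- M[1:3, 1:3]
  Mi <- diag(4)
  Mi[1:3, 1:3] <- t(R)
  Mi[1:3, 4] <- -t(R) %*% M[1:3, 4]
  class(Mi) <- c("rigid_transform", "matrix", "array")
  Mi
}

#' Test / assert that a matrix is a rigid transform
#'
#' @param M matrix to check.
#' @param tol orthonormality tolerance on `R'R - I` and `det(R) - 1`.
#' @return `is_rigid` returns a logical; `assert_rigid` errors if not rigid.
#' @export
is_rigid <- function(M, tol = 1e-6) {
  if (!is.matrix(M) || any(dim(M) != c(4, 4)) || !all(is.finite(M))) return(FALSE)
  if (any(abs(M[4, ] - c(0, 0, 0, 1)) > tol)) return(FALSE)
  R <- M[1:3, 1:3]
  if (max(abs(t(R) %*% R - diag(3))) > tol) return(FALSE)
  abs(det(R) - 1) <= tol
}

#' @rdname is_rigid
#' @export
assert_rigid <- function(M, tol = 1e-6) {
  if (!is_rigid(M, tol)) stop("not a rigid 4x4 transform")
  invisible(M)
}

#' Apply a rigid transform to points
#'
#' @param M rigid 4x4 matrix.
#' @param pts n x 3 matrix of points (mm).
#' @return n x 3 matrix of transformed points.
#' @export
apply_transform <- function(M, pts) {
  pts <- rbind_points(pts)
  sweep(pts %*% t(M[1:3, 1:3]), 2, M[1:3, 4], `+`)
}

#' Rotation angle of a rigid transform
#'
#' Total rotation angle (degrees) from the trace of the rotation block,
#' i.e. the screw-axis rotation magnitude.
#' @param M rigid 4x4 matrix.
#' @export
rotation_angle <- function(M) {
  tr <- sum(diag(M[1:3, 1:3]))
  acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
}

#' Translation vector norm of a rigid transform (mm)
#' @param M rigid 4x4 matrix.
#' @export
translation_norm <- function(M) sqrt(sum(M[1:3, 4]^2))

#' Serialize a rigid transform to / from JSON
#'
#' The JSON carries the row-major 4x4 matrix, the 6-parameter form and a
#' convention tag for the Euler sequence.
#' @param M rigid 4x4 matrix.
#' @param path file to write / read.
#' @export
write_transform_json <- function(M, path) {
  assert_rigid(M)
  obj <- list(
    matrix_row_major = as.vector(t(unclass(M))),
    parameters = as.list(matrix_to_params(M)),
    convention = "translation mm; rotation deg; Euler sequence y,x,z (R = Rz Rx Ry), fixed axes"
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  M <- matrix(obj$matrix_row_major, 4, 4, byrow = TRUE)
  assert_rigid(M)
  class(M) <- c("rigid_transform", "matrix", "array")
  M
}

# coerce a 3-vector or n x 3 matrix to n x 3 matrix
rbind_points <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  stopifnot(ncol(pts) == 3)
  pts
}
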