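# Rotation representations: axis-angle, scalar-last unit quaternions,
# rotation matrices.

#' Convert an axis-angle rotation to a scalar-last quaternion
#'
#' For a unit rotation axis `(x', y', z')` and angle `alpha` in
#' `(-pi, pi]` radians, returns
#' `(x' sin(alpha/2), y' sin(alpha/2), z' sin(alpha/2), cos(alpha/2))`.
#' The result is unit-norm, and the hemisphere with non-negative scalar
#' part is guaranteed by the angle range, which removes the (q, -q)
#' double-cover ambiguity in L1 comparisons of quaternions.
#'
#' @param axis Numeric 3-vector with unit Euclidean norm (checked to
#'   1e-6).
#' @param angle Rotation angle in radians, in `(-pi, pi]`.
#' @return Numeric 4-vector `(x, y, z, w)` with unit norm.
#' @examples
#' axis_angle_to_quaternion(c(0, 0, 1), pi / 2)
#' @export
axis_angle_to_quaternion <- function(axis, angle) {
  if (length(axis) != 3) stop_posevote("axis must be a 3-vector")
  check_finite(c(axis, angle), "axis-angle")
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-6)
    stop_posevote("rotation axis must be unit-norm (|norm - 1| <= 1e-6)")
  if (angle <= -pi || angle > pi)
    stop_posevote("angle must lie in (-pi, pi] radians")
  c(axis * sin(angle / 2), cos(angle / 2))
}

#' Convert a scalar-last quaternion to a rotation matrix
#'
#' @param q Numeric 4-vector `(x, y, z, w)` with norm within 1e-6 of 1
#'   (re-normalized internally).
#' @return A proper orthogonal 3x3 matrix.
#' @examples
#' quaternion_to_rotation(c(0, 0, 0, 1))  # identity
#' @export
quaternion_to_rotation <- function(q) {
  if (length(q) != 4) stop_posevote("quaternion must be a 4-vector")
  check_finite(q, "quaternion")
  n <- sqrt(sum(q^2))
  if (n < 1e-8) stop_posevote("near-zero quaternion has no defined rotation")
  q <- q / n
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + z * w), 2 * (x * z - y * w),
    2 * (x * y - z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z + x * w),
    2 * (x * z + y * w), 2 * (y * z - x * w), 1 - 2 * (x^2 + y^2)
  ), nrow = 3)  # column-major: columns are images of the basis vectors
}

#' Extract the scalar-last quaternion of a rotation matrix
#'
#' Inverse of [quaternion_to_rotation()] up to the double cover; the
#' hemisphere with non-negative scalar part is returned.
#'
#' @param R Proper orthogonal 3x3 matrix.
#' @return Unit 4-vector `(x, y, z, w)` with `w >= 0`.
#' @export
rotation_to_quaternion <- function(R) {
  check_matrix(R, "rotation matrix", ncol = 3)
  if (nrow(R) != 3) stop_posevote("rotation matrix must be 3 x 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop_posevote("matrix is not a proper rotation")
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- 2 * sqrt(tr + 1)
    q <- c((R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s, s / 4)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- 2 * sqrt(R[i, i] - R[j, j] - R[k, k] + 1)
    q <- numeric(4)
    q[i] <- s / 4
    q[j] <- (R[j, i] + R[i, j]) / s
    q[k] <- (R[k, i] + R[i, k]) / s
    q[4] <- (R[k, j] - R[j, k]) / s
  }
  q <- q / sqrt(sum(q^2))
  if (q[4] < 0) q <- -q
  q
}
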