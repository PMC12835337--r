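# Unit quaternions, stored scalar-last: q = (q1, q2, q3, q4) with vector part
# (q1, q2, q3) and scalar q4. A quaternion here encodes the rotation from the
# sensor (body) frame to the navigation (world) frame, so the direction-cosine
# matrix C_ns returned by quat_to_dcm() maps navigation-frame vectors into the
# sensor frame.

#' Normalize a quaternion to unit length
#'
#' @param q Numeric vector of length 4, scalar-last.
#' @return Unit quaternion.
#' @keywords internal
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n == 0) stop("cannot normalize a zero quaternion")
  q / n
}

#' Quaternion for a rotation about an axis
#'
#' @param axis Numeric length-3 rotation axis (need not be unit length).
#' @param angle Rotation angle in radians.
#' @return Unit quaternion, scalar-last.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n == 0) {
    if (abs(angle) > 0) stop("zero axis with non-zero angle")
    return(c(0, 0, 0, 1))
  }
  u <- axis / n
  c(u * sin(angle / 2), cos(angle / 2))
}

#' Direction-cosine matrix (navigation to sensor) from a quaternion
#'
#' Returns the 3x3 orthonormal matrix \eqn{C_{ns}} that rotates a
#' navigation-frame vector into the sensor frame. Its transpose maps sensor
#' to navigation.
#'
#' @param q Unit quaternion (scalar-last); an error is raised when the norm
#'   deviates from 1 by more than `tol`.
#' @param tol Allowed deviation of the quaternion norm from 1.
#' @return 3x3 rotation matrix with determinant +1.
#' @export
quat_to_dcm <- function(q, tol = 1e-6) {
  stopifnot(length(q) == 4, all(is.finite(q)))
  if (abs(sqrt(sum(q^2)) - 1) > tol) {
    stop("quaternion is not unit length (norm deviates by more than tolerance)")
  }
  q1 <- q[1]; q2 <- q[2]; q3 <- q[3]; q4 <- q[4]
  matrix(c(
    1 - 2 * q2^2 - 2 * q3^2, 2 * (q1 * q2 + q3 * q4), 2 * (q1 * q3 - q2 * q4),
    2 * (q1 * q2 - q3 * q4), 1 - 2 * q1^2 - 2 * q3^2, 2 * (q2 * q3 + q1 * q4),
    2 * (q1 * q3 + q2 * q4), 2 * (q2 * q3 - q1 * q4), 1 - 2 * q1^2 - 2 * q2^2
  ), nrow = 3, byrow = TRUE)
}

#' Rotate a sensor-frame vector into the navigation frame
#'
#' @param q Unit quaternion (sensor-to-navigation, scalar-last).
#' @param v Numeric length-3 vector in the sensor frame.
#' @return The vector expressed in the navigation frame.
#' @export
quat_rotate <- function(q, v) {
  # v_n = C_ns' v_s; expanded form avoids building the matrix
  qv <- q[1:3]; qw <- q[4]
  t2 <- 2 * c(qv[2] * v[3] - qv[3] * v[2],
              qv[3] * v[1] - qv[1] * v[3],
              qv[1] * v[2] - qv[2] * v[1])
  v + qw * t2 + c(qv[2] * t2[3] - qv[3] * t2[2],
                  qv[3] * t2[1] - qv[1] * t2[3],
                  qv[1] * t2[2] - qv[2] * t2[1])
}

#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
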