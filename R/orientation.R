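# Orientation estimation: Mahony proportional-integral complementary filter
# on raw (unfiltered) sensor samples, followed by gravity compensation that
# expresses acceleration in the navigation frame with gravity removed.

#' Detect quasi-stationary samples from gyroscope magnitude
#'
#' A sample is stationary when the Euclidean norm of the tri-axial angular
#' velocity is strictly below `threshold` (default 0.0436 rad/s, about
#' 2.5 deg/s).
#'
#' @param gyr n-by-3 matrix of angular velocity in rad/s.
#' @param threshold Positive threshold in rad/s.
#' @return Logical vector, one element per sample.
#' @export
detect_stationary <- function(gyr, threshold = 0.0436) {
  gyr <- as.matrix(gyr)
  if (nrow(gyr) == 0) stop("empty recording")
  stopifnot(threshold > 0)
  sqrt(rowSums(gyr^2)) < threshold
}

#' Estimate the initial gravity vector and orientation
#'
#' Averages accelerometer samples over quasi-stationary periods to estimate
#' the gravity vector in the sensor frame, and derives the initial quaternion
#' that rotates this vector onto the navigation +z axis (zero yaw).
#'
#' @param acc n-by-3 accelerometer matrix in m/s^2.
#' @param stationary Logical mask from [detect_stationary()].
#' @return List with `g_s` (mean gravity vector, sensor frame) and `q0`
#'   (initial unit quaternion, sensor-to-navigation, scalar-last).
#' @export
estimate_initial_gravity <- function(acc, stationary) {
  acc <- as.matrix(acc)
  stopifnot(length(stationary) == nrow(acc))
  if (!any(stationary)) {
    stop("no stationary samples found; supply an initial orientation explicitly")
  }
  g_s <- colMeans(acc[stationary, , drop = FALSE])
  gn <- sqrt(sum(g_s^2))
  if (gn == 0) stop("stationary acceleration averages to zero; cannot orient")
  u <- g_s / gn
  z <- c(0, 0, 1)
  axis <- cross3(u, z)
  s <- sqrt(sum(axis^2))
  cth <- sum(u * z)
  if (s < 1e-12) {
    # aligned or anti-aligned with +z; for the latter pitch 180 deg about x
    q0 <- if (cth > 0) c(0, 0, 0, 1) else c(1, 0, 0, 0)
  } else {
    q0 <- quat_from_axis_angle(axis / s, atan2(s, cth))
  }
  list(g_s = as.numeric(g_s), q0 = q0)
}

#' One step of the Mahony complementary filter
#'
#' Compares the measured acceleration direction with the gravity direction
#' expected from the current orientation, forms the error as their cross
#' product (both unit-normalized), applies a proportional-integral correction
#' to the gyroscope rates, propagates the quaternion with the first-order
#' update matrix, and renormalizes.
#'
#' When the accelerometer magnitude is near zero (free fall or dropout) the
#' correction is skipped and the step is gyro-only.
#'
#' @param q Current unit quaternion (sensor-to-navigation, scalar-last).
#' @param gyr Length-3 angular velocity sample, rad/s.
#' @param acc Length-3 accelerometer sample, m/s^2.
#' @param kp,ki Proportional and integral gains (dimensionless).
#' @param integral Length-3 accumulated integral of the error vector.
#' @param dt Time step in seconds, positive.
#' @return List with `q` (updated unit quaternion) and `integral`.
#' @export
mahony_step <- function(q, gyr, acc, kp = 2.0, ki = 0.1,
                        integral = c(0, 0, 0), dt) {
  stopifnot(dt > 0)
  an <- sqrt(sum(acc^2))
  if (an > 1e-9) {
    g_s <- quat_to_dcm(q) %*% c(0, 0, STANDARD_GRAVITY)
    e <- cross3(acc / an, g_s / sqrt(sum(g_s^2)))
    integral <- integral + e * dt
    w <- gyr + kp * e + ki * integral
  } else {
    w <- gyr
  }
  # q' = q + (dt/2) q (x) (0, w): first-order update matrix, then renormalize
  qv <- q[1:3]; qw <- q[4]
  dv <- qw * w + cross3(qv, w)
  dw <- -sum(qv * w)
  q2 <- quat_normalize(c(qv + 0.5 * dt * dv, qw + 0.5 * dt * dw))
  list(q = q2, integral = integral)
}

#' Subtract gravity from one sensor-frame acceleration sample
#'
#' Rotates the sample into the navigation frame and removes the constant
#' gravity vector (0, 0, g).
#'
#' @param acc Length-3 sensor-frame acceleration, m/s^2.
#' @param q Unit quaternion (sensor-to-navigation).
#' @return Length-3 navigation-frame acceleration with gravity removed.
#' @export
compensate_gravity <- function(acc, q) {
  quat_rotate(q, acc) - c(0, 0, STANDARD_GRAVITY)
}

#' Run the Mahony filter over a recording
#'
#' Produces the per-sample orientation quaternion and the gravity-compensated
#' navigation-frame acceleration. The filter consumes raw (unfiltered)
#' samples; event detection applies its own low-pass filtering downstream.
#'
#' @param rec An [imu_recording].
#' @param kp,ki Mahony gains.
#' @param q0 Initial quaternion; when `NULL` it is estimated from stationary
#'   samples via [estimate_initial_gravity()].
#' @param stationary_threshold Threshold for the initial-gravity mask, rad/s.
#' @param verbose Emit a convergence log line.
#' @return An object of class `orientation_trace`: list with `t`, `q`
#'   (n-by-4), `acc_n` (n-by-3), and `integral` (final PI integral state).
#' @export
estimate_orientation <- function(rec, kp = 2.0, ki = 0.1, q0 = NULL,
                                 stationary_threshold = 0.0436,
                                 verbose = FALSE) {
  stopifnot(inherits(rec, "imu_recording"))
  n <- length(rec$t)
  if (is.null(q0)) {
    mask <- detect_stationary(rec$gyr, stationary_threshold)
    q0 <- estimate_initial_gravity(rec$acc, mask)$q0
    if (verbose) {
      message(sprintf("orientation: %d samples, %.1f%% stationary",
                      n, 100 * mean(mask)))
    }
  }
  dt <- 1 / rec$fs
  qs <- matrix(0, n, 4)
  acc_n <- matrix(0, n, 3)
  q <- quat_normalize(q0)
  integ <- c(0, 0, 0)
  for (i in seq_len(n)) {
    st <- mahony_step(q, rec$gyr[i, ], rec$acc[i, ], kp, ki, integ, dt)
    q <- st$q; integ <- st$integral
    qs[i, ] <- q
    acc_n[i, ] <- compensate_gravity(rec$acc[i, ], q)
  }
  if (verbose) {
    tail_i <- rec$t > rec$t[n] - min(1, rec$t[n] - rec$t[1])
    message(sprintf("orientation: final-second mean |acc_n| = %.3f m/s^2",
                    mean(sqrt(rowSums(acc_n[tail_i, , drop = FALSE]^2)))))
  }
  structure(list(t = rec$t, q = qs, acc_n = acc_n, integral = integ,
                 kp = kp, ki = ki),
            class = "orientation_trace")
}

#' @export
print.orientation_trace <- function(x, ...) {
  cat(sprintf("<orientation_trace> %d samples; mean |acc_n| = %.3f m/s^2\n",
              nrow(x$q), mean(sqrt(rowSums(x$acc_n^2)))))
  invisible(x)
}
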