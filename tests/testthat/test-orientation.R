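# Orientation pipeline: stationarity detection, initial gravity alignment,
# quaternion/DCM conventions, Mahony filter behaviour, gravity compensation.

test_that("stationarity mask uses a strict threshold on the gyro norm", {
  g <- rbind(c(0, 0, 0),
             c(0.0436, 0, 0),              # norm exactly at threshold
             c(0.03, 0.03, 0.03),          # norm ~0.05196
             c(0.02, 0.01, 0.01))          # norm ~0.0245
  m <- detect_stationary(g)
  expect_identical(m, c(TRUE, FALSE, FALSE, TRUE))
  expect_true(all(detect_stationary(matrix(0, 5, 3))))
  expect_error(detect_stationary(matrix(numeric(0), 0, 3)), "empty")
  expect_error(detect_stationary(g, threshold = 0))
})

test_that("initial gravity estimate aligns the mean vector with navigation +z", {
  acc <- matrix(rep(c(0, 0, 9.81), each = 4), 4, 3)
  r <- estimate_initial_gravity(acc, rep(TRUE, 4))
  expect_equal(r$g_s, c(0, 0, 9.81))
  expect_equal(r$q0, c(0, 0, 0, 1))

  # 10 degree tilt about x: rotating the mean by q0 must recover +z gravity
  th <- 10 * pi / 180
  acc <- matrix(rep(9.81 * c(0, sin(th), cos(th)), each = 3), 3, 3, byrow = FALSE)
  r <- estimate_initial_gravity(acc, rep(TRUE, 3))
  expect_equal(quat_rotate(r$q0, r$g_s), c(0, 0, 9.81), tolerance = 1e-9)

  acc <- rbind(c(0, 0, 9.80), c(0, 0, 9.82))
  expect_equal(estimate_initial_gravity(acc, c(TRUE, TRUE))$g_s, c(0, 0, 9.81))

  expect_error(estimate_initial_gravity(acc, c(FALSE, FALSE)),
               "initial orientation")
})

test_that("quaternion-to-DCM matches an independent Rodrigues oracle", {
  expect_equal(quat_to_dcm(c(0, 0, 0, 1)), diag(3))
  set.seed(11)
  for (i in 1:1000) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    aa <- quat_axis_angle(q)
    R_or <- rodrigues(aa$axis, aa$angle)   # sensor -> navigation
    C <- quat_to_dcm(q)
    expect_lt(max(abs(C - t(R_or))), 1e-12)
    expect_lt(max(abs(t(C) %*% C - diag(3))), 1e-12)
  }
  expect_error(quat_to_dcm(c(0, 0, 0, 2)), "unit")
})

test_that("Mahony step has the gravity-aligned fixed point and integrates rates", {
  # stationary, aligned: error vector vanishes and q is unchanged
  s <- mahony_step(c(0, 0, 0, 1), c(0, 0, 0), c(0, 0, 9.81),
                   kp = 2, ki = 0.005, integral = c(0, 0, 0), dt = 0.005)
  expect_equal(s$q, c(0, 0, 0, 1))
  expect_equal(s$integral, c(0, 0, 0))

  # pure gyro integration (gains zero): constant pi/2 rad/s about x for 1 s
  q <- c(0, 0, 0, 1); integ <- c(0, 0, 0)
  for (i in 1:1000) {
    s <- mahony_step(q, c(pi / 2, 0, 0), c(0, 0, 0), 0, 0, integ, 1e-3)
    q <- s$q
  }
  q_exp <- quat_from_axis_angle(c(1, 0, 0), pi / 2)
  angle_err <- 2 * acos(min(1, abs(sum(q * q_exp))))
  expect_lt(angle_err, 1e-3)

  # antiparallel accelerometer: cross product degenerates, gyro-only step
  q0 <- c(0, 0, 0, 1)
  s1 <- mahony_step(q0, c(0.3, 0, 0), c(0, 0, -9.81), 2, 0.005,
                    c(0, 0, 0), 0.005)
  s2 <- mahony_step(q0, c(0.3, 0, 0), c(0, 0, 9e-10), 2, 0.005,
                    c(0, 0, 0), 0.005)  # near-zero: correction skipped
  expect_equal(s1$q, s2$q, tolerance = 1e-12)
})

test_that("gravity compensation removes gravity in the navigation frame", {
  expect_equal(compensate_gravity(c(0, 0, 9.81), c(0, 0, 0, 1)), c(0, 0, 0))
  expect_equal(compensate_gravity(c(0, 0, 0), c(0, 0, 0, 1)), c(0, 0, -9.81))
  th <- 30 * pi / 180
  q <- quat_from_axis_angle(c(1, 0, 0), -th)  # sensor tilted about x
  a_s <- as.numeric(quat_to_dcm(q) %*% c(0, 0, 9.81))
  expect_equal(compensate_gravity(a_s, q), c(0, 0, 0), tolerance = 1e-9)
})

test_that("quaternion norm stays unit across many filter steps", {
  set.seed(5)
  q <- quat_normalize(rnorm(4)); integ <- c(0, 0, 0)
  worst <- 0
  for (i in 1:100000) {
    s <- mahony_step(q, c(0.8, -0.4, 0.2), c(0.3, 0.1, 9.7), 2, 0.005,
                     integ, 0.005)
    q <- s$q; integ <- s$integral
    if (i %% 1000 == 0) worst <- max(worst, abs(sqrt(sum(q^2)) - 1))
  }
  expect_lt(max(worst, abs(sqrt(sum(q^2)) - 1)), 1e-9)
})

test_that("static tilted recordings converge to near-zero residual acceleration", {
  set.seed(21)
  fs <- 200; n <- 10 * fs
  for (tilt in c(10, 30, 55) * pi / 180) {
    a_true <- 9.81 * c(0, sin(tilt), cos(tilt))
    acc <- matrix(rep(a_true, each = n), n, 3) + rnorm(3 * n, sd = 0.2)
    gyr <- matrix(rnorm(3 * n, sd = 0.005), n, 3)
    rec <- imu_recording(seq(0, by = 1 / fs, length.out = n), acc, gyr, fs)
    ori <- estimate_orientation(rec)
    half <- (n %/% 2):n
    # norm of the mean residual: zero-mean sensor noise averages out and
    # what remains is the orientation (tilt) error
    expect_lt(sqrt(sum(colMeans(ori$acc_n[half, ])^2)), 0.05)
  }
})

test_that("the integral gain rejects constant gyro bias", {
  set.seed(31)
  fs <- 200; n <- 10 * fs
  tilt <- 20 * pi / 180
  a_true <- 9.81 * c(0, sin(tilt), cos(tilt))
  acc <- matrix(rep(a_true, each = n), n, 3)
  gyr <- matrix(rep(c(0.02, 0, 0), each = n), n, 3)   # constant bias
  rec <- imu_recording(seq(0, by = 1 / fs, length.out = n), acc, gyr, fs)
  tilt_err <- function(ki) {
    ori <- estimate_orientation(rec, kp = 2, ki = ki)
    mean(sqrt(rowSums(ori$acc_n[(n - fs):n, ]^2)))
  }
  expect_lt(tilt_err(0.5), tilt_err(0))
})
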