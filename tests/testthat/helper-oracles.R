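# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths: rotations via Rodrigues' formula, ICC via
# stats::aov mean squares, sliding-window minima via exhaustive scans.

# rotation matrix from axis-angle (Rodrigues), mapping v -> R v
rodrigues <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# axis-angle of a scalar-last quaternion
quat_axis_angle <- function(q) {
  s <- sqrt(sum(q[1:3]^2))
  if (s < 1e-15) return(list(axis = c(1, 0, 0), angle = 0))
  list(axis = q[1:3] / s, angle = 2 * atan2(s, q[4]))
}

# two-way ANOVA mean squares via stats::aov on long-format data
icc_aov_oracle <- function(m) {
  df <- data.frame(
    y = as.vector(m),
    subject = factor(rep(seq_len(nrow(m)), ncol(m))),
    rater = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  tab <- summary(stats::aov(y ~ subject + rater, data = df))[[1]]
  bms <- tab["subject", "Mean Sq"]
  ems <- tab["Residuals", "Mean Sq"]
  k <- ncol(m)
  list(icc31 = (bms - ems) / (bms + (k - 1) * ems),
       icc3k = (bms - ems) / bms)
}

# exhaustive mid-stance scan: recompute both detector minima and the blended
# timestamp directly from the definitions
ms_bruteforce_oracle <- function(gyr, acc_h, t, ic, tc, prev_var,
                                 trim_frac = 0.1, window_frac = 0.3) {
  fs <- 1 / stats::median(diff(t))
  ct <- tc - ic
  sel <- which(t >= ic + trim_frac * ct & t <= tc - trim_frac * ct)
  win <- max(3L, round(window_frac * ct * fs))
  best_e <- Inf; best_v <- Inf; t_omega <- NA; t_v <- NA; var_a <- NA
  for (k in seq_len(length(sel) - win + 1L)) {
    idx <- sel[k:(k + win - 1L)]
    e <- mean(rowSums(gyr[idx, , drop = FALSE]^2))
    v <- stats::var(acc_h[idx, 1]) + stats::var(acc_h[idx, 2])
    ctr <- t[idx[1]] + (win - 1) / (2 * fs)
    if (e < best_e) { best_e <- e; t_omega <- ctr }
    if (v < best_v) { best_v <- v; t_v <- ctr; var_a <- v }
  }
  w <- if (is.null(prev_var)) 1 else {
    den <- var_a + abs(var_a - prev_var)
    if (den > 0) min(1, max(0, var_a / den)) else 1
  }
  list(ms = w * t_omega + (1 - w) * t_v, t_omega = t_omega, t_v = t_v, w = w)
}

# default noise-free profile used by several deterministic tests
quiet_profile <- function(...) {
  gait_profile(sigma_acc = 0, sigma_gyr = 0, gyro_bias = 0, stride_cv = 0, ...)
}
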