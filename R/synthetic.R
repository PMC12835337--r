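# Synthetic foot-mounted IMU simulator. A running foot is modelled as a
# planar (sagittal) trajectory built from smooth raised-cosine acceleration
# and pitch-rate pulses: a quiet stance, a push-off acceleration pulse around
# toe-off, a swing translation of known stride length, a braking pulse at
# landing, and a pitch-rate profile with the classic foot signature (toe-off
# dip, mid-swing positive peak, terminal dorsiflexion bump, landing dip).
# Because the sensor signals are derived analytically from this trajectory,
# every event time and parameter is known exactly, standing in for an
# optical/force-plate reference. Pulse placement follows impact physiology:
# the braking acceleration peak and the foot-slap pitch dip occur a few
# milliseconds after touchdown, the propulsive peak just after toe-off.

# raised-cosine pulse, unit amplitude, support width w centred at c
rc_bump <- function(t, c, w) {
  u <- t - c
  ifelse(abs(u) < w / 2, 0.5 * (1 + cos(2 * pi * u / w)), 0)
}

# running integral of rc_bump (0 before the support, w/2 after)
rc_bump_int <- function(t, c, w) {
  u <- pmin(pmax(t - c, -w / 2), w / 2)
  0.5 * (u + w / (2 * pi) * sin(2 * pi * u / w)) + w / 4
}

# asymmetric raised-cosine pulse: half-widths wl (rise) and wr (fall), unit
# peak at c, continuously differentiable; area (wl + wr) / 4
rc_bump_asym <- function(t, c, wl, wr) {
  u <- t - c
  ifelse(u < 0, rc_bump(u, 0, wl), rc_bump(u, 0, wr))
}

rc_bump_asym_int <- function(t, c, wl, wr) {
  u <- t - c
  ifelse(u < 0,
         rc_bump_int(u, 0, wl),
         wl / 4 + rc_bump_int(u, 0, wr) - wr / 4)
}

#' Synthetic running profile
#'
#' Defines the gait conditions for [simulate_run()]. Defaults reproduce the
#' population means of overground running at a self-selected comfortable
#' speed (stride time 0.740 s, contact time 0.308 s, stride length 1.929 m,
#' about 2.6 m/s), sampled at 200 Hz with consumer-grade IMU noise.
#'
#' @param n_strides Number of complete (foot-strike to foot-strike) strides
#'   with full ground truth.
#' @param stride_time,contact_time Mean stride and contact time, s.
#' @param stride_length Mean stride length, m.
#' @param peak_pitch_rate Mid-swing sagittal angular-velocity peak, rad/s.
#' @param foot_lift Peak vertical foot excursion during swing, m.
#' @param strike_pattern `"rearfoot"` (landing pitch dip at touchdown) or
#'   `"forefoot"` (attenuated dip shifted earlier, advanced braking peak).
#' @param sigma_acc,sigma_gyr Gaussian sensor noise SDs (m/s^2, rad/s).
#' @param gyro_bias Constant gyroscope bias magnitude, rad/s (random fixed
#'   direction).
#' @param stride_cv Coefficient of variation of per-stride timing and length.
#' @param fs Sampling rate, Hz.
#' @param mass_kg Body mass used for Newton-scale ground-truth forces.
#' @param lead_in_s Standing still period before the first stride, s.
#' @param seed RNG seed; fixes the output bit-exactly.
#' @return A list of class `gait_profile`.
#' @export
gait_profile <- function(n_strides = 12, stride_time = 0.740,
                         contact_time = 0.308, stride_length = 1.929,
                         peak_pitch_rate = 8, foot_lift = 0.12,
                         strike_pattern = c("rearfoot", "forefoot"),
                         sigma_acc = 0.3, sigma_gyr = 0.01,
                         gyro_bias = 0.005, stride_cv = 0.02,
                         fs = 200, mass_kg = 75, lead_in_s = 2, seed = 1L) {
  strike_pattern <- match.arg(strike_pattern)
  stopifnot(n_strides >= 1, stride_time > 0, contact_time > 0,
            contact_time < stride_time, stride_length > 0,
            peak_pitch_rate > 0, foot_lift > 0, fs > 0, mass_kg > 0,
            sigma_acc >= 0, sigma_gyr >= 0, gyro_bias >= 0, stride_cv >= 0,
            lead_in_s > 0)
  structure(as.list(environment()), class = "gait_profile")
}

#' @export
print.gait_profile <- function(x, ...) {
  cat(sprintf(
    "<gait_profile> %d strides, st=%.3fs ct=%.3fs sl=%.3fm (%s strike), fs=%g Hz, seed=%d\n",
    x$n_strides, x$stride_time, x$contact_time, x$stride_length,
    x$strike_pattern, x$fs, x$seed))
  invisible(x)
}

# strike-pattern-dependent pulse shape constants (widths/amplitudes in
# s and rad/s); landing dip offsets are relative to the true touchdown
strike_shape <- function(pattern, peak_pitch_rate) {
  if (pattern == "rearfoot") {
    list(c_to_off = -0.005,
         A_b = 2, w_b = 0.12, c_b_off = -0.07,
         A_ic = 8, w_ic = 0.10, c_ic_off = 0.005,
         brake_off = 0.015)
  } else {
    list(c_to_off = -0.005,
         A_b = 2, w_b = 0.12, c_b_off = -0.08,
         A_ic = 2.5, w_ic = 0.10, c_ic_off = -0.045,
         brake_off = 0.002)
  }
}

#' Simulate a foot-mounted IMU recording of running
#'
#' Builds the analytic foot trajectory described by the profile, projects
#' gravity into the rotating sensor frame, adds seeded Gaussian noise and a
#' constant gyroscope bias, and returns the recording together with the
#' exact ground-truth events and parameters.
#'
#' @param profile A [gait_profile()].
#' @return List with `recording` (an [imu_recording]) and `truth` (class
#'   `synthetic_truth`): `msw` (all mid-swing times), `strides` (data frame
#'   of true `ic`, `ms`, `tc`, `ic_next`, `st`, `ct`, `swt`, `ft`, `sl`,
#'   `sv`, `sf`, `peak_vgrf_bw`, `vgrf_on`, `vgrf_off`), plus the noise-free
#'   navigation-frame acceleration (`acc_n_true`), pitch trace (`theta`) and
#'   the profile itself.
#' @export
simulate_run <- function(profile) {
  stopifnot(inherits(profile, "gait_profile"))
  p <- profile
  set.seed(p$seed)
  K <- p$n_strides + 2L            # gait cycles; first/last lack a full stride
  draw <- function(mu) mu * pmax(0.5, 1 + p$stride_cv * stats::rnorm(K))
  st_k <- draw(p$stride_time)
  ct_k <- pmin(draw(p$contact_time), 0.6 * st_k)
  sl_k <- draw(p$stride_length)
  sh <- strike_shape(p$strike_pattern, p$peak_pitch_rate)

  T_k <- p$lead_in_s + c(0, cumsum(st_k))   # cycle boundaries, length K+1
  total <- T_k[K + 1] + 0.8
  t <- seq(0, total, by = 1 / p$fs)
  n <- length(t)

  wx <- numeric(n)        # sagittal pitch rate, rad/s
  theta <- numeric(n)     # pitch angle, rad
  ay <- numeric(n)        # anterior-posterior navigation-frame accel
  az <- numeric(n)        # vertical navigation-frame accel
  add_pulse <- function(sig, A, c, w) sig + A * rc_bump(t, c, w)

  msw_true <- numeric(K)
  for (k in seq_len(K)) {
    toe <- T_k[k] + ct_k[k]
    land <- T_k[k + 1]
    swing <- land - toe
    msw_true[k] <- toe + swing / 2
    # pitch-rate pulses
    w_m <- 0.16
    pulses <- list(
      list(p$peak_pitch_rate, msw_true[k], w_m),
      list(sh$A_b, land + sh$c_b_off, sh$w_b),
      list(-sh$A_ic, land + sh$c_ic_off, sh$w_ic)
    )
    for (pl in pulses) {
      wx <- wx + pl[[1]] * rc_bump(t, pl[[2]], pl[[3]])
      theta <- theta + pl[[1]] * rc_bump_int(t, pl[[2]], pl[[3]])
    }
    # toe-off dip: one continuous feature — a sharp plantarflexion rise out
    # of quiet stance with a gradual recovery spanning the early swing (so
    # it has a single curvature inflection on each side); its amplitude
    # balances the cycle's net pitch rotation to zero
    wl <- 0.09; wr <- max(0.20, 0.65 * swing)
    A_to <- (p$peak_pitch_rate * w_m + sh$A_b * sh$w_b -
               sh$A_ic * sh$w_ic) / ((wl + wr) / 2)
    wx <- wx - A_to * rc_bump_asym(t, toe + sh$c_to_off, wl, wr)
    theta <- theta - A_to * rc_bump_asym_int(t, toe + sh$c_to_off, wl, wr)
    # anterior-posterior acceleration: push-off pulse then braking pulse;
    # displacement of the pulse pair is exactly V * (centre separation)
    w_p <- 0.12; w_br <- 0.10
    c_p <- toe + 0.02
    c_br <- land + sh$brake_off
    A_p <- 2 * sl_k[k] / (w_p * (c_br - c_p))
    A_br <- A_p * w_p / w_br
    ay <- add_pulse(ay, A_p, c_p, w_p)
    ay <- ay - A_br * rc_bump(t, c_br, w_br)
    # vertical lift: half-sine-squared arc over the swing
    sw_sel <- t >= toe & t <= land
    az[sw_sel] <- az[sw_sel] + 2 * p$foot_lift * (pi / swing)^2 *
      cos(2 * pi * (t[sw_sel] - toe) / swing)
  }

  acc_n_true <- cbind(x = numeric(n), y = ay, z = az)
  # sensor frame: rotate navigation specific force by the pitch angle
  fz <- az + STANDARD_GRAVITY
  acc_s <- cbind(x = numeric(n),
                 y = cos(theta) * ay + sin(theta) * fz,
                 z = -sin(theta) * ay + cos(theta) * fz)
  gyr_s <- cbind(x = wx, y = numeric(n), z = numeric(n))

  if (p$gyro_bias > 0) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    gyr_s <- sweep(gyr_s, 2, p$gyro_bias * u, "+")
  }
  if (p$sigma_acc > 0) acc_s <- acc_s + stats::rnorm(3 * n, sd = p$sigma_acc)
  if (p$sigma_gyr > 0) gyr_s <- gyr_s + stats::rnorm(3 * n, sd = p$sigma_gyr)

  rec <- imu_recording(t, acc_s, gyr_s, fs = p$fs)

  # ground truth for the complete strides j = 1..n_strides:
  # stride j starts at the landing into cycle j+1
  j <- seq_len(p$n_strides)
  ic <- T_k[j + 1]
  ct <- ct_k[j + 1]
  tc <- ic + ct
  ic_next <- T_k[j + 2]
  st <- ic_next - ic
  swt <- ic_next - tc
  ft <- (swt - ct) / 2
  sl <- sl_k[j + 1]
  fmax_bw <- (pi / 2) * (pmax(ft, 0) / ct + 1)
  fmax_n <- fmax_bw * p$mass_kg * STANDARD_GRAVITY
  t25 <- (ct / pi) * asin(pmin(1, 25 / fmax_n))
  strides <- data.frame(
    stride = j, ic = ic, ms = ic + ct / 2, tc = tc, ic_next = ic_next,
    st = st, ct = ct, swt = swt, ft = ft, sl = sl, sv = sl / st,
    sf = 120 / st, peak_vgrf_bw = fmax_bw,
    vgrf_on = ic + t25, vgrf_off = tc - t25
  )
  truth <- structure(
    list(msw = msw_true, strides = strides, acc_n_true = acc_n_true,
         theta = theta, t = t, cycle_starts = T_k, profile = p),
    class = "synthetic_truth")
  list(recording = rec, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d strides (%s strike); st=%.3f+/-%.3fs sl=%.3fm\n",
              nrow(x$strides), x$profile$strike_pattern,
              mean(x$strides$st), stats::sd(x$strides$st),
              mean(x$strides$sl)))
  invisible(x)
}

#' Simulate the same run under a different strike pattern
#'
#' Re-runs [simulate_run()] with only the strike pattern changed; the seed and
#' therefore all true event times and parameters are unchanged — only the
#' stance-adjacent signal morphology differs (attenuated, earlier landing
#' pitch dip and advanced braking peak for forefoot).
#'
#' @param profile A [gait_profile()].
#' @param pattern `"rearfoot"` or `"forefoot"`.
#' @return As [simulate_run()].
#' @export
simulate_strike_pattern_shift <- function(profile,
                                          pattern = c("rearfoot", "forefoot")) {
  pattern <- match.arg(pattern)
  profile$strike_pattern <- pattern
  simulate_run(profile)
}

#' Write ground truth to JSON
#'
#' @param truth A `synthetic_truth` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(msw = truth$msw, strides = truth$strides,
         profile = unclass(truth$profile)[setdiff(names(truth$profile), "")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
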