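# Gait event detection on low-pass-filtered signals. Strides are segmented at
# mid-swing (MSW) peaks of the sagittal angular velocity; within each stride
# the initial contact (IC), mid-stance (MS) and terminal contact (TC) are
# localized either by the conventional angular-velocity rules (AVGS) or by the
# fused kinematic/kinetic scheme (MFD-GED) that combines gyroscope and
# anterior-posterior acceleration candidates with a weighted average.

#' Indices of strict local maxima
#' @keywords internal
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Detect mid-swing events with an adaptive threshold
#'
#' Local maxima of the filtered sagittal angular velocity exceeding the
#' dynamic threshold `mean(wx) + k_sigma * sd(wx)` are confirmed as mid-swing
#' (MSW) events. Peaks closer together than `min_separation_s` are
#' deduplicated, keeping the larger (ties: the earlier) peak. Consecutive MSW
#' pairs delimit strides.
#'
#' @param wx Filtered sagittal (medial-lateral axis) angular velocity, rad/s.
#' @param t Sample times, seconds.
#' @param k_sigma Multiplier on the standard deviation for the threshold.
#' @param min_separation_s Minimum separation between retained peaks.
#' @return Numeric vector of MSW timestamps (at sample resolution).
#' @export
detect_msw <- function(wx, t, k_sigma = 1.0, min_separation_s = 0.4) {
  stopifnot(length(wx) == length(t))
  fs <- 1 / stats::median(diff(t))
  if (length(wx) < fs) stop("signal shorter than one second")
  thr <- mean(wx) + k_sigma * stats::sd(wx)
  cand <- local_maxima(wx)
  cand <- cand[wx[cand] > thr]
  if (length(cand)) {
    # greedy dedup: larger amplitude first, ties earlier
    ord <- order(-wx[cand], t[cand])
    keep <- integer(0)
    for (i in cand[ord]) {
      if (!length(keep) || all(abs(t[i] - t[keep]) >= min_separation_s)) {
        keep <- c(keep, i)
      }
    }
    cand <- sort(keep)
  }
  if (length(cand) < 2) {
    stop("no complete stride: fewer than 2 mid-swing events detected")
  }
  t[cand]
}

#' Interpolated positive-to-non-positive zero crossings
#'
#' @return Times where the signal transitions from > 0 to <= 0, linearly
#'   interpolated between samples.
#' @keywords internal
zero_crossings_down <- function(x, t) {
  n <- length(x)
  i <- which(x[-n] > 0 & x[-1] <= 0)
  if (!length(i)) return(numeric(0))
  t[i] + (t[i + 1] - t[i]) * x[i] / (x[i] - x[i + 1])
}

#' AVGS initial-contact detection within one stride
#'
#' The conventional angular-velocity rule: IC is the negative peak of the
#' sagittal angular velocity shortly after mid-swing; the zero-crossing
#' refinement takes the first positive-to-non-positive transition after MSW
#' instead (sub-sample, linearly interpolated).
#'
#' @param wx Filtered sagittal angular velocity.
#' @param t Sample times.
#' @param window Length-2 numeric: the stride window (MSW to next MSW).
#' @param search_frac Fraction of the stride after MSW searched for the
#'   negative peak (the IC signature precedes the next stance's toe-off dip).
#' @return List with `ic_negpeak`, `ic_zerocross` (NA when absent) and
#'   `flags` (character).
#' @export
detect_ic_avgs <- function(wx, t, window, search_frac = 0.5) {
  stride <- window[2] - window[1]
  lo <- window[1]; hi <- window[1] + search_frac * stride
  sel <- which(t > lo & t <= hi)
  if (length(sel) < 3) stop("stride window too short for IC detection")
  neg <- t[sel[which.min(wx[sel])]]
  zc <- zero_crossings_down(wx[sel], t[sel])
  flags <- character(0)
  if (!length(zc)) {
    zc <- NA_real_
    flags <- "no_zero_crossing"
  } else {
    zc <- zc[1]
  }
  list(ic_negpeak = neg, ic_zerocross = zc, flags = flags)
}

#' Fused (MFD-GED) initial-contact detection
#'
#' Inside a stride-adaptive search window (30 percent of the stride duration,
#' centered on the coarse AVGS estimate) the kinematic candidate is the
#' sagittal angular-velocity zero crossing nearest the coarse estimate, the
#' kinetic candidate is the largest-magnitude anterior-posterior acceleration
#' peak (the braking impact transient), and the final IC is their weighted
#' linear combination with the dominant weight on the acceleration.
#'
#' @param wx,a_ap Filtered sagittal angular velocity / anterior-posterior
#'   acceleration.
#' @param t Sample times.
#' @param ic_coarse Coarse IC from [detect_ic_avgs()].
#' @param stride_duration Stride duration in seconds.
#' @param w_acc Weight on the kinetic (acceleration) candidate; the
#'   kinematic weight is `1 - w_acc`.
#' @param window_frac Total window width as a fraction of the stride.
#' @param stride_window Optional length-2 clip interval (the stride itself).
#' @return List with `ic`, `ic_kinematic`, `ic_kinetic`, `flags`.
#' @export
detect_ic_fused <- function(wx, a_ap, t, ic_coarse, stride_duration,
                            w_acc = 0.7, window_frac = 0.3,
                            stride_window = NULL) {
  stopifnot(w_acc >= 0, w_acc <= 1)
  half <- window_frac / 2 * stride_duration
  lo <- ic_coarse - half; hi <- ic_coarse + half
  if (!is.null(stride_window)) {
    lo <- max(lo, stride_window[1]); hi <- min(hi, stride_window[2])
  }
  sel <- which(t >= lo & t <= hi)
  flags <- character(0)
  t_kin <- NA_real_
  if (length(sel) >= 3) {
    zc <- zero_crossings_down(wx[sel], t[sel])
    if (length(zc)) t_kin <- zc[which.min(abs(zc - ic_coarse))]
    t_acc <- t[sel[which.max(abs(a_ap[sel]))]]
  } else {
    t_acc <- NA_real_
  }
  if (is.na(t_acc)) {
    flags <- c(flags, "ic_no_candidates")
    ic <- ic_coarse
  } else if (is.na(t_kin)) {
    flags <- c(flags, "ic_no_kinematic_candidate")
    ic <- t_acc
  } else {
    ic <- w_acc * t_acc + (1 - w_acc) * t_kin
  }
  list(ic = ic, ic_kinematic = t_kin, ic_kinetic = t_acc, flags = flags)
}

#' Fused (MFD-GED) terminal-contact detection
#'
#' Searches a dynamic forward-projected window after IC. The AVGS reference is
#' the toe-off dip (sagittal angular-velocity minimum in the window); the
#' kinematic candidate is the angular-velocity inflection (zero crossing of
#' its second difference) nearest that dip; the kinetic candidate is the
#' propulsive (signed positive) anterior-posterior acceleration peak. TC is
#' their weighted average and is guaranteed to lie after IC.
#'
#' @inheritParams detect_ic_fused
#' @param ic Localized initial contact, seconds.
#' @param search_lo_frac,search_hi_frac Window bounds after IC as fractions
#'   of the stride duration.
#' @return List with `tc`, `tc_avgs` (toe-off dip), `tc_kinematic`,
#'   `tc_kinetic`, `flags`.
#' @export
detect_tc_fused <- function(wx, a_ap, t, ic, stride_duration,
                            w_acc = 0.7, search_lo_frac = 0.1,
                            search_hi_frac = 0.6) {
  lo <- ic + search_lo_frac * stride_duration
  hi <- ic + search_hi_frac * stride_duration
  sel <- which(t >= lo & t <= hi)
  flags <- character(0)
  if (length(sel) < 5) {
    stop("empty terminal-contact search window")
  }
  tc_avgs <- t[sel[which.min(wx[sel])]]
  # inflection: the curvature sign change entering the valley floor of the
  # toe-off dip (second difference crossing from negative to non-negative),
  # nearest the dip minimum
  d2 <- diff(wx[sel], differences = 2)
  tm <- t[sel][2:(length(sel) - 1)]
  i <- which(d2[-length(d2)] < 0 & d2[-1] >= 0)
  t_kin <- NA_real_
  if (length(i)) {
    zc <- tm[i] + (tm[i + 1] - tm[i]) * d2[i] / (d2[i] - d2[i + 1])
    t_kin <- zc[which.min(abs(zc - tc_avgs))]
  }
  ap <- a_ap[sel]
  t_acc <- if (any(ap > 0)) t[sel[which.max(ap)]] else NA_real_
  if (is.na(t_acc) && is.na(t_kin)) {
    flags <- c(flags, "tc_no_candidates")
    tc <- tc_avgs
  } else if (is.na(t_acc)) {
    flags <- c(flags, "tc_no_kinetic_candidate")
    tc <- t_kin
  } else if (is.na(t_kin)) {
    flags <- c(flags, "tc_no_kinematic_candidate")
    tc <- t_acc
  } else {
    tc <- w_acc * t_acc + (1 - w_acc) * t_kin
  }
  if (tc <= ic) {
    flags <- c(flags, "tc_fallback_avgs")
    tc <- tc_avgs
  }
  list(tc = tc, tc_avgs = tc_avgs, tc_kinematic = t_kin,
       tc_kinetic = t_acc, flags = flags)
}

#' Mid-stance detection by dual-detector sliding windows
#'
#' Over the stance phase with its first and last 10 percent excluded, a
#' sliding window of 30 percent of the stance duration locates (a) the
#' minimum mean tri-axial angular-velocity energy (time `t_omega`) and (b)
#' the minimum horizontal-plane (navigation frame x, y) acceleration variance
#' (time `t_v`). The two are blended with the adaptive weight
#' `w = var_a / (var_a + |var_a - var_a_prev|)` (clamped to \[0, 1\]), where
#' `var_a_prev` is the acceleration variance retained from the previous
#' stride; the first stride uses `w = 1`.
#'
#' @param gyr n-by-3 filtered angular velocity, rad/s.
#' @param acc_h n-by-2 filtered horizontal-plane navigation-frame
#'   acceleration, m/s^2.
#' @param t Sample times.
#' @param ic,tc Stance boundaries, seconds.
#' @param prev_var Horizontal-acceleration variance from the previous stride,
#'   or `NULL` for the first stride.
#' @param trim_frac Fraction of stance excluded at each end.
#' @param window_frac Sliding-window length as a fraction of stance.
#' @return List with `ms` (seconds), `var` (variance to carry forward),
#'   `t_omega`, `t_v`, `w`, `flags`.
#' @export
detect_ms <- function(gyr, acc_h, t, ic, tc, prev_var = NULL,
                      trim_frac = 0.1, window_frac = 0.3) {
  stopifnot(tc > ic)
  fs <- 1 / stats::median(diff(t))
  ct <- tc - ic
  sel <- which(t >= ic + trim_frac * ct & t <= tc - trim_frac * ct)
  win <- max(3L, round(window_frac * ct * fs))
  if (length(sel) <= win + 2 || ct * fs <= 10) {
    return(list(ms = ic + ct / 2, var = if (is.null(prev_var)) 0 else prev_var,
                t_omega = NA_real_, t_v = NA_real_, w = NA_real_,
                flags = "ms_stance_too_short"))
  }
  energy <- rowSums(gyr[sel, , drop = FALSE]^2)
  ah <- acc_h[sel, , drop = FALSE]
  nwin <- length(sel) - win + 1L
  e_mean <- numeric(nwin); v_sum <- numeric(nwin)
  for (k in seq_len(nwin)) {
    idx <- k:(k + win - 1L)
    e_mean[k] <- mean(energy[idx])
    v_sum[k] <- stats::var(ah[idx, 1]) + stats::var(ah[idx, 2])
  }
  centers <- t[sel][seq_len(nwin)] + (win - 1) / (2 * fs)
  t_omega <- centers[which.min(e_mean)]   # ties resolve to the earliest
  k_v <- which.min(v_sum)
  t_v <- centers[k_v]
  var_a <- v_sum[k_v]
  if (is.null(prev_var)) {
    w <- 1
  } else {
    denom <- var_a + abs(var_a - prev_var)
    w <- if (denom > 0) var_a / denom else 1
    w <- min(1, max(0, w))
  }
  list(ms = w * t_omega + (1 - w) * t_v, var = var_a,
       t_omega = t_omega, t_v = t_v, w = w, flags = character(0))
}

#' Detect all gait events in a recording
#'
#' Runs mid-swing segmentation and per-stride IC/MS/TC localization using
#' either the fused MFD-GED scheme or the conventional AVGS baseline.
#' Signals are low-pass filtered (zero phase) before detection; the
#' anterior-posterior acceleration channel is the sensor-frame y axis and the
#' horizontal-plane channels for mid-stance are navigation-frame x and y.
#'
#' @param rec An [imu_recording].
#' @param orientation An `orientation_trace` from [estimate_orientation()]
#'   (needed for the horizontal-plane acceleration); computed on the fly
#'   when `NULL`.
#' @param method `"mfdged"` (fused) or `"avgs"` (baseline).
#' @param config A [gait_config()] list (event-related entries are used).
#' @return An object of class `gait_events`: list with `msw` (timestamps)
#'   and `strides`, a data.frame with columns `ic`, `ms`, `tc`, candidate
#'   columns, `method` and `flags`.
#' @export
detect_events <- function(rec, orientation = NULL,
                          method = c("mfdged", "avgs"),
                          config = gait_config()) {
  method <- match.arg(method)
  stopifnot(inherits(rec, "imu_recording"))
  if (is.null(orientation)) {
    orientation <- estimate_orientation(rec, kp = config$mahony$kp,
                                        ki = config$mahony$ki)
  }
  fs <- rec$fs
  flt <- function(x) butterworth_lowpass(x, fs, config$filter$cutoff_hz,
                                         config$filter$order)
  wx <- flt(rec$gyr[, 1])
  a_ap <- flt(rec$acc[, 2])
  gyr_f <- flt(rec$gyr)
  acc_h <- flt(orientation$acc_n[, 1:2])
  t <- rec$t

  msw <- detect_msw(wx, t, config$msw$k_sigma, config$msw$min_separation_s)
  n_str <- length(msw) - 1L
  out <- vector("list", n_str)
  prev_var <- NULL
  for (k in seq_len(n_str)) {
    win <- c(msw[k], msw[k + 1])
    sd_k <- diff(win)
    avgs <- detect_ic_avgs(wx, t, win, config$ic$search_frac)
    flags <- avgs$flags
    if (method == "avgs") {
      ic <- avgs$ic_negpeak
      ic_kin <- avgs$ic_zerocross; ic_acc <- NA_real_
      tcd <- detect_tc_fused(wx, a_ap, t, ic, sd_k, w_acc = config$tc$w_acc,
                             search_lo_frac = config$tc$search_lo_frac,
                             search_hi_frac = config$tc$search_hi_frac)
      tc <- tcd$tc_avgs
      tc_kin <- tcd$tc_kinematic; tc_acc <- NA_real_
    } else {
      fic <- detect_ic_fused(wx, a_ap, t, avgs$ic_negpeak, sd_k,
                             w_acc = config$ic$w_acc,
                             window_frac = config$ic$window_frac,
                             stride_window = win)
      ic <- fic$ic; ic_kin <- fic$ic_kinematic; ic_acc <- fic$ic_kinetic
      flags <- c(flags, fic$flags)
      tcd <- detect_tc_fused(wx, a_ap, t, ic, sd_k, w_acc = config$tc$w_acc,
                             search_lo_frac = config$tc$search_lo_frac,
                             search_hi_frac = config$tc$search_hi_frac)
      tc <- tcd$tc; tc_kin <- tcd$tc_kinematic; tc_acc <- tcd$tc_kinetic
      flags <- c(flags, tcd$flags)
    }
    msd <- detect_ms(gyr_f, acc_h, t, ic, tc, prev_var,
                     trim_frac = config$ms$trim_frac,
                     window_frac = config$ms$window_frac)
    prev_var <- msd$var
    flags <- c(flags, msd$flags)
    out[[k]] <- data.frame(
      stride = k, ic = ic, ms = msd$ms, tc = tc,
      ic_kinematic = ic_kin, ic_kinetic = ic_acc,
      tc_kinematic = tc_kin, tc_kinetic = tc_acc,
      ms_weight = msd$w, method = method,
      flags = paste(flags, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  strides <- do.call(rbind, out)
  bad <- which(!(msw[-length(msw)] < strides$ic & strides$ic < strides$ms &
                   strides$ms < strides$tc & strides$tc < msw[-1]))
  if (length(bad)) {
    strides$flags[bad] <- paste(strides$flags[bad], "event_order_violation",
                                sep = ";")
  }
  structure(list(msw = msw, strides = strides, method = method),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> method=%s: %d mid-swing events, %d strides\n",
              x$method, length(x$msw), nrow(x$strides)))
  nflag <- sum(nzchar(gsub(";", "", x$strides$flags)))
  if (nflag) cat(sprintf("  %d stride(s) carry warning flags\n", nflag))
  invisible(x)
}
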