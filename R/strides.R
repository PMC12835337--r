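# ZUPT-anchored stride reconstruction: gravity-compensated navigation-frame
# acceleration is integrated between consecutive mid-stance anchors (where
# foot velocity is physically zero), the endpoint velocity error is linearly
# redistributed across the stride, and the corrected velocity is integrated
# again to yield the stride displacement.

#' Integrate acceleration to raw velocity over one stride
#'
#' Cumulative trapezoidal integration with zero initial velocity at the
#' stride's starting mid-stance anchor.
#'
#' @param acc_n n-by-3 navigation-frame acceleration (gravity removed).
#' @param t Sample times for the rows of `acc_n`.
#' @param interval Length-2 numeric: the integration interval (consecutive
#'   mid-stance anchors), seconds.
#' @return List with `t` (sample times inside the interval) and `v` (m-by-3
#'   raw velocity, first row zero).
#' @export
integrate_velocity <- function(acc_n, t, interval) {
  sel <- which(t >= interval[1] & t <= interval[2])
  if (length(sel) < 3) stop("integration interval shorter than 3 samples")
  ts <- t[sel]
  v <- pracma::cumtrapz(ts, acc_n[sel, , drop = FALSE])
  list(t = ts, v = v)
}

#' Linear ZUPT drift correction
#'
#' Removes the endpoint velocity error by subtracting `(j/n) * v[n]` from
#' every sample `j` on each axis, enforcing zero velocity exactly at both
#' stride boundaries. A purely linear drift is annihilated exactly, and the
#' operation is idempotent.
#'
#' @param v m-by-3 (or vector) raw velocity with `v[1, ] = 0`.
#' @return Corrected velocity of the same shape.
#' @export
drift_correct <- function(v) {
  v <- as.matrix(v)
  m <- nrow(v)
  if (m < 2) stop("need at least 2 samples")
  w <- (seq_len(m) - 1) / (m - 1)
  v - outer(w, v[m, ])
}

#' Stride displacement and stride length
#'
#' Integrates the drift-corrected velocity to the net displacement and
#' reports the stride length as the horizontal-plane resultant
#' `sqrt(dx^2 + dy^2)` (the vertical component is excluded).
#'
#' @param v m-by-3 corrected velocity.
#' @param t Sample times matching the rows of `v`.
#' @return List with `disp` (length-3 net displacement, m) and `sl`
#'   (stride length, m).
#' @export
stride_displacement <- function(v, t) {
  v <- as.matrix(v)
  disp <- vapply(seq_len(ncol(v)), function(j) pracma::trapz(t, v[, j]),
                 numeric(1))
  list(disp = disp, sl = sqrt(disp[1]^2 + disp[2]^2))
}

#' Reconstruct all strides between mid-stance anchors
#'
#' @param acc_n n-by-3 navigation-frame acceleration (gravity removed,
#'   unfiltered by the event filter).
#' @param t Sample times.
#' @param ms_anchors Increasing mid-stance timestamps; stride `i` spans
#'   `ms_anchors[i]` to `ms_anchors[i + 1]`.
#' @return Data frame with one row per stride: `stride`, `t_start`, `t_end`,
#'   `disp_x`, `disp_y`, `disp_z`, `sl`; the per-stride corrected velocity
#'   series are attached as the `"velocities"` attribute.
#' @export
reconstruct_strides <- function(acc_n, t, ms_anchors) {
  ms_anchors <- sort(ms_anchors)
  n <- length(ms_anchors) - 1L
  if (n < 1) stop("need at least two mid-stance anchors")
  rows <- vector("list", n)
  vels <- vector("list", n)
  for (i in seq_len(n)) {
    iv <- integrate_velocity(acc_n, t, ms_anchors[i + c(0, 1)])
    vc <- drift_correct(iv$v)
    sd_ <- stride_displacement(vc, iv$t)
    rows[[i]] <- data.frame(stride = i, t_start = ms_anchors[i],
                            t_end = ms_anchors[i + 1],
                            disp_x = sd_$disp[1], disp_y = sd_$disp[2],
                            disp_z = sd_$disp[3], sl = sd_$sl)
    vels[[i]] <- list(t = iv$t, v_raw = iv$v, v_corr = vc)
  }
  out <- do.call(rbind, rows)
  attr(out, "velocities") <- vels
  out
}
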