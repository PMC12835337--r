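# Per-stride spatiotemporal and kinetic parameters: stride/contact/swing
# times from the event timestamps, flight time under the single-foot symmetry
# assumption, stride frequency and velocity, and the spring-mass (SLIP)
# sinusoidal approximation of the vertical ground reaction force.

#' Temporal parameters of one stride
#'
#' @param ic,tc Initial and terminal contact of the stride, seconds.
#' @param ic_next Initial contact of the following stride (same foot).
#' @return List with `st` (stride time), `ct` (contact time) and `swt`
#'   (swing time), seconds; `st = ct + swt` by construction.
#' @export
temporal_parameters <- function(ic, tc, ic_next) {
  if (!(ic < tc && tc < ic_next)) {
    stop(sprintf("event ordering violated (ic=%.3f, tc=%.3f, next ic=%.3f)",
                 ic, tc, ic_next))
  }
  list(st = ic_next - ic, ct = tc - ic, swt = ic_next - tc)
}

#' Flight time from swing and contact time
#'
#' Under left-right symmetry both feet share the contact time, so the flight
#' phase (both feet airborne) is `(swt - ct) / 2`. Negative values (grounded
#' gait) are returned as-is with a flag.
#'
#' @param swt,ct Swing and contact time, seconds.
#' @return List with `ft` (seconds) and `flags`.
#' @export
flight_time <- function(swt, ct) {
  ft <- (swt - ct) / 2
  list(ft = ft, flags = if (ft < 0) "no_flight" else character(0))
}

#' Stride frequency in steps per minute
#'
#' One stride comprises two steps, hence `120 / st`.
#'
#' @param st Stride time, seconds, positive.
#' @return Steps per minute.
#' @export
stride_frequency <- function(st) {
  if (any(st <= 0)) stop("stride time must be positive")
  120 / st
}

#' Stride velocity
#'
#' @param sl Stride length, m.
#' @param st Stride time, s, positive.
#' @return m/s.
#' @export
stride_velocity <- function(sl, st) {
  if (any(st <= 0)) stop("stride time must be positive")
  sl / st
}

#' Spring-mass (SLIP) vertical ground reaction force waveform
#'
#' Sinusoidal stance-phase approximation
#' `F(t) = (pi/2) m g (ft/ct + 1) sin(pi t / ct)`, zero at touchdown and
#' toe-off. Negative flight times are clipped to zero inside the model (with
#' a flag) to keep the force physical.
#'
#' @param mass_kg Body mass, kg, positive.
#' @param ft,ct Flight and contact time, seconds.
#' @param t_grid Times since touchdown, in `[0, ct]`.
#' @return Numeric vector of forces in Newtons.
#' @export
vgrf_waveform <- function(mass_kg, ft, ct, t_grid) {
  if (mass_kg <= 0) stop("mass must be positive")
  if (ct <= 0) stop("contact time must be positive")
  ft <- max(ft, 0)
  (pi / 2) * mass_kg * STANDARD_GRAVITY * (ft / ct + 1) * sin(pi * t_grid / ct)
}

#' Peak vertical ground reaction force in body weights
#'
#' Closed-form maximum of the SLIP sinusoid: `(pi/2) (ft/ct + 1)`,
#' dimensionless (multiples of body weight).
#'
#' @param ft,ct Flight and contact time, seconds; negative `ft` is clipped
#'   to zero (flagged).
#' @return List with `fmax_bw` and `flags`.
#' @export
peak_vgrf <- function(ft, ct) {
  if (ct <= 0) stop("contact time must be positive")
  flags <- character(0)
  if (ft < 0) {
    ft <- 0
    flags <- "ft_clipped"
  }
  list(fmax_bw = (pi / 2) * (ft / ct + 1), flags = flags)
}

#' Assemble the per-stride parameter table
#'
#' Joins detected events with reconstructed stride lengths and derives the
#' eight per-stride outputs: stride velocity (SV), stride length (SL), stride
#' frequency (SF), stride time (ST), contact time (CT), swing time (SWT),
#' flight time (FT) and peak vertical ground reaction force (BW, and Newtons
#' when a body mass is supplied).
#'
#' @param events A `gait_events` object.
#' @param strides Data frame from [reconstruct_strides()] whose stride `i`
#'   spans the mid-stance anchors of event strides `i` and `i + 1`.
#' @param mass_kg Optional body mass for Newton-scale forces.
#' @return Data frame with one row per complete stride.
#' @export
stride_parameters <- function(events, strides, mass_kg = NULL) {
  ev <- events$strides
  n <- nrow(ev) - 1L
  if (n < 1) stop("need at least two event strides for parameters")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tp <- temporal_parameters(ev$ic[i], ev$tc[i], ev$ic[i + 1])
    ftr <- flight_time(tp$swt, tp$ct)
    pk <- peak_vgrf(ftr$ft, tp$ct)
    sl <- strides$sl[i]
    flags <- c(ftr$flags, pk$flags)
    rows[[i]] <- data.frame(
      stride = i, ic = ev$ic[i], tc = ev$tc[i], ms = ev$ms[i],
      sv = stride_velocity(sl, tp$st), sl = sl,
      sf = stride_frequency(tp$st), st = tp$st, ct = tp$ct, swt = tp$swt,
      ft = ftr$ft, peak_vgrf_bw = pk$fmax_bw,
      peak_vgrf_n = if (is.null(mass_kg)) NA_real_ else
        pk$fmax_bw * mass_kg * STANDARD_GRAVITY,
      flags = paste(flags, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}
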