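# Zero-phase Butterworth low-pass filtering for event detection. Coefficients
# come from signal::butter; the forward-backward pass is applied here with
# odd-reflection edge padding and steady-state initial conditions so that
# constant signals pass through unchanged and no phase lag is introduced
# (event timestamps must not be shifted). The effective magnitude response is
# the squared single-pass Butterworth response.

#' Single IIR pass assuming the signal was at steady state `x0` beforehand
#'
#' Runs b(z)/a(z) over `x` with the filter state initialized as if the input
#' had been the constant `x0` forever, so a constant signal maps to itself
#' exactly (DC gain 1 filters) with no start-up transient.
#' @keywords internal
iir_filter <- function(b, a, x, x0 = x[1]) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b); m <- length(a) - 1
  # moving-average part with constant pre-history x0
  u <- stats::filter(c(rep(x0, nb - 1), x), b, method = "convolution", sides = 1)
  u <- as.numeric(u)[nb - 1 + seq_along(x)]
  if (m == 0) return(u)
  y0 <- x0 * sum(b) / sum(c(1, a[-1]))
  y <- stats::filter(u, -a[-1], method = "recursive", init = rep(y0, m))
  as.numeric(y)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Fourth-order 6 Hz low-pass by default, applied forward and backward
#' (zero phase). Edges are handled by odd-reflection padding with
#' steady-state initial conditions, so a constant signal is returned
#' unchanged and filtered extrema are not time-shifted.
#'
#' @param x Numeric vector, or a matrix filtered column-wise.
#' @param fs Sampling rate in Hz.
#' @param cutoff_hz Cutoff frequency, must be below `fs/2`.
#' @param order Filter order (of each pass).
#' @param zero_phase Apply the backward pass as well (default `TRUE`).
#' @return Filtered signal of identical shape.
#' @export
butterworth_lowpass <- function(x, fs, cutoff_hz = 6, order = 4,
                                zero_phase = TRUE) {
  stopifnot(order >= 1, cutoff_hz > 0)
  if (cutoff_hz >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  if (is.matrix(x)) {
    return(apply(x, 2, butterworth_lowpass, fs = fs, cutoff_hz = cutoff_hz,
                 order = order, zero_phase = zero_phase))
  }
  n <- length(x)
  if (n <= 3 * order) stop("signal too short to filter (need > 3 * order samples)")
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  b <- bf$b; a <- bf$a
  if (!zero_phase) return(iir_filter(b, a, x))
  p <- min(n - 1, max(3 * (max(length(a), length(b)) - 1),
                      ceiling(3 * fs / cutoff_hz)))
  ext <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- iir_filter(b, a, ext)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(p + 1):(p + n)]
}
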