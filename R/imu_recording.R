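# The ImuRecording container: uniformly sampled tri-axial accelerometer and
# gyroscope data from one foot-mounted sensor. Axis convention (sensor frame):
# x medial-lateral, y anterior-posterior, z vertical. Internally everything is
# SI: acceleration m/s^2, angular velocity rad/s.

STANDARD_GRAVITY <- 9.81

#' Construct an IMU recording
#'
#' Validates and packages a uniformly sampled tri-axial accelerometer +
#' gyroscope time series. Input units are converted to SI (m/s^2, rad/s)
#' according to the declared units, never guessed from signal magnitude.
#'
#' @param t Sample times in seconds, strictly increasing on a uniform grid
#'   (jitter below half a sample period is tolerated).
#' @param acc n-by-3 matrix of accelerometer samples (columns x, y, z).
#' @param gyr n-by-3 matrix of gyroscope samples (columns x, y, z).
#' @param fs Sampling rate in Hz. When `NULL`, inferred as `1/median(diff(t))`.
#' @param acc_units `"ms2"` (m/s^2) or `"g"`.
#' @param gyr_units `"rads"` (rad/s) or `"degs"`.
#' @return An object of class `imu_recording` with elements `t`, `acc`, `gyr`,
#'   `fs` (all SI) and `units_in` recording the declared input units.
#' @export
imu_recording <- function(t, acc, gyr, fs = NULL,
                          acc_units = c("ms2", "g"),
                          gyr_units = c("rads", "degs")) {
  acc_units <- match.arg(acc_units)
  gyr_units <- match.arg(gyr_units)
  acc <- as.matrix(acc); gyr <- as.matrix(gyr)
  n <- length(t)
  if (n < 2) stop("empty recording: need at least 2 samples")
  if (nrow(acc) != n || nrow(gyr) != n) {
    stop("t, acc and gyr must have the same number of samples")
  }
  if (ncol(acc) != 3 || ncol(gyr) != 3) stop("acc and gyr must have 3 columns")
  if (!all(is.finite(t)) || !all(is.finite(acc)) || !all(is.finite(gyr))) {
    stop("non-finite samples in recording")
  }
  dt <- diff(t)
  if (any(dt <= 0)) stop("t must be strictly increasing")
  if (is.null(fs)) fs <- 1 / stats::median(dt)
  if (fs <= 0) stop("fs must be positive")
  if (max(abs(dt - 1 / fs)) >= 0.5 / fs) {
    stop("time grid jitter exceeds half a sample period")
  }
  if (acc_units == "g") acc <- acc * STANDARD_GRAVITY
  if (gyr_units == "degs") gyr <- gyr * pi / 180
  colnames(acc) <- colnames(gyr) <- c("x", "y", "z")
  structure(
    list(t = as.numeric(t), acc = acc, gyr = gyr, fs = fs,
         units_in = c(acc = acc_units, gyr = gyr_units)),
    class = "imu_recording"
  )
}

#' Read an IMU recording from CSV
#'
#' Expects the column header `time,ax,ay,az,gx,gy,gz` with time in seconds.
#'
#' @param path Path to the CSV file.
#' @inheritParams imu_recording
#' @return An [imu_recording] object.
#' @export
read_imu_csv <- function(path, fs = NULL, acc_units = "ms2", gyr_units = "rads") {
  df <- utils::read.csv(path)
  need <- c("time", "ax", "ay", "az", "gx", "gy", "gz")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("malformed CSV: missing columns ", paste(miss, collapse = ", "))
  }
  bad <- which(!stats::complete.cases(df[need]))
  if (length(bad)) stop("malformed CSV: non-numeric or missing value at row ", bad[1])
  imu_recording(df$time, as.matrix(df[c("ax", "ay", "az")]),
                as.matrix(df[c("gx", "gy", "gz")]),
                fs = fs, acc_units = acc_units, gyr_units = gyr_units)
}

#' Write an IMU recording to CSV
#'
#' @param rec An [imu_recording].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  df <- data.frame(time = rec$t,
                   ax = rec$acc[, 1], ay = rec$acc[, 2], az = rec$acc[, 3],
                   gx = rec$gyr[, 1], gy = rec$gyr[, 2], gz = rec$gyr[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %d samples @ %g Hz (%.2f s)\n",
              length(x$t), x$fs, x$t[length(x$t)] - x$t[1]))
  cat(sprintf("  |acc| range: %.2f-%.2f m/s^2; |gyr| range: %.3f-%.3f rad/s\n",
              min(sqrt(rowSums(x$acc^2))), max(sqrt(rowSums(x$acc^2))),
              min(sqrt(rowSums(x$gyr^2))), max(sqrt(rowSums(x$gyr^2)))))
  invisible(x)
}
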