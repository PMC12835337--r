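# End-to-end orchestration: recording -> orientation -> events -> ZUPT stride
# reconstruction -> per-stride parameters, packaged as a classed S3 object in
# the style of R model fits, plus alignment and comparison against a
# reference parameter table (simulator ground truth or an external system).

#' Analyze a running trial from a foot-mounted IMU recording
#'
#' The main entry point: estimates orientation, detects gait events with the
#' requested method, reconstructs strides between zero-velocity mid-stance
#' anchors, and derives the per-stride parameter table. The analysis path is
#' fully deterministic: identical input and configuration give identical
#' output.
#'
#' @param recording An [imu_recording], or a path to a CSV readable by
#'   [read_imu_csv()].
#' @param method `"mfdged"` (fused kinematic/kinetic event detection) or
#'   `"avgs"` (conventional angular-velocity baseline).
#' @param config A [gait_config()]; a frozen copy is embedded in the result.
#' @param mass_kg Optional body mass for Newton-scale peak forces.
#' @param verbose Emit per-stage log messages (to stderr).
#' @return An object of class `gait_analysis` with components `parameters`
#'   (per-stride data frame), `events`, `strides` (displacements), the
#'   `orientation` trace, `method`, `config` and `mass_kg`. Methods:
#'   `print`, `summary`, `coef` (per-parameter means), `plot`,
#'   `as.data.frame`.
#' @export
gait_analysis <- function(recording, method = c("mfdged", "avgs"),
                          config = gait_config(), mass_kg = NULL,
                          verbose = FALSE) {
  method <- match.arg(method)
  if (is.character(recording)) recording <- read_imu_csv(recording)
  stopifnot(inherits(recording, "imu_recording"))
  if (verbose) message(sprintf("analyze: %d samples at %g Hz, method=%s",
                               length(recording$t), recording$fs, method))
  ori <- estimate_orientation(recording, kp = config$mahony$kp,
                              ki = config$mahony$ki,
                              stationary_threshold =
                                config$stationary_threshold_rads,
                              verbose = verbose)
  ev <- detect_events(recording, ori, method = method, config = config)
  anchors <- if (identical(config$integration$anchors, "msw")) {
    ev$msw
  } else {
    ev$strides$ms
  }
  if (length(anchors) < 2) {
    stop("no strides found: fewer than two integration anchors")
  }
  sr <- reconstruct_strides(ori$acc_n, recording$t, anchors)
  pars <- stride_parameters(ev, sr, mass_kg = mass_kg)
  if (verbose) {
    message(sprintf("analyze: %d strides, %d flagged", nrow(pars),
                    sum(nzchar(gsub(";", "", pars$flags)))))
  }
  structure(list(parameters = pars, events = ev, strides = sr,
                 orientation = ori, method = method, config = config,
                 mass_kg = mass_kg,
                 n_samples = length(recording$t), fs = recording$fs),
            class = "gait_analysis")
}

#' @export
print.gait_analysis <- function(x, ...) {
  cat(sprintf("<gait_analysis> method=%s: %d strides from %.1f s of data\n",
              x$method, nrow(x$parameters), x$n_samples / x$fs))
  cat(sprintf("  SV %.2f m/s  SL %.2f m  ST %.3f s  CT %.3f s  peak vGRF %.2f BW\n",
              mean(x$parameters$sv), mean(x$parameters$sl),
              mean(x$parameters$st), mean(x$parameters$ct),
              mean(x$parameters$peak_vgrf_bw)))
  invisible(x)
}

#' @export
summary.gait_analysis <- function(object, ...) {
  p <- object$parameters
  vars <- c("sv", "sl", "sf", "st", "ct", "swt", "ft", "peak_vgrf_bw")
  tab <- data.frame(
    parameter = vars,
    mean = vapply(vars, function(v) mean(p[[v]]), numeric(1)),
    sd = vapply(vars, function(v) stats::sd(p[[v]]), numeric(1)),
    row.names = NULL
  )
  structure(list(method = object$method, n_strides = nrow(p), table = tab,
                 n_flagged = sum(nzchar(gsub(";", "", p$flags)))),
            class = "summary.gait_analysis")
}

#' @export
print.summary.gait_analysis <- function(x, ...) {
  cat(sprintf("Gait analysis (%s), %d strides (%d flagged)\n",
              x$method, x$n_strides, x$n_flagged))
  print(transform(x$table, mean = signif(mean, 4), sd = signif(sd, 3)),
        row.names = FALSE)
  invisible(x)
}

#' @export
coef.gait_analysis <- function(object, ...) {
  p <- object$parameters
  vars <- c("sv", "sl", "sf", "st", "ct", "swt", "ft", "peak_vgrf_bw")
  vapply(vars, function(v) mean(p[[v]]), numeric(1))
}

#' @export
as.data.frame.gait_analysis <- function(x, ...) x$parameters

#' @export
plot.gait_analysis <- function(x, which = c("events", "vgrf"), ...) {
  which <- match.arg(which)
  p <- x$parameters
  if (which == "events") {
    ev <- x$events$strides
    graphics::plot(p$stride, p$ct, type = "b", pch = 19, ylim =
                     range(c(p$ct, p$swt, p$st)),
                   xlab = "Stride", ylab = "Duration (s)",
                   main = sprintf("Temporal parameters (%s)", x$method))
    graphics::lines(p$stride, p$swt, type = "b", pch = 1)
    graphics::lines(p$stride, p$st, type = "b", pch = 2)
    graphics::legend("right", c("CT", "SWT", "ST"), pch = c(19, 1, 2),
                     bty = "n")
  } else {
    ct <- mean(p$ct); ft <- max(mean(p$ft), 0)
    m <- if (is.null(x$mass_kg)) 1 / STANDARD_GRAVITY else x$mass_kg
    tg <- seq(0, ct, length.out = 200)
    f <- vgrf_waveform(m, ft, ct, tg)
    ylab <- if (is.null(x$mass_kg)) "vGRF (BW)" else "vGRF (N)"
    graphics::plot(tg, f, type = "l", lwd = 2, xlab = "Stance time (s)",
                   ylab = ylab, main = "Modeled vGRF (SLIP sinusoid)")
  }
  invisible(x)
}

#' Align estimated strides to a reference by nearest initial contact
#'
#' Greedy one-to-one matching of stride rows on the `ic` column, nearest
#' first, rejecting pairs more than `gate_s` apart. Unmatched strides are
#' dropped with a warning.
#'
#' @param est,ref Data frames with an `ic` column (seconds).
#' @param gate_s Matching gate, seconds.
#' @return Data frame with columns `i_est`, `i_ref` of matched row indices.
#' @export
align_strides <- function(est, ref, gate_s = 0.05) {
  d <- abs(outer(est$ic, ref$ic, "-"))
  pairs <- which(d <= gate_s, arr.ind = TRUE)
  if (!nrow(pairs)) stop("no strides matched within the alignment gate")
  ord <- order(d[pairs])
  pairs <- pairs[ord, , drop = FALSE]
  used_e <- logical(nrow(est)); used_r <- logical(nrow(ref))
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    e <- pairs[i, 1]; r <- pairs[i, 2]
    if (!used_e[e] && !used_r[r]) {
      keep[i] <- TRUE; used_e[e] <- TRUE; used_r[r] <- TRUE
    }
  }
  m <- pairs[keep, , drop = FALSE]
  if (any(!used_e) || any(!used_r)) {
    warning(sprintf("%d estimated / %d reference stride(s) unmatched",
                    sum(!used_e), sum(!used_r)))
  }
  m <- m[order(m[, 1]), , drop = FALSE]
  data.frame(i_est = m[, 1], i_ref = m[, 2])
}

#' Compare both detection methods against a reference
#'
#' Analyzes the recording with the fused and the baseline method, aligns each
#' stride table to the reference by nearest initial contact, and reports
#' per-parameter agreement for both methods plus a paired comparison of
#' their absolute-scale error series.
#'
#' @param recording An [imu_recording] (or CSV path).
#' @param reference Reference per-stride table: a `synthetic_truth`, or a
#'   data frame with columns `ic` and any of `sv`, `sl`, `sf`, `st`, `ct`,
#'   `swt`, `ft`, `peak_vgrf_bw`.
#' @param config A [gait_config()].
#' @param mass_kg Optional body mass.
#' @param gate_s Stride alignment gate, seconds.
#' @return An object of class `gait_comparison`: per-parameter list with
#'   `mfdged` and `avgs` agreement reports and `method_test` (paired t and
#'   Cohen's d between the two methods' error series).
#' @export
compare_methods <- function(recording, reference, config = gait_config(),
                            mass_kg = NULL, gate_s = 0.05) {
  if (inherits(reference, "synthetic_truth")) reference <- reference$strides
  fits <- list(mfdged = gait_analysis(recording, "mfdged", config, mass_kg),
               avgs = gait_analysis(recording, "avgs", config, mass_kg))
  vars <- intersect(c("sv", "sl", "sf", "st", "ct", "swt", "ft",
                      "peak_vgrf_bw"), names(reference))
  out <- list()
  for (v in vars) {
    per_method <- list()
    errs <- list()
    for (m in names(fits)) {
      est <- fits[[m]]$parameters
      al <- align_strides(est, reference, gate_s)
      ref_v <- reference[[v]][al$i_ref]
      est_v <- est[[v]][al$i_est]
      per_method[[m]] <- agreement_report(ref_v, est_v)
      errs[[m]] <- data.frame(i_ref = al$i_ref, err = ref_v - est_v)
    }
    common <- intersect(errs$mfdged$i_ref, errs$avgs$i_ref)
    e1 <- errs$mfdged$err[match(common, errs$mfdged$i_ref)]
    e2 <- errs$avgs$err[match(common, errs$avgs$i_ref)]
    mt <- tryCatch(paired_t_and_cohens_d(e1, e2), error = function(e) NULL)
    out[[v]] <- list(mfdged = per_method$mfdged, avgs = per_method$avgs,
                     method_test = mt)
  }
  structure(list(parameters = out, fits = fits), class = "gait_comparison")
}

#' @export
print.gait_comparison <- function(x, ...) {
  cat("<gait_comparison> bias (ref - est) by parameter:\n")
  cat(sprintf("  %-12s %12s %12s %10s\n", "parameter", "MFD-GED", "AVGS",
              "p (paired)"))
  for (v in names(x$parameters)) {
    pv <- x$parameters[[v]]
    cat(sprintf("  %-12s %6.4f+/-%.4f %6.4f+/-%.4f %10.3g\n", v,
                pv$mfdged$bias, pv$mfdged$sd_diff,
                pv$avgs$bias, pv$avgs$sd_diff,
                if (is.null(pv$method_test)) NA else pv$method_test$p))
  }
  invisible(x)
}

#' Export a per-stride parameter table to CSV
#'
#' @param fit A `gait_analysis`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameters_csv <- function(fit, path) {
  utils::write.csv(fit$parameters, path, row.names = FALSE)
  invisible(path)
}

#' Export detected events to JSON
#'
#' @param fit A `gait_analysis`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_json <- function(fit, path) {
  ev <- fit$events
  jsonlite::write_json(
    list(method = ev$method, msw = ev$msw,
         strides = ev$strides[c("stride", "ic", "ms", "tc", "method",
                                "flags")],
         config = unclass(fit$config)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
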