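# Nested configuration for the whole pipeline. Unknown keys are rejected so
# that typos cannot silently fall back to defaults; a frozen copy of the
# effective configuration is embedded in every analysis object.

#' Pipeline configuration
#'
#' Builds the nested configuration controlling every processing stage, with
#' the defaults used throughout the package. Partial overrides are merged
#' recursively; unknown keys raise an error.
#'
#' @param ... Named overrides, e.g. `mahony = list(kp = 1.0)` or
#'   `ic = list(w_acc = 0.8)`.
#' @return A named list of class `gait_config` with entries:
#' \describe{
#'   \item{fs}{Expected sampling rate, Hz (informational; the recording's own
#'     rate governs).}
#'   \item{stationary_threshold_rads}{Gyro-norm threshold for stationarity,
#'     rad/s.}
#'   \item{filter}{`order`, `cutoff_hz`, `zero_phase` for the event filter.}
#'   \item{mahony}{`kp`, `ki` gains of the orientation filter.}
#'   \item{msw}{`k_sigma`, `min_separation_s` for mid-swing detection.}
#'   \item{ic}{`window_frac`, `w_acc`, `search_frac` for initial contact.}
#'   \item{tc}{`search_lo_frac`, `search_hi_frac`, `w_acc` for terminal
#'     contact.}
#'   \item{ms}{`trim_frac`, `window_frac` for mid-stance detection.}
#'   \item{integration}{`anchors`: `"ms"` (zero-velocity mid-stance, default)
#'     or `"msw"` (mid-swing segmentation points).}
#' }
#' @export
gait_config <- function(...) {
  defaults <- list(
    fs = 200,
    stationary_threshold_rads = 0.0436,
    filter = list(order = 4, cutoff_hz = 6, zero_phase = TRUE),
    mahony = list(kp = 2.0, ki = 0.1),
    msw = list(k_sigma = 1.0, min_separation_s = 0.4),
    ic = list(window_frac = 0.3, w_acc = 0.7, search_frac = 0.5),
    tc = list(search_lo_frac = 0.1, search_hi_frac = 0.6, w_acc = 0.7),
    ms = list(trim_frac = 0.1, window_frac = 0.3),
    integration = list(anchors = "ms")
  )
  overrides <- list(...)
  if (length(overrides) == 1 && is.null(names(overrides)) &&
      is.list(overrides[[1]])) {
    overrides <- overrides[[1]]
  }
  cfg <- merge_config(defaults, overrides, path = "")
  class(cfg) <- "gait_config"
  cfg
}

#' @keywords internal
merge_config <- function(base, override, path) {
  if (!length(override)) return(base)
  nm <- names(override)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("config overrides must be named", if (nzchar(path)) paste0(" (at ", path, ")"))
  }
  unknown <- setdiff(nm, names(base))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  }
  for (k in nm) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(override[[k]])) stop("config key '", k, "' must be a list")
      base[[k]] <- merge_config(base[[k]], override[[k]], paste0(path, ".", k))
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Read a pipeline configuration from JSON or YAML
#'
#' @param path File path; format is chosen by extension (`.json`, `.yaml`,
#'   `.yml`).
#' @return A `gait_config` list (defaults merged with the file's overrides).
#' @export
read_gait_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    stop("unsupported config format: ", ext)
  }
  gait_config(raw)
}
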