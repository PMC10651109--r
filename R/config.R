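#' Analysis configuration
#'
#' Builds the validated list of tunable analysis parameters with their
#' defaults. Every parameter can be overridden here or via a YAML
#' configuration file ([readAnalysisConfig()]).
#'
#' @param pre_window_s pre-stimulus window length (s); `NULL` (default) uses
#'   the stimulus duration.
#' @param heatmap_bins bins per axis for occupancy maps.
#' @param bands matrix of [low, high) wavelet frequency band edges in Hz.
#' @param power_bin_s wavelet power time-bin width (s).
#' @param smoothing_window_s moving-average window for explicit smoothing (s).
#' @param step_min_prominence_mm step-peak prominence threshold (mm).
#' @param step_min_separation_s minimum step separation (s).
#' @param step_pause_s gap after which the stepping rate reads 0 (s).
#' @param pid_min_prominence_frac PID extrema prominence as a fraction of the
#'   window's voltage range.
#' @param kde_bandwidth kernel density bandwidth; `NULL` = automatic.
#' @param max_gap_s longest tracking dropout filled by linear interpolation (s).
#' @param combined_speed `"euclidean"` (norm of component rates) or
#'   `"abs_sum"`.
#' @param normalize_axes `"joint"` (both antennae share axis scales) or
#'   `"per_antenna"`.
#' @param distance_mode `"xz"` (perpendicular distance to the stream centre
#'   line in the x-z plane) or `"x_only"` (lateral only).
#' @param head_line `"tunnel"` (head-line fixed to the tunnel +y midline) or
#'   `"body"` (locked to the tether-to-head axis).
#' @param profile_floor_frac row counts above this fraction of the profile
#'   maximum count as plume; defines the profile width.
#' @param pid_rate_mode `"pooled"` (mean reciprocal inter-event interval of
#'   the pooled min+max sequence) or `"count"` (events / duration).
#' @param stepping_norm `"mean"` (per-leg within-trial mean) or `"max"`.
#' @param bootstrap_n bootstrap resamples for window summaries.
#' @param wavelet_omega0 Morlet centre frequency (dimensionless).
#' @param voices_per_octave wavelet scales per octave.
#' @param seed default random seed.
#' @return a named list of class `"antennascanConfig"`.
#' @examples
#' cfg <- analysisConfig()
#' cfg$heatmap_bins
#' @export
analysisConfig <- function(pre_window_s = NULL,
                           heatmap_bins = 24L,
                           bands = cbind(low = c(0.5, 1, 2, 3, 5),
                                         high = c(1, 2, 3, 5, 10)),
                           power_bin_s = 1,
                           smoothing_window_s = 1,
                           step_min_prominence_mm = 0.5,
                           step_min_separation_s = 0.15,
                           step_pause_s = 2,
                           pid_min_prominence_frac = 0.02,
                           kde_bandwidth = NULL,
                           max_gap_s = 0.1,
                           combined_speed = c("euclidean", "abs_sum"),
                           normalize_axes = c("joint", "per_antenna"),
                           distance_mode = c("xz", "x_only"),
                           head_line = c("tunnel", "body"),
                           profile_floor_frac = 0.05,
                           pid_rate_mode = c("pooled", "count"),
                           stepping_norm = c("mean", "max"),
                           bootstrap_n = 2000L,
                           wavelet_omega0 = 6,
                           voices_per_octave = 12L,
                           seed = 1L) {
  cfg <- list(
    pre_window_s = pre_window_s,
    heatmap_bins = as.integer(heatmap_bins),
    bands = bands,
    power_bin_s = power_bin_s,
    smoothing_window_s = smoothing_window_s,
    step_min_prominence_mm = step_min_prominence_mm,
    step_min_separation_s = step_min_separation_s,
    step_pause_s = step_pause_s,
    pid_min_prominence_frac = pid_min_prominence_frac,
    kde_bandwidth = kde_bandwidth,
    max_gap_s = max_gap_s,
    combined_speed = match.arg(combined_speed),
    normalize_axes = match.arg(normalize_axes),
    distance_mode = match.arg(distance_mode),
    head_line = match.arg(head_line),
    profile_floor_frac = profile_floor_frac,
    pid_rate_mode = match.arg(pid_rate_mode),
    stepping_norm = match.arg(stepping_norm),
    bootstrap_n = as.integer(bootstrap_n),
    wavelet_omega0 = wavelet_omega0,
    voices_per_octave = as.integer(voices_per_octave),
    seed = as.integer(seed))
  validateConfig(cfg)
  class(cfg) <- "antennascanConfig"
  cfg
}

validateConfig <- function(cfg) {
  b <- cfg$bands
  if (!is.matrix(b) || ncol(b) != 2 || any(b[, 2] <= b[, 1]))
    stop("bands must be a matrix of [low, high) pairs with high > low")
  if (nrow(b) > 1) {
    if (any(diff(b[, 1]) <= 0))
      stop("bands must be ascending")
    if (any(b[-nrow(b), 2] > b[-1, 1] + 1e-12))
      stop("bands must not overlap")
  }
  for (w in c("power_bin_s", "smoothing_window_s", "step_min_separation_s",
              "step_pause_s", "max_gap_s"))
    if (!(is.numeric(cfg[[w]]) && cfg[[w]] > 0))
      stop(w, " must be positive")
  if (!is.null(cfg$pre_window_s) && cfg$pre_window_s <= 0)
    stop("pre_window_s must be positive")
  if (cfg$heatmap_bins < 2) stop("heatmap_bins must be >= 2")
  invisible(TRUE)
}

#' Read an analysis configuration file
#'
#' Reads a declarative `key: value` (YAML) configuration file and overlays
#' it on the defaults of [analysisConfig()]. Unknown keys are an error, so
#' typos never pass silently. `bands` may be given as a list of two-element
#' `[low, high)` pairs.
#'
#' @param path configuration file path.
#' @return a validated config list, as from [analysisConfig()].
#' @export
readAnalysisConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(analysisConfig))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (!is.null(raw$bands)) {
    m <- do.call(rbind, lapply(raw$bands, as.numeric))
    colnames(m) <- c("low", "high")
    raw$bands <- m
  }
  do.call(analysisConfig, raw)
}
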