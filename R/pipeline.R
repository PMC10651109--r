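## End-to-end driver: read every trial in a directory, run the kinematic,
## spatial, stepping and spectral analyses, and write long-format reports.

#' Run the full analysis pipeline over a directory of trials
#'
#' Discovers `<id>_tracking.csv` / `<id>_protocol.yml` pairs, and for every
#' trial computes antennal angles and speeds, normalized coordinates,
#' per-antenna distance to the stream, baseline-change window summaries
#' (distance, per-antenna and overall range, stepping rate), the
#' responsive-antenna label, stream-following correlations over the
#' stimulus window, and the wavelet band-power matrix for both angle
#' components. Odour trials with a matching `<id>_sham` trial of the same
#' animal are additionally sham-corrected. Reports are written as
#' long-format CSVs into `out_dir`.
#'
#' @param trials_dir directory of tracking/protocol file pairs.
#' @param out_dir output directory (created).
#' @param config an [analysisConfig()] list.
#' @return invisibly, a list with the per-trial summary data.frame
#'   (`summary`), the band-power long table (`band_power`) and the paths
#'   written.
#' @export
runPipeline <- function(trials_dir, out_dir, config = analysisConfig()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  protos <- list.files(trials_dir, pattern = "_protocol\\.yml$",
                       full.names = TRUE)
  ids <- sub("_protocol\\.yml$", "", basename(protos))
  if (!length(ids)) stop("no trials found in ", trials_dir)
  trials <- lapply(seq_along(ids), function(i)
    readTrial(file.path(trials_dir, paste0(ids[i], "_tracking.csv")),
              protos[i], max_gap_s = config$max_gap_s))
  names(trials) <- ids

  perTrial <- list()
  bandRows <- list()
  changes <- list()
  for (id in ids) {
    tr <- trials[[id]]
    res <- analyseTrial(tr, config)
    perTrial[[id]] <- res$summary
    changes[[id]] <- res$dist_change
    bandRows[[id]] <- res$band_long
  }

  ## sham correction where an odour trial has a matched sham of the animal
  for (id in ids) {
    sid <- paste0(id, "_sham")
    if (protocol(trials[[id]])@isSham || !sid %in% ids) next
    for (a in ANTENNAE) {
      corr <- shamCorrect(changes[[id]][[a]], changes[[sid]][[a]])
      perTrial[[id]][[paste0("dist_change_sham_corrected_", a)]] <-
        unname(windowMeans(corr)["odour"])
    }
  }

  allCols <- unique(unlist(lapply(perTrial, names)))
  summary <- do.call(rbind, lapply(names(perTrial), function(id) {
    row <- perTrial[[id]]
    row[setdiff(allCols, names(row))] <- NA
    cbind(data.frame(trial_id = id), as.data.frame(row[allCols]))
  }))
  bandPower <- do.call(rbind, bandRows)

  summaryLong <- stats::reshape(
    summary, direction = "long",
    varying = setdiff(names(summary), "trial_id"),
    v.names = "value", timevar = "metric",
    times = setdiff(names(summary), "trial_id"))
  summaryLong <- data.frame(trial_id = summaryLong$trial_id,
                            metric = summaryLong$metric,
                            window = "odour", value = summaryLong$value)
  writeResults(summaryLong, file.path(out_dir, "window_summaries.csv"))
  utils::write.csv(bandPower, file.path(out_dir, "band_power.csv"),
                   row.names = FALSE)
  utils::write.csv(summary, file.path(out_dir, "trial_summaries.csv"),
                   row.names = FALSE)
  invisible(list(summary = summary, band_power = bandPower,
                 paths = file.path(out_dir, c("window_summaries.csv",
                                              "band_power.csv",
                                              "trial_summaries.csv"))))
}

## Single-trial analysis used by runPipeline; returns the odour-window
## summary metrics, the per-antenna distance ChangeSeries (for sham
## pairing) and the band-power long table.
analyseTrial <- function(tr, config = analysisConfig()) {
  fr <- frameRate(tr)
  pr <- protocol(tr)
  ang <- antennalAngles(tr, head_line = config$head_line)
  nc <- normalizeCoords(tr, axes = config$normalize_axes)
  dist <- distanceToStream(nc, tr, mode = config$distance_mode)
  n <- nFrames(tr)
  dur <- pr@offset - pr@onset
  preIdx <- windowFrames(pr@onset - dur, pr@onset, fr, n)
  odIdx <- windowFrames(pr@onset, pr@offset, fr, n)

  distChange <- list(
    L = baselineChange(dist[, "L"], pr, fr, label = "dist_L",
                       pre_window_s = config$pre_window_s),
    R = baselineChange(dist[, "R"], pr, fr, label = "dist_R",
                       pre_window_s = config$pre_window_s))
  lab <- labelResponsive(dist, pr, fr)

  rangeChange <- function(x) {
    antennalRange(x, odIdx) - antennalRange(x, preIdx)
  }
  out <- list(
    responsive = lab$responsive,
    control_label = lab$control,
    dist_change_L = unname(windowMeans(distChange$L)["odour"]),
    dist_change_R = unname(windowMeans(distChange$R)["odour"]),
    range_change_L = rangeChange(nc@L[, 1]),
    range_change_R = rangeChange(nc@R[, 1]),
    overall_range_change = overallRange(nc@L[, 1], nc@R[, 1], odIdx) -
      overallRange(nc@L[, 1], nc@R[, 1], preIdx))

  ## stream-following correlation over the stimulus window
  tOd <- (odIdx - 1) / fr
  sx <- streamX(pr, tOd)
  for (a in ANTENNAE) {
    tipx <- slot(nc, a)[odIdx, 1]
    out[[paste0("stream_corr_", a)]] <- if (stats::sd(sx) == 0) NA_real_
      else tryCatch(streamFollowingCorrelation(tipx, sx),
                    warning = function(w) NA_real_)
  }

  ## stepping
  legsHere <- intersect(STEPPING_LEGS, pointLabels(tr))
  if (length(legsHere) == 4L) {
    steps <- lapply(legsHere, function(leg)
      detectSteps(trackedPoint(tr, leg)$xyz[, 2], fr,
                  min_prominence_mm = config$step_min_prominence_mm,
                  min_separation_s = config$step_min_separation_s))
    names(steps) <- legsHere
    ss <- steppingRate(steps, n, fr, pause_s = config$step_pause_s,
                       norm = config$stepping_norm)
    out$step_rate_ratio <- windowMean(ss@meanRate, odIdx) /
      windowMean(ss@meanRate, preIdx)
  } else {
    out$step_rate_ratio <- NA_real_
  }

  ## wavelet band power of both components, responsive antenna
  ra <- lab$responsive
  bandLong <- do.call(rbind, lapply(c("azimuth", "elevation"), function(cmp) {
    series <- slot(ang, cmp)[, ra]
    bpm <- waveletBandPower(series, fr, pr, config,
                            pre_window_s = config$pre_window_s)
    sel <- bpm@binStart >= pr@onset - 1e-9 &
      bpm@binStart + bpm@binWidth <= pr@offset + 1e-9
    data.frame(trial_id = trialId(tr), antenna = ra, component = cmp,
               time_bin = rep(bpm@binStart, ncol(bpm@scaled)),
               band = rep(bandLabels(bpm), each = nrow(bpm@scaled)),
               scaled_power = as.vector(bpm@scaled))
  }))

  list(summary = out, dist_change = distChange, band_long = bandLong)
}
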