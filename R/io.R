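## File formats.
## Tracking tables: plain CSV, one row per frame per point, columns
##   frame, time_s, label, x_mm, y_mm, z_mm, valid.
## Protocol files: key-value YAML (ids, odour, frame rate, stimulus timing,
##   stream geometry, sham flag).
## PID traces: CSV (time_s, volts). Arena tracks: CSV (time_s, x_mm, y_mm).
## Smoke sequences: a directory of grayscale PNG frames + mask.png + meta.yml.

#' Read a trial from a tracking table and protocol file
#'
#' @param path CSV tracking table (`frame, time_s, label, x_mm, y_mm, z_mm,
#'   valid`), one row per frame per tracked point.
#' @param protocol_path YAML protocol descriptor with trial/animal ids,
#'   odour, frame rate, stimulus timing, stream geometry and sham flag.
#' @param interpolate fill tracking dropouts up to `max_gap_s` by linear
#'   interpolation (default `TRUE`); longer runs stay invalid.
#' @param max_gap_s longest gap (s) filled by interpolation.
#' @return a [Trial-class].
#' @export
readTrial <- function(path, protocol_path, interpolate = TRUE,
                      max_gap_s = 0.1) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "time_s", "label", "x_mm", "y_mm", "z_mm", "valid")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("tracking table lacks column(s): ", paste(miss, collapse = ", "))
  meta <- yaml::read_yaml(protocol_path)
  fr <- meta$frame_rate
  labels <- unique(tab$label)
  for (lab in REQUIRED_POINTS)
    if (!lab %in% labels) stop("required point ", lab, " absent")
  points <- lapply(labels, function(lab) {
    sub <- tab[tab$label == lab, , drop = FALSE]
    if (any(diff(sub$frame) <= 0))
      stop("non-monotonic frame index for point ", lab)
    xyz <- as.matrix(sub[, c("x_mm", "y_mm", "z_mm")])
    colnames(xyz) <- c("x", "y", "z")
    valid <- as.logical(sub$valid) & apply(is.finite(xyz), 1, all)
    xyz[!valid, ] <- NA_real_
    if (interpolate) {
      fixed <- interpolateGaps(xyz, valid,
                               max_gap = max(1L, floor(max_gap_s * fr)))
      xyz <- fixed$mat; valid <- fixed$valid
    }
    list(xyz = xyz, valid = valid)
  })
  names(points) <- labels
  trial(trial_id = meta$trial_id, animal_id = meta$animal_id,
        odour = meta$odour, frame_rate = fr, points = points,
        protocol = protocolFromMeta(meta))
}

protocolFromMeta <- function(meta) {
  sx <- if (!is.null(meta$stream_path)) {
    data.frame(time_s = vapply(meta$stream_path, `[[`, numeric(1), "time_s"),
               x_mm = vapply(meta$stream_path, `[[`, numeric(1), "x_mm"))
  } else meta$stream_x_mm %||% 0
  sp <- if (!is.null(meta$static_positions)) {
    data.frame(
      label = vapply(meta$static_positions, `[[`, character(1), "label"),
      start_s = vapply(meta$static_positions, `[[`, numeric(1), "start_s"),
      end_s = vapply(meta$static_positions, `[[`, numeric(1), "end_s"))
  } else NULL
  stimulusProtocol(onset = meta$onset_s, offset = meta$offset_s,
                   stream_x = sx, stream_z = meta$stream_z_mm %||% 0,
                   is_sham = isTRUE(meta$is_sham), static_positions = sp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trial to a tracking table and protocol file
#'
#' Inverse of [readTrial()]: values survive the round trip to full printed
#' precision (15 significant digits), and validity flags exactly.
#'
#' @param x a [Trial-class].
#' @param path output CSV path.
#' @param protocol_path output YAML path.
#' @return invisibly, `path`.
#' @export
writeTrial <- function(x, path, protocol_path) {
  fr <- frameRate(x)
  n <- nFrames(x)
  rows <- lapply(pointLabels(x), function(lab) {
    p <- trackedPoint(x, lab)
    data.frame(frame = seq_len(n), time_s = (seq_len(n) - 1) / fr,
               label = lab, x_mm = p$xyz[, 1], y_mm = p$xyz[, 2],
               z_mm = p$xyz[, 3], valid = as.integer(p$valid))
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  pr <- protocol(x)
  meta <- list(trial_id = trialId(x), animal_id = x@animalId,
               odour = x@odour, frame_rate = fr,
               onset_s = pr@onset, offset_s = pr@offset,
               stream_z_mm = pr@streamZ, is_sham = pr@isSham)
  if (nrow(pr@streamPath) == 1L) {
    meta$stream_x_mm <- pr@streamPath$x_mm
  } else {
    meta$stream_path <- lapply(seq_len(nrow(pr@streamPath)), function(i)
      list(time_s = pr@streamPath$time_s[i], x_mm = pr@streamPath$x_mm[i]))
  }
  if (nrow(pr@staticPositions))
    meta$static_positions <- lapply(seq_len(nrow(pr@staticPositions)),
      function(i) list(label = pr@staticPositions$label[i],
                       start_s = pr@staticPositions$start_s[i],
                       end_s = pr@staticPositions$end_s[i]))
  yaml::write_yaml(meta, protocol_path, precision = 15)
  invisible(path)
}

#' Write a long-format results table
#'
#' All pipeline outputs share one long CSV layout: `trial_id, metric,
#' time_s` (or a window label in `window`), `value`. The table is
#' re-readable with [readResults()].
#'
#' @param results data.frame with at least `trial_id`, `metric`, `value` and
#'   one of `time_s` / `window`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writeResults <- function(results, path) {
  if (is.null(results) || !nrow(results)) stop("empty result set")
  need <- c("trial_id", "metric", "value")
  miss <- setdiff(need, names(results))
  if (length(miss))
    stop("results lack column(s): ", paste(miss, collapse = ", "))
  if (!any(c("time_s", "window") %in% names(results)))
    stop("results need a time_s or window column")
  utils::write.csv(results, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeResults
#' @export
readResults <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' Convert a ChangeSeries to a long results table
#' @param x a [ChangeSeries-class].
#' @param trial_id trial identifier for the table.
#' @return data.frame in the [writeResults()] layout, one row per frame.
#' @export
changeSeriesTable <- function(x, trial_id) {
  data.frame(trial_id = trial_id, metric = x@metric,
             time_s = x@time_s, value = x@change)
}

#' Read / write a PID voltage trace
#'
#' @param path CSV with columns `time_s`, `volts`.
#' @return [readPIDTrace()]: a [PIDTrace-class] with no extrema detected yet.
#' @export
readPIDTrace <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("time_s", "volts") %in% names(tab)))
    stop("PID trace needs columns time_s, volts")
  new("PIDTrace", time_s = tab$time_s, volts = tab$volts,
      minima = integer(0), maxima = integer(0))
}

#' @rdname readPIDTrace
#' @param x a [PIDTrace-class].
#' @export
writePIDTrace <- function(x, path) {
  utils::write.csv(data.frame(time_s = x@time_s, volts = x@volts),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a smoke-visualisation sequence directory
#'
#' A sequence directory holds `frame_0001.png`, `frame_0002.png`, ... (8-bit
#' grayscale), `mask.png` (white = body) and `meta.yml` with `threshold`,
#' `roi` (row1, row2, col1, col2) and `left_right_axis`.
#'
#' @param dir sequence directory.
#' @return a [SmokeSequence-class].
#' @export
readSmokeSequence <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yml"))
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (!length(files)) stop("no frame_*.png files in ", dir)
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  })
  mask <- png::readPNG(file.path(dir, "mask.png"))
  if (length(dim(mask)) == 3L) mask <- mask[, , 1]
  smokeSequence(frames, threshold = meta$threshold,
                roi = unlist(meta$roi), mask = mask >= 0.5,
                left_right_axis = meta$left_right_axis %||% "row")
}

#' @rdname readSmokeSequence
#' @param x a [SmokeSequence-class].
#' @export
writeSmokeSequence <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(x@frames))
    png::writePNG(x@frames[[i]],
                  file.path(dir, sprintf("frame_%04d.png", i)))
  png::writePNG(x@mask * 1, file.path(dir, "mask.png"))
  yaml::write_yaml(list(threshold = x@threshold, roi = as.list(x@roi),
                        left_right_axis = x@leftRightAxis),
                   file.path(dir, "meta.yml"))
  invisible(dir)
}

#' Read / write an arena track
#'
#' @param path CSV with columns `time_s`, `x_mm`, `y_mm`.
#' @param zones_path YAML with `odour` and `control` zones, each
#'   `{x_mm, y_mm, r_mm}`, and `duration_s`.
#' @return an [ArenaTrack-class].
#' @export
readArenaTrack <- function(path, zones_path) {
  tab <- utils::read.csv(path)
  z <- yaml::read_yaml(zones_path)
  zone <- function(v) c(v$x_mm, v$y_mm, v$r_mm)
  new("ArenaTrack", time_s = tab$time_s, x = tab$x_mm, y = tab$y_mm,
      zones = list(odour = zone(z$odour), control = zone(z$control)),
      duration = z$duration_s %||% max(tab$time_s))
}

#' @rdname readArenaTrack
#' @param x an [ArenaTrack-class].
#' @export
writeArenaTrack <- function(x, path, zones_path) {
  utils::write.csv(data.frame(time_s = x@time_s, x_mm = x@x, y_mm = x@y),
                   path, row.names = FALSE, quote = FALSE)
  zl <- function(v) list(x_mm = v[1], y_mm = v[2], r_mm = v[3])
  yaml::write_yaml(list(odour = zl(x@zones$odour),
                        control = zl(x@zones$control),
                        duration_s = x@duration), zones_path)
  invisible(path)
}
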