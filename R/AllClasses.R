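## Central S4 containers of the pipeline. All per-frame data are held as
## matrices with one row per frame; antennae are always ordered (L, R).

ODOURS <- c("colony", "butanol", "linalool", "air_sham")
ANTENNAE <- c("L", "R")
LEG_LABELS <- c("L1", "L2", "L3", "R1", "R2", "R3")
REQUIRED_POINTS <- c("head", "ant_L", "ant_R")

#' StimulusProtocol: timing and geometry of one trial's stimulus
#'
#' Describes the odour (or sham air) stimulus of a trial: onset/offset in
#' seconds, the lateral position of the stream centre over time (constant for
#' static positions, piecewise for a moving stream), the stream height, and
#' optional named static periods (e.g. P1/P2/P3 of a shifting stream).
#'
#' @slot onset stimulus onset, seconds from trial start.
#' @slot offset stimulus offset, seconds.
#' @slot streamPath data.frame with `time_s` and `x_mm`; lateral stream-centre
#'   position, linearly interpolated between rows and held constant outside.
#' @slot streamZ stream axis height (mm, tunnel frame; head level by default).
#' @slot isSham `TRUE` for air-only control trials.
#' @slot staticPositions data.frame (`label`, `start_s`, `end_s`) naming
#'   static periods of a moving stream; may be empty.
#' @export
setClass("StimulusProtocol", representation(
  onset = "numeric", offset = "numeric",
  streamPath = "data.frame", streamZ = "numeric",
  isSham = "logical", staticPositions = "data.frame"))

setValidity("StimulusProtocol", function(object) {
  msg <- character(0)
  if (length(object@onset) != 1 || length(object@offset) != 1)
    msg <- c(msg, "onset and offset must be scalars")
  else if (!(object@onset >= 0 && object@onset < object@offset))
    msg <- c(msg, "need 0 <= onset < offset")
  if (!all(c("time_s", "x_mm") %in% names(object@streamPath)))
    msg <- c(msg, "streamPath needs columns time_s, x_mm")
  else if (nrow(object@streamPath) < 1)
    msg <- c(msg, "streamPath must have at least one row")
  if (length(msg)) msg else TRUE
})

#' Construct a StimulusProtocol
#'
#' @param onset,offset stimulus window in seconds.
#' @param stream_x either a single lateral position (mm) for a static stream,
#'   or a data.frame (`time_s`, `x_mm`) for a moving stream.
#' @param stream_z stream axis height in mm (default 0 = head level in the
#'   head-centred convention used downstream).
#' @param is_sham logical sham flag.
#' @param static_positions optional data.frame (`label`, `start_s`, `end_s`).
#' @return a [StimulusProtocol-class].
#' @examples
#' stimulusProtocol(5, 7, stream_x = 0)
#' @export
stimulusProtocol <- function(onset, offset, stream_x = 0, stream_z = 0,
                             is_sham = FALSE, static_positions = NULL) {
  if (is.numeric(stream_x) && length(stream_x) == 1L)
    stream_x <- data.frame(time_s = 0, x_mm = stream_x)
  if (is.null(static_positions))
    static_positions <- data.frame(label = character(0),
                                   start_s = numeric(0), end_s = numeric(0))
  new("StimulusProtocol", onset = onset, offset = offset,
      streamPath = stream_x, streamZ = stream_z, isSham = is_sham,
      staticPositions = static_positions)
}

#' @rdname streamX
#' @export
setMethod("streamX", "StimulusProtocol", function(x, t) {
  sp <- x@streamPath
  if (nrow(sp) == 1L) return(rep(sp$x_mm, length(t)))
  stats::approx(sp$time_s, sp$x_mm, xout = t, rule = 2)$y
})

setMethod("show", "StimulusProtocol", function(object) {
  cat("StimulusProtocol: ",
      if (object@isSham) "sham air" else "odour",
      sprintf(" stimulus %.2f-%.2f s", object@onset, object@offset), "\n",
      sep = "")
  if (nrow(object@streamPath) == 1L)
    cat("  static stream at x =", object@streamPath$x_mm, "mm\n")
  else
    cat("  moving stream,", nrow(object@streamPath), "path points\n")
})

#' Trial: one recording session's tracked points plus stimulus protocol
#'
#' The unit of all analyses. Holds, for each tracked point (head, antennal
#' tips, tarsi), an n x 3 coordinate matrix in the tunnel frame (x: mm,
#' left(-)/right(+); y: mm, back(-)/front(+); z: mm, up(+)) and a per-frame
#' validity flag marking tracking dropouts. Invalid frames are explicit,
#' never silently zero.
#'
#' @slot trialId,animalId character identifiers.
#' @slot odour one of `"colony"`, `"butanol"`, `"linalool"`, `"air_sham"`.
#' @slot frameRate frames per second (100 in the reference recordings).
#' @slot points named list; each element a list with `xyz` (n x 3 matrix) and
#'   `valid` (logical length n).
#' @slot protocol a [StimulusProtocol-class].
#' @export
setClass("Trial", representation(
  trialId = "character", animalId = "character", odour = "character",
  frameRate = "numeric", points = "list", protocol = "StimulusProtocol"))

setValidity("Trial", function(object) {
  msg <- character(0)
  if (!(length(object@frameRate) == 1 && object@frameRate > 0))
    msg <- c(msg, "frameRate must be a positive scalar")
  if (!object@odour %in% ODOURS)
    msg <- c(msg, paste0("odour must be one of ",
                         paste(ODOURS, collapse = ", ")))
  missing <- setdiff(REQUIRED_POINTS, names(object@points))
  if (length(missing))
    msg <- c(msg, paste0("required point ", missing[1], " absent"))
  ns <- vapply(object@points, function(p) nrow(p$xyz), integer(1))
  if (length(unique(ns)) > 1)
    msg <- c(msg, "all point series must share one frame count")
  extra <- setdiff(names(object@points), c(REQUIRED_POINTS, LEG_LABELS))
  if (length(extra))
    msg <- c(msg, paste0("unknown point label: ", extra[1]))
  for (p in object@points) {
    if (length(p$valid) != nrow(p$xyz))
      msg <- c(msg, "validity flag length must equal frame count")
    if (any(!is.finite(p$xyz[p$valid, , drop = FALSE])))
      msg <- c(msg, "valid frames must hold finite coordinates")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Trial
#'
#' @param trial_id,animal_id identifiers.
#' @param odour odour label.
#' @param frame_rate frames per second.
#' @param points named list of point series; each element either an n x 3
#'   matrix (all frames valid) or a list with `xyz` and `valid`.
#' @param protocol a [StimulusProtocol-class].
#' @return a [Trial-class].
#' @export
trial <- function(trial_id, animal_id, odour, frame_rate, points, protocol) {
  points <- lapply(points, function(p) {
    if (is.matrix(p)) p <- list(xyz = p, valid = rep(TRUE, nrow(p)))
    colnames(p$xyz) <- c("x", "y", "z")
    p$valid <- as.logical(p$valid)
    p$xyz[!p$valid, ] <- NA_real_
    p
  })
  new("Trial", trialId = trial_id, animalId = animal_id, odour = odour,
      frameRate = frame_rate, points = points, protocol = protocol)
}

#' @rdname nFrames
#' @export
setMethod("nFrames", "Trial", function(x) nrow(x@points[[1]]$xyz))
#' @rdname frameRate
#' @export
setMethod("frameRate", "Trial", function(x) x@frameRate)
#' @rdname trialId
#' @export
setMethod("trialId", "Trial", function(x) x@trialId)
#' @rdname protocol
#' @export
setMethod("protocol", "Trial", function(x) x@protocol)
#' @rdname pointLabels
#' @export
setMethod("pointLabels", "Trial", function(x) names(x@points))
#' @rdname trackedPoint
#' @export
setMethod("trackedPoint", "Trial", function(x, label) {
  if (!label %in% names(x@points))
    stop("required point ", label, " absent")
  x@points[[label]]
})

setMethod("show", "Trial", function(object) {
  cat("Trial ", object@trialId, " (animal ", object@animalId, ", ",
      object@odour, ")\n", sep = "")
  cat("  ", nFrames(object), " frames at ", object@frameRate, " fps (",
      sprintf("%.1f", nFrames(object) / object@frameRate), " s)\n", sep = "")
  cat("  points:", paste(names(object@points), collapse = ", "), "\n")
  show(object@protocol)
})

#' AngleSeries: antennal azimuth and elevation per frame
#'
#' Azimuth is the signed angle, in the horizontal plane, between the
#' head-to-tip line and the forward head-line (0 deg = parallel to the
#' head-line; negative left, positive right). Elevation is the signed angle
#' of the head-to-tip line above (+) or below (-) the horizontal plane at
#' head height.
#'
#' @slot azimuth,elevation n x 2 matrices (columns `L`, `R`), degrees.
#' @slot valid n x 2 logical matrix.
#' @slot frameRate frames per second.
#' @export
setClass("AngleSeries", representation(
  azimuth = "matrix", elevation = "matrix", valid = "matrix",
  frameRate = "numeric"))

setValidity("AngleSeries", function(object) {
  az <- object@azimuth[object@valid]
  el <- object@elevation[object@valid]
  msg <- character(0)
  if (length(az) && (any(az <= -180 - 1e-9) || any(az > 180 + 1e-9)))
    msg <- c(msg, "azimuth must lie in (-180, 180]")
  if (length(el) && (any(el < -90 - 1e-9) || any(el > 90 + 1e-9)))
    msg <- c(msg, "elevation must lie in [-90, 90]")
  if (length(msg)) msg else TRUE
})

#' @rdname azimuth
#' @export
setMethod("azimuth", "AngleSeries", function(x) x@azimuth)
#' @rdname elevation
#' @export
setMethod("elevation", "AngleSeries", function(x) x@elevation)
#' @rdname nFrames
#' @export
setMethod("nFrames", "AngleSeries", function(x) nrow(x@azimuth))
#' @rdname frameRate
#' @export
setMethod("frameRate", "AngleSeries", function(x) x@frameRate)

setMethod("show", "AngleSeries", function(object) {
  cat("AngleSeries:", nrow(object@azimuth), "frames,",
      sprintf("%.0f%% valid\n", 100 * mean(object@valid)))
  cat(sprintf("  azimuth   L median %6.1f deg, R median %6.1f deg\n",
              stats::median(object@azimuth[object@valid[, 1], 1], na.rm = TRUE),
              stats::median(object@azimuth[object@valid[, 2], 2], na.rm = TRUE)))
  cat(sprintf("  elevation L median %6.1f deg, R median %6.1f deg\n",
              stats::median(object@elevation[object@valid[, 1], 1], na.rm = TRUE),
              stats::median(object@elevation[object@valid[, 2], 2], na.rm = TRUE)))
})

#' HeadingSeries: signed heading of the head about the tether point
#'
#' Heading is the signed angle of the tether-to-head line against the tunnel
#' midline (+y); negative left, positive right. The absolute heading
#' (`abs(heading)`) quantifies deviation from straight-ahead.
#'
#' @slot heading numeric per frame, degrees.
#' @slot valid logical per frame.
#' @slot frameRate frames per second.
#' @export
setClass("HeadingSeries", representation(
  heading = "numeric", valid = "logical", frameRate = "numeric"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "HeadingSeries", function(x) length(x@heading))
#' @rdname frameRate
#' @export
setMethod("frameRate", "HeadingSeries", function(x) x@frameRate)

#' NormalizedCoords: head-centred, within-trial-scaled tip coordinates
#'
#' Antennal tip coordinates centred on the head at each frame and scaled per
#' axis by the within-trial maximum absolute value, so each axis lies in
#' [-1, 1] — effectively normalising by the antennal length of the animal.
#'
#' @slot L,R n x 3 matrices of normalized (x, y, z) per antenna.
#' @slot valid n x 2 logical matrix.
#' @slot axisScale length-3 numeric, the mm value mapped to 1 on each axis.
#' @slot scaleFactor max head-to-tip distance (mm), approx. antennal length.
#' @slot frameRate frames per second.
#' @export
setClass("NormalizedCoords", representation(
  L = "matrix", R = "matrix", valid = "matrix", axisScale = "numeric",
  scaleFactor = "numeric", frameRate = "numeric"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "NormalizedCoords", function(x) nrow(x@L))
#' @rdname frameRate
#' @export
setMethod("frameRate", "NormalizedCoords", function(x) x@frameRate)

setMethod("show", "NormalizedCoords", function(object) {
  cat("NormalizedCoords:", nrow(object@L), "frames; scale factor",
      sprintf("%.1f mm", object@scaleFactor), "\n")
  cat("  axis scales (mm -> 1):",
      paste(sprintf("%.1f", object@axisScale), collapse = ", "), "\n")
})

#' SpeedSeries: per-antenna angular speeds
#'
#' Frame-to-frame finite differences of azimuth and elevation multiplied by
#' the frame rate, plus the combined angular speed (Euclidean norm of the two
#' component rates, or sum of absolute values if so configured). The first
#' frame has no preceding frame and is NA.
#'
#' @slot azimuthSpeed,elevationSpeed,combined n x 2 matrices, deg/s.
#' @slot frameRate frames per second.
#' @export
setClass("SpeedSeries", representation(
  azimuthSpeed = "matrix", elevationSpeed = "matrix", combined = "matrix",
  frameRate = "numeric"))

#' @rdname combinedSpeed
#' @export
setMethod("combinedSpeed", "SpeedSeries", function(x) x@combined)
#' @rdname nFrames
#' @export
setMethod("nFrames", "SpeedSeries", function(x) nrow(x@combined))
#' @rdname frameRate
#' @export
setMethod("frameRate", "SpeedSeries", function(x) x@frameRate)

#' ChangeSeries: a metric as difference from its pre-stimulus mean
#'
#' Event-triggered baseline correction: the metric at each frame minus the
#' mean of the pre-stimulus window (a window of the stimulus length directly
#' before odour onset), so the pre-stimulus average is zero by construction.
#' Optionally further corrected by the same animal's sham control trial.
#'
#' @slot metric metric label.
#' @slot time_s per-frame time, seconds.
#' @slot change per-frame change values.
#' @slot windowMeans named numeric (`pre`, `odour`, `post`).
#' @slot shamCorrected logical.
#' @slot onset,offset stimulus window, seconds.
#' @slot frameRate frames per second.
#' @export
setClass("ChangeSeries", representation(
  metric = "character", time_s = "numeric", change = "numeric",
  windowMeans = "numeric", shamCorrected = "logical",
  onset = "numeric", offset = "numeric", frameRate = "numeric"))

#' @rdname changeValues
#' @export
setMethod("changeValues", "ChangeSeries", function(x) x@change)
#' @rdname windowMeans
#' @export
setMethod("windowMeans", "ChangeSeries", function(x) x@windowMeans)
#' @rdname nFrames
#' @export
setMethod("nFrames", "ChangeSeries", function(x) length(x@change))
#' @rdname frameRate
#' @export
setMethod("frameRate", "ChangeSeries", function(x) x@frameRate)

setMethod("show", "ChangeSeries", function(object) {
  cat("ChangeSeries '", object@metric, "'",
      if (object@shamCorrected) " (sham-corrected)", ": ",
      length(object@change), " frames\n", sep = "")
  wm <- object@windowMeans
  cat(sprintf("  window means: pre %.4g, odour %.4g, post %.4g\n",
              wm["pre"], wm["odour"], wm["post"]))
})

#' OccupancyMap: 2-D histogram of normalized tip positions
#'
#' Binned occupancy of antennal tip positions in a coordinate plane of the
#' normalized system, expressed as the proportion of observations per bin
#' (values sum to 1). Bin edges span [-1, 1] on each axis.
#'
#' @slot values bins x bins matrix of proportions.
#' @slot xBreaks,yBreaks bin edges.
#' @slot plane `"xy"` or `"xz"`.
#' @export
setClass("OccupancyMap", representation(
  values = "matrix", xBreaks = "numeric", yBreaks = "numeric",
  plane = "character"))

setValidity("OccupancyMap", function(object) {
  s <- sum(object@values)
  if (abs(s - 1) > 1e-9) "bin proportions must sum to 1" else TRUE
})

#' StepSeries: detected steps and normalized stepping rate
#'
#' Per-leg step times, the per-frame instantaneous stepping rate (reciprocal
#' of the enclosing inter-step interval, zero after a long pause), and the
#' mean normalized rate over the four reliably tracked front/middle legs
#' (L1, L2, R1, R2), each leg normalized by its within-trial mean rate.
#'
#' @slot stepTimes named list of numeric step times (s) per leg.
#' @slot rate n x n_legs matrix of instantaneous rates (Hz).
#' @slot meanRate per-frame mean normalized rate (dimensionless).
#' @slot frameRate frames per second.
#' @export
setClass("StepSeries", representation(
  stepTimes = "list", rate = "matrix", meanRate = "numeric",
  frameRate = "numeric"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "StepSeries", function(x) length(x@meanRate))
#' @rdname frameRate
#' @export
setMethod("frameRate", "StepSeries", function(x) x@frameRate)

setMethod("show", "StepSeries", function(object) {
  cnt <- vapply(object@stepTimes, length, integer(1))
  cat("StepSeries:", length(object@meanRate), "frames\n")
  cat("  steps per leg:",
      paste(names(cnt), cnt, sep = "=", collapse = ", "), "\n")
})

#' BandPowerMatrix: time-binned, baseline-scaled wavelet band power
#'
#' Continuous Morlet wavelet power averaged in 1 s time bins and fixed
#' frequency bands, then scaled per band as (P_t - P0)/P0 where P0 is the
#' band's average power over the pre-stimulus window. Values are bounded
#' below by -1 (power is nonnegative) and average 0 over the pre-stimulus
#' bins by construction.
#'
#' @slot scaled bins x bands matrix of (P_t - P0)/P0.
#' @slot raw bins x bands matrix of raw mean power (deg^2).
#' @slot bands bands x 2 matrix of [low, high) edges in Hz.
#' @slot p0 per-band pre-stimulus mean power.
#' @slot nScales number of wavelet scales falling in each band (band
#'   occupancy; the weight used when merging bands on raw power).
#' @slot binStart start time (s) of each time bin.
#' @slot binWidth time bin width, seconds.
#' @slot onset,offset stimulus window (s), carried for window summaries.
#' @slot edgeBin logical per time bin; `TRUE` where the bin overlaps the
#'   cone of influence of the largest scale (edge-affected, retained).
#' @export
setClass("BandPowerMatrix", representation(
  scaled = "matrix", raw = "matrix", bands = "matrix", p0 = "numeric",
  nScales = "numeric", binStart = "numeric", binWidth = "numeric",
  onset = "numeric", offset = "numeric", edgeBin = "logical"))

#' @rdname scaledPower
#' @export
setMethod("scaledPower", "BandPowerMatrix", function(x) x@scaled)
#' @rdname bandLabels
#' @export
setMethod("bandLabels", "BandPowerMatrix", function(x)
  sprintf("[%g,%g)", x@bands[, 1], x@bands[, 2]))

setMethod("show", "BandPowerMatrix", function(object) {
  cat("BandPowerMatrix:", nrow(object@scaled), "time bins x",
      nrow(object@bands), "bands\n")
  cat("  bands:", paste(bandLabels(object), collapse = " "), "Hz\n")
})

#' PIDTrace: photo-ionisation detector voltage trace with extrema
#'
#' A PID voltage time series (proxy for local odorant concentration) with
#' detected, alternation-enforced minima and maxima, from which per-window
#' fluctuation rate and magnitude are derived.
#'
#' @slot time_s sample times, seconds.
#' @slot volts voltages.
#' @slot minima,maxima integer sample indices of detected extrema.
#' @export
setClass("PIDTrace", representation(
  time_s = "numeric", volts = "numeric",
  minima = "integer", maxima = "integer"))

setValidity("PIDTrace", function(object) {
  if (length(object@time_s) != length(object@volts))
    return("time and voltage must have equal length")
  ev <- sort(c(object@minima, object@maxima))
  typ <- ifelse(ev %in% object@minima, "min", "max")
  if (length(typ) > 1 && any(typ[-1] == typ[-length(typ)]))
    return("extrema must alternate min/max")
  TRUE
})

setMethod("show", "PIDTrace", function(object) {
  cat("PIDTrace:", length(object@volts), "samples,",
      length(object@minima), "minima /", length(object@maxima), "maxima\n")
})

#' SmokeSequence: grayscale smoke-visualisation frames with ROI and mask
#'
#' Ordered grayscale frames (matrices in [0, 1]) of a laser-illuminated
#' smoke plume, a single intensity threshold shared by all frames of the
#' sequence, a region of interest in front of the head, and a binary body
#' mask removing pixels belonging to the animal.
#'
#' @slot frames list of numeric matrices in [0, 1], identical dimensions.
#' @slot threshold intensity threshold shared across frames.
#' @slot roi integer (row1, row2, col1, col2), inclusive, inside the frame.
#' @slot mask logical matrix, `TRUE` = body pixel (excluded).
#' @slot leftRightAxis `"row"` if ROI rows run along the animal's
#'   left-to-right axis (counts are then per ROI row), else `"col"`.
#' @export
setClass("SmokeSequence", representation(
  frames = "list", threshold = "numeric", roi = "integer",
  mask = "matrix", leftRightAxis = "character"))

setValidity("SmokeSequence", function(object) {
  msg <- character(0)
  if (!length(object@frames)) msg <- c(msg, "no frames")
  d <- dim(object@frames[[1]])
  if (!all(vapply(object@frames, function(f) identical(dim(f), d), logical(1))))
    msg <- c(msg, "all frames must share dimensions")
  if (!identical(dim(object@mask), d))
    msg <- c(msg, "mask dimensions must match the frames")
  r <- object@roi
  if (length(r) != 4L || r[1] < 1L || r[3] < 1L || r[2] > d[1] || r[4] > d[2] ||
      r[1] > r[2] || r[3] > r[4])
    msg <- c(msg, "ROI must be (row1, row2, col1, col2) inside the frame")
  if (!object@leftRightAxis %in% c("row", "col"))
    msg <- c(msg, "leftRightAxis must be 'row' or 'col'")
  if (length(msg)) msg else TRUE
})

#' Construct a SmokeSequence
#' @param frames list of grayscale matrices in [0, 1].
#' @param threshold shared intensity threshold.
#' @param roi integer (row1, row2, col1, col2).
#' @param mask logical body mask (TRUE = body), frame-sized.
#' @param left_right_axis `"row"` (default) or `"col"`; which matrix axis of
#'   the ROI runs along the animal's left-to-right direction.
#' @return a [SmokeSequence-class].
#' @export
smokeSequence <- function(frames, threshold, roi, mask,
                          left_right_axis = "row") {
  new("SmokeSequence", frames = frames, threshold = threshold,
      roi = as.integer(roi), mask = mask, leftRightAxis = left_right_axis)
}

setMethod("show", "SmokeSequence", function(object) {
  d <- dim(object@frames[[1]])
  cat("SmokeSequence:", length(object@frames), "frames of", d[1], "x", d[2],
      "px, threshold", object@threshold, "\n")
  cat("  ROI rows", object@roi[1], "-", object@roi[2], ", cols",
      object@roi[3], "-", object@roi[4], "\n")
})

#' ArenaTrack: animal positions in the two-shelter valence arena
#'
#' Tracked centroid positions in a circular arena with two disjoint circular
#' shelter zones (odour and control), from which shelter occupancy times and
#' the preference index are computed.
#'
#' @slot time_s sample times, seconds.
#' @slot x,y positions, arena mm.
#' @slot zones named list (`odour`, `control`); each `c(x, y, r)` in mm.
#' @slot duration session duration, seconds.
#' @export
setClass("ArenaTrack", representation(
  time_s = "numeric", x = "numeric", y = "numeric",
  zones = "list", duration = "numeric"))

setValidity("ArenaTrack", function(object) {
  msg <- character(0)
  if (!all(c("odour", "control") %in% names(object@zones)))
    msg <- c(msg, "zones must name 'odour' and 'control'")
  else {
    zo <- object@zones$odour; zc <- object@zones$control
    d <- sqrt(sum((zo[1:2] - zc[1:2])^2))
    if (d < zo[3] + zc[3]) msg <- c(msg, "shelter zones must be disjoint")
  }
  if (length(object@x) != length(object@y) ||
      length(object@x) != length(object@time_s))
    msg <- c(msg, "time, x and y must have equal length")
  if (length(msg)) msg else TRUE
})
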