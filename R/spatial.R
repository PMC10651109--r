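## Spatial metrics in the normalized (head-centred, antenna-length-scaled)
## coordinate system: occupancy maps, density curves, distance to the odour
## stream centre line, sweeping ranges, event-triggered baseline changes,
## sham correction, responsive-antenna labelling and stream-following
## correlation.

#' Occupancy map of antennal tip positions
#'
#' 2-D histogram of normalized tip positions over a coordinate plane,
#' expressed as proportions of all observations (values sum to 1). Bin edges
#' span [-1, 1]; values outside (possible after cross-trial rescaling) are
#' clipped to the edge bins.
#'
#' @param coords a [NormalizedCoords-class], or a list of them to pool
#'   across trials (pooled counts are normalized once, so the total is 1).
#' @param window frame indices to include (`NULL` = all), applied per trial.
#' @param plane `"xy"` (top view) or `"xz"` (front view).
#' @param bins bins per axis.
#' @param antenna `"both"`, `"L"` or `"R"`.
#' @return an [OccupancyMap-class].
#' @export
occupancyMap <- function(coords, window = NULL, plane = c("xy", "xz"),
                         bins = 24L, antenna = "both") {
  plane <- match.arg(plane)
  if (!is.list(coords)) coords <- list(coords)
  cols <- if (plane == "xy") c(1L, 2L) else c(1L, 3L)
  pts <- do.call(rbind, lapply(coords, function(nc) {
    idx <- if (is.null(window)) seq_len(nFrames(nc)) else window
    mats <- switch(antenna, both = list(nc@L[idx, , drop = FALSE],
                                        nc@R[idx, , drop = FALSE]),
                   L = list(nc@L[idx, , drop = FALSE]),
                   R = list(nc@R[idx, , drop = FALSE]))
    do.call(rbind, lapply(mats, function(m) m[, cols, drop = FALSE]))
  }))
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (!nrow(pts)) stop("empty window: no valid observations")
  breaks <- seq(-1, 1, length.out = bins + 1L)
  bin <- function(v) pmin(pmax(findInterval(v, breaks, all.inside = TRUE),
                               1L), bins)
  counts <- table(factor(bin(pts[, 1]), levels = seq_len(bins)),
                  factor(bin(pts[, 2]), levels = seq_len(bins)))
  vals <- matrix(as.numeric(counts), bins, bins)
  new("OccupancyMap", values = vals / sum(vals), xBreaks = breaks,
      yBreaks = breaks, plane = plane)
}

#' Rescale centred coordinates by the dataset-wide maximum
#'
#' Cross-trial occupancy maps are computed in a shared frame: each trial's
#' head-centred coordinates are expressed relative to the maximum absolute
#' coordinate across all trials (per axis), so 1/-1 is the furthest point
#' reached in the whole dataset. The shared constant is returned in the
#' `datasetScale` attribute, to be stored in a run manifest.
#'
#' @param coords_list list of [NormalizedCoords-class] objects.
#' @return list of rescaled [NormalizedCoords-class] objects with attribute
#'   `datasetScale` (mm per axis).
#' @export
crossTrialNormalize <- function(coords_list) {
  mm <- lapply(coords_list, function(nc)
    rbind(sweep(nc@L, 2, nc@axisScale, "*"),
          sweep(nc@R, 2, nc@axisScale, "*")))
  dsScale <- apply(abs(do.call(rbind, mm)), 2, max, na.rm = TRUE)
  dsScale[dsScale == 0] <- 1
  out <- lapply(coords_list, function(nc) {
    f <- nc@axisScale / dsScale
    nc@L <- sweep(nc@L, 2, f, "*")
    nc@R <- sweep(nc@R, 2, f, "*")
    nc@axisScale <- unname(dsScale)
    nc
  })
  attr(out, "datasetScale") <- unname(dsScale)
  out
}

#' Kernel probability density curve of 1-D positions
#'
#' Gaussian-kernel density of normalized 1-D coordinates; the area under the
#' curve equals 1. When comparing curves within one panel, pass the same
#' `bandwidth` to all.
#'
#' @param values numeric vector (NAs dropped).
#' @param bandwidth kernel bandwidth; `NULL` = automatic (`bw.nrd0`). A
#'   zero-variance input with automatic bandwidth is an error asking for an
#'   explicit bandwidth.
#' @param n grid points.
#' @return data.frame (`x`, `density`).
#' @export
densityCurve <- function(values, bandwidth = NULL, n = 512L) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 points")
  if (is.null(bandwidth)) {
    if (stats::var(values) == 0)
      stop("zero-variance input: supply an explicit bandwidth")
    d <- stats::density(values, n = n)
  } else {
    d <- stats::density(values, bw = bandwidth, n = n)
  }
  data.frame(x = d$x, density = d$y)
}

#' Distance of each antennal tip to the stream centre line
#'
#' Per-frame absolute Euclidean distance between the normalized tip
#' coordinates and the stream centre line — a line running along y at
#' lateral position `streamX(t)` and at the stream's nominal height (head
#' level by default), both mapped into the normalized frame (head-relative,
#' scaled by the trial's axis scales). With `mode = "xz"` (default) the
#' perpendicular distance in the x-z plane is used; `"x_only"` uses the
#' lateral component alone.
#'
#' @param coords a [NormalizedCoords-class].
#' @param trial the [Trial-class] the coordinates came from (for the head
#'   series and protocol).
#' @param mode `"xz"` or `"x_only"`.
#' @return n x 2 matrix (columns `L`, `R`) of nonnegative distances, in
#'   normalized (antennal-length) units.
#' @export
distanceToStream <- function(coords, trial, mode = c("xz", "x_only")) {
  mode <- match.arg(mode)
  pr <- protocol(trial)
  if (is.null(pr)) stop("protocol missing")
  n <- nFrames(coords)
  t <- (seq_len(n) - 1) / frameRate(coords)
  head <- trackedPoint(trial, "head")
  sx <- (streamX(pr, t) - head$xyz[, 1]) / coords@axisScale[1]
  sz <- (pr@streamZ - head$xyz[, 3]) / coords@axisScale[3]
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, ANTENNAE))
  for (a in ANTENNAE) {
    m <- slot(coords, a)
    out[, a] <- if (mode == "xz")
      sqrt((m[, 1] - sx)^2 + (m[, 3] - sz)^2)
    else
      abs(m[, 1] - sx)
  }
  out
}

#' Antennal sweeping range within a window
#'
#' The absolute maximum difference between horizontal (x) positions of one
#' antenna within the window: `max(x) - min(x)`.
#'
#' @param x numeric vector of one antenna's normalized x positions.
#' @param window frame indices (`NULL` = all).
#' @return nonnegative scalar.
#' @export
antennalRange <- function(x, window = NULL) {
  v <- if (is.null(window)) x else x[window]
  v <- v[!is.na(v)]
  if (length(v) < 2L) stop("need at least 2 valid frames in window")
  max(v) - min(v)
}

#' Overall range of both antennae combined
#'
#' The absolute maximum difference between the left-most and right-most
#' positions reached by the two antennae together.
#'
#' @param xL,xR normalized x positions of the left and right antenna.
#' @param window frame indices (`NULL` = all).
#' @return nonnegative scalar, always >= each individual range.
#' @export
overallRange <- function(xL, xR, window = NULL) {
  if (!is.null(window)) { xL <- xL[window]; xR <- xR[window] }
  v <- c(xL, xR)
  v <- v[!is.na(v)]
  if (length(v) < 2L) stop("need at least 2 valid frames in window")
  max(v) - min(v)
}

#' Event-triggered baseline change of a metric
#'
#' Expresses a per-frame metric as its difference from the mean over the
#' pre-stimulus window — a window of the same length as the stimulus,
#' directly before odour onset — so the pre-stimulus average is zero by
#' construction. Window means are computed for the pre, odour and post
#' windows (post = one stimulus length after offset, truncated at the trial
#' end); a window with more than half its frames invalid yields NA.
#'
#' @param metric numeric per-frame series (NA = invalid frame).
#' @param protocol a [StimulusProtocol-class].
#' @param frame_rate frames per second.
#' @param label metric name carried into the result.
#' @param pre_window_s pre-window length; `NULL` = stimulus duration.
#' @return a [ChangeSeries-class].
#' @export
baselineChange <- function(metric, protocol, frame_rate,
                           label = "metric", pre_window_s = NULL) {
  n <- length(metric)
  dur <- protocol@offset - protocol@onset
  preLen <- pre_window_s %||% dur
  preFrom <- protocol@onset - preLen
  if (preFrom < -1e-9)
    stop("pre-stimulus window [", round(preFrom, 3), ", ",
         protocol@onset, ") is truncated by the trial start")
  pre <- windowFrames(preFrom, protocol@onset, frame_rate, n)
  odour <- windowFrames(protocol@onset, protocol@offset, frame_rate, n)
  post <- windowFrames(protocol@offset, protocol@offset + dur, frame_rate, n)
  preMean <- windowMean(metric, pre)
  change <- metric - preMean
  wm <- c(pre = windowMean(change, pre), odour = windowMean(change, odour),
          post = windowMean(change, post))
  new("ChangeSeries", metric = label, time_s = (seq_len(n) - 1) / frame_rate,
      change = change, windowMeans = wm, shamCorrected = FALSE,
      onset = protocol@onset, offset = protocol@offset,
      frameRate = frame_rate)
}

#' Sham correction of a change series
#'
#' Subtracts the same animal's sham (air-only) control trial's change series
#' from an odour trial's, frame-aligned on time from odour onset, removing
#' mechanical (non-olfactory) response components. Both series must share
#' the stimulus timing; a length mismatch beyond `tol_s` is an error,
#' smaller mismatches are truncated to the common length.
#'
#' @param change odour-trial [ChangeSeries-class].
#' @param sham_change sham-trial [ChangeSeries-class].
#' @param tol_s tolerated duration mismatch, seconds.
#' @return a sham-corrected [ChangeSeries-class].
#' @export
shamCorrect <- function(change, sham_change, tol_s = 0.05) {
  if (abs(change@onset - sham_change@onset) > tol_s ||
      abs(change@offset - sham_change@offset) > tol_s)
    stop("stimulus timing differs between odour and sham trial")
  n1 <- length(change@change); n2 <- length(sham_change@change)
  if (abs(n1 - n2) / change@frameRate > tol_s)
    stop("trial lengths differ by more than ", tol_s, " s")
  n <- min(n1, n2)
  out <- change
  out@change <- change@change[seq_len(n)] - sham_change@change[seq_len(n)]
  out@time_s <- change@time_s[seq_len(n)]
  fr <- change@frameRate
  dur <- change@offset - change@onset
  pre <- windowFrames(change@onset - dur, change@onset, fr, n)
  odour <- windowFrames(change@onset, change@offset, fr, n)
  post <- windowFrames(change@offset, change@offset + dur, fr, n)
  out@windowMeans <- c(pre = windowMean(out@change, pre),
                       odour = windowMean(out@change, odour),
                       post = windowMean(out@change, post))
  out@shamCorrected <- TRUE
  out
}

#' Label the responsive antenna of a trial
#'
#' The responsive antenna is the one with the strongest decrease in distance
#' to the stream upon odour onset (the more negative odour-window mean
#' change, regardless of left/right identity). As a control, the same rule
#' is applied to the baseline variation between two consecutive pre-onset
#' windows (clean air only), without transferring antenna identities: on
#' stimulus-free data this control label splits at chance. Ties break to the
#' left antenna with a warning (measure-zero on real data).
#'
#' @param dist n x 2 matrix (columns `L`, `R`) of per-frame distances to the
#'   stream, as from [distanceToStream()].
#' @param protocol a [StimulusProtocol-class].
#' @param frame_rate frames per second.
#' @return list with `responsive` (`"L"`/`"R"`), `control` (pre-stimulus
#'   split label), `odour_change` (named numeric, odour-window mean change in
#'   distance per antenna) and `control_change` (same for the pre-onset
#'   split).
#' @export
labelResponsive <- function(dist, protocol, frame_rate) {
  dur <- protocol@offset - protocol@onset
  n <- nrow(dist)
  changeOf <- function(a, from, to) {
    cs <- baselineChange(dist[, a], stimulusProtocol(
      onset = from, offset = to,
      stream_x = protocol@streamPath, stream_z = protocol@streamZ),
      frame_rate, pre_window_s = to - from)
    windowMeans(cs)["odour"]
  }
  odourChange <- c(L = unname(changeOf("L", protocol@onset, protocol@offset)),
                   R = unname(changeOf("R", protocol@onset, protocol@offset)))
  if (any(is.na(odourChange)))
    stop("both antennae need valid odour-window means")
  if (isTRUE(all.equal(unname(odourChange["L"]), unname(odourChange["R"]))))
    warning("tied odour-window changes; responsive label breaks to L")
  responsive <- if (odourChange["R"] < odourChange["L"]) "R" else "L"
  ## control: the same rule on two consecutive pre-onset windows
  ctrlFrom <- protocol@onset - dur
  controlChange <- c(L = NA_real_, R = NA_real_)
  control <- NA_character_
  if (ctrlFrom - dur >= -1e-9) {
    controlChange <- c(L = unname(changeOf("L", ctrlFrom, protocol@onset)),
                       R = unname(changeOf("R", ctrlFrom, protocol@onset)))
    if (!any(is.na(controlChange)))
      control <- if (controlChange["R"] < controlChange["L"]) "R" else "L"
  }
  list(responsive = responsive, control = control,
       odour_change = odourChange, control_change = controlChange)
}

#' Correlation between antennal tip and stream movement
#'
#' Pearson correlation of the tip's lateral (x) position against the stream
#' centre position over the stimulus window; quantifies stream-following.
#' Constant input on either side leaves the correlation undefined and
#' returns NA with a warning.
#'
#' @param tip_x numeric tip lateral positions.
#' @param stream_x numeric stream centre positions, same length.
#' @return correlation coefficient in [-1, 1], or NA.
#' @export
streamFollowingCorrelation <- function(tip_x, stream_x) {
  ok <- !is.na(tip_x) & !is.na(stream_x)
  if (sum(ok) < 3L) stop("need at least 3 paired frames")
  x <- tip_x[ok]; y <- stream_x[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant series: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}
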