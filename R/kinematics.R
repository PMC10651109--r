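## Kinematic variables derived from the tracked points. Each antenna is
## approximated as a straight line from the tracked head point to the
## tracked tip (the flagellum cannot be bent voluntarily and passive bending
## is negligible at these air speeds), so angles are fully defined by the
## head-to-tip vector.

#' Antennal azimuth and elevation angles
#'
#' Azimuth is the signed angle between the horizontal projection of the
#' head-to-tip vector and the forward head-line (the tunnel +y midline
#' through the head point, or the tether-to-head axis with
#' `head_line = "body"`): 0 deg is parallel to the head-line, negative is
#' left, positive right. Elevation is the signed angle between the
#' head-to-tip vector and its horizontal projection: negative below head
#' level, positive above.
#'
#' Frames where head or tip is invalid, or where the head-to-tip vector has
#' zero length, are flagged invalid.
#'
#' @param x a [Trial-class].
#' @param head_line `"tunnel"` (default) or `"body"`; see
#'   [analysisConfig()].
#' @param tether_xy tether point (mm), required for `head_line = "body"`.
#' @return an [AngleSeries-class].
#' @examples
#' tr <- generateTrial(trialGeneratorParams(duration_s = 4), seed = 1)$trial
#' antennalAngles(tr)
#' @export
antennalAngles <- function(x, head_line = "tunnel", tether_xy = c(0, -20)) {
  head <- trackedPoint(x, "head")
  n <- nFrames(x)
  fwd <- if (head_line == "body") {
    v <- cbind(head$xyz[, 1] - tether_xy[1], head$xyz[, 2] - tether_xy[2])
    nv <- sqrt(rowSums(v^2))
    v / ifelse(nv > 0, nv, NA_real_)
  } else {
    cbind(rep(0, n), rep(1, n))          # tunnel midline, +y forward
  }
  az <- el <- valid <- matrix(NA_real_, n, 2, dimnames = list(NULL, ANTENNAE))
  valid <- matrix(FALSE, n, 2, dimnames = list(NULL, ANTENNAE))
  for (a in ANTENNAE) {
    tip <- trackedPoint(x, paste0("ant_", a))
    d <- tip$xyz - head$xyz
    ok <- head$valid & tip$valid
    len <- sqrt(rowSums(d^2))
    ok <- ok & !is.na(len) & len > 0
    ## signed azimuth: atan2 of the cross/dot of the horizontal projection
    ## against the forward direction; right of the head-line is positive
    cross <- d[, 1] * fwd[, 2] - d[, 2] * fwd[, 1]
    dot <- d[, 1] * fwd[, 1] + d[, 2] * fwd[, 2]
    az[, a] <- atan2(cross, dot) * 180 / pi
    horiz <- sqrt(d[, 1]^2 + d[, 2]^2)
    el[, a] <- atan2(d[, 3], horiz) * 180 / pi
    valid[, a] <- ok
    az[!ok, a] <- NA_real_
    el[!ok, a] <- NA_real_
  }
  new("AngleSeries", azimuth = az, elevation = el, valid = valid,
      frameRate = frameRate(x))
}

#' Heading of the head about the tether point
#'
#' The signed angle of the tether-to-head line against the tunnel midline
#' (+y) through the fixed tether point: negative left, positive right.
#' `abs()` of the result is the absolute heading (deviation from
#' straight-ahead). Frames where the head coincides with the tether point
#' are invalid.
#'
#' @param x a [Trial-class].
#' @param tether_xy tether point (x, y) in tunnel mm.
#' @return a [HeadingSeries-class].
#' @export
heading <- function(x, tether_xy) {
  head <- trackedPoint(x, "head")
  d <- cbind(head$xyz[, 1] - tether_xy[1], head$xyz[, 2] - tether_xy[2])
  len <- sqrt(rowSums(d^2))
  ok <- head$valid & !is.na(len) & len > 0
  h <- atan2(d[, 1], d[, 2]) * 180 / pi
  h[!ok] <- NA_real_
  new("HeadingSeries", heading = h, valid = ok, frameRate = frameRate(x))
}

#' Head-centred, within-trial normalized antennal tip coordinates
#'
#' Centres both antennal tips on the head at every frame (head maps to
#' (0, 0, 0)) and scales each axis by the within-trial maximum absolute
#' value — effectively normalising by the antennal length of the animal, so
#' normalized metrics are proportions of antennal length. With
#' `axes = "joint"` (default) both antennae share one scale per axis; with
#' `"per_antenna"` each antenna is scaled by its own maxima.
#'
#' An axis with zero maximum (no motion) passes through unscaled with a
#' warning.
#'
#' @param x a [Trial-class].
#' @param axes `"joint"` or `"per_antenna"`.
#' @return a [NormalizedCoords-class].
#' @export
normalizeCoords <- function(x, axes = c("joint", "per_antenna")) {
  axes <- match.arg(axes)
  head <- trackedPoint(x, "head")
  cent <- list()
  valid <- matrix(FALSE, nFrames(x), 2, dimnames = list(NULL, ANTENNAE))
  for (a in ANTENNAE) {
    tip <- trackedPoint(x, paste0("ant_", a))
    cent[[a]] <- tip$xyz - head$xyz
    valid[, a] <- head$valid & tip$valid
    cent[[a]][!valid[, a], ] <- NA_real_
  }
  lens <- unlist(lapply(cent, function(m) sqrt(rowSums(m^2))))
  scaleFactor <- max(lens, na.rm = TRUE)
  axisScaleOf <- function(mats) {
    s <- apply(abs(do.call(rbind, mats)), 2, max, na.rm = TRUE)
    if (any(s == 0 | !is.finite(s))) {
      warning("axis with zero maximum passes through unscaled")
      s[s == 0 | !is.finite(s)] <- 1
    }
    s
  }
  if (axes == "joint") {
    s <- axisScaleOf(cent)
    norm <- lapply(cent, function(m) sweep(m, 2, s, "/"))
    axisScale <- s
  } else {
    norm <- list()
    sL <- axisScaleOf(cent["L"]); sR <- axisScaleOf(cent["R"])
    norm$L <- sweep(cent$L, 2, sL, "/")
    norm$R <- sweep(cent$R, 2, sR, "/")
    axisScale <- pmax(sL, sR)
  }
  new("NormalizedCoords", L = norm$L, R = norm$R, valid = valid,
      axisScale = unname(axisScale), scaleFactor = scaleFactor,
      frameRate = frameRate(x))
}

#' Angular antennal speeds
#'
#' Frame-to-frame finite differences of azimuth and elevation at the native
#' frame rate (no implicit smoothing), and the combined angular speed:
#' the Euclidean norm of the two component rates by default,
#' `sqrt(az_rate^2 + el_rate^2)`, or their absolute sum with
#' `combined = "abs_sum"`. The first frame is NA (no preceding frame).
#'
#' @param x an [AngleSeries-class].
#' @param combined `"euclidean"` or `"abs_sum"`.
#' @return a [SpeedSeries-class].
#' @export
angularSpeed <- function(x, combined = c("euclidean", "abs_sum")) {
  combined <- match.arg(combined)
  if (nFrames(x) < 2) stop("need at least 2 frames")
  rate <- function(m) rbind(NA_real_, diff(m)) * x@frameRate
  azr <- rate(x@azimuth)
  elr <- rate(x@elevation)
  comb <- if (combined == "euclidean") sqrt(azr^2 + elr^2)
          else abs(azr) + abs(elr)
  new("SpeedSeries", azimuthSpeed = azr, elevationSpeed = elr,
      combined = comb, frameRate = x@frameRate)
}

#' Moving-average smoothing of a per-frame series
#'
#' Centred moving average with shrinking windows at the edges. Smoothing is
#' explicit and opt-in throughout the pipeline; no metric is smoothed
#' implicitly.
#'
#' @param x numeric per-frame vector.
#' @param window_s window length, seconds.
#' @param frame_rate frames per second.
#' @return numeric vector, same length.
#' @export
smoothSeries <- function(x, window_s, frame_rate) {
  movingAverage(x, window_s, frame_rate)
}
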