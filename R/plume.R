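## Plume structure analysis: smoke-visualisation image sequences
## (threshold, body mask, ROI, row-wise pixel profiles) and PID voltage
## traces (extrema detection, fluctuation rate and magnitude, and their
## regression on antennal speed).

#' Threshold and mask a smoke sequence
#'
#' Binarizes every frame of the sequence with its shared threshold and
#' restricts to the ROI, removing body-mask pixels, so white pixels only
#' represent smoke particles. Masking and thresholding commute, so the
#' result is order-invariant.
#'
#' @param x a [SmokeSequence-class].
#' @return list of logical ROI matrices (TRUE = smoke pixel).
#' @export
thresholdAndMask <- function(x) {
  r <- x@roi
  lapply(x@frames, function(f) {
    if (!identical(dim(f), dim(x@mask)))
      stop("mask and frame dimensions differ")
    bin <- (f >= x@threshold) & !x@mask
    bin[r[1]:r[2], r[3]:r[4], drop = FALSE]
  })
}

#' Row-wise smoke pixel profile of a binary ROI frame
#'
#' Counts white pixels along the animal's left-to-right axis of the ROI —
#' the left-to-right distribution of smoke particles in front of the head.
#' The profile width is the longest contiguous run of rows whose count
#' exceeds `floor_frac` of the profile's maximum count; widths are
#' normalized against a reference frame (frame I of the sequence), whose
#' normalized width is 1.
#'
#' @param bin logical ROI matrix from [thresholdAndMask()].
#' @param left_right_axis `"row"` or `"col"`: which matrix axis runs
#'   left-to-right (declared in the sequence metadata, never guessed).
#' @param floor_frac fraction of the maximum count a row must exceed to
#'   count as plume.
#' @param reference_width width (rows) of the reference frame; `NULL`
#'   leaves `norm_width` NA.
#' @return list: `counts` (integer per row), `width` (rows),
#'   `norm_width` (width / reference width).
#' @export
rowProfile <- function(bin, left_right_axis = "row", floor_frac = 0.05,
                       reference_width = NULL) {
  if (!length(bin)) stop("empty ROI")
  counts <- if (left_right_axis == "row") rowSums(bin) else colSums(bin)
  counts <- as.integer(counts)
  width <- profileWidth(counts, floor_frac)
  norm <- NA_real_
  if (!is.null(reference_width)) {
    if (reference_width == 0) stop("reference width is zero")
    norm <- width / reference_width
  }
  list(counts = counts, width = width, norm_width = norm)
}

## Longest contiguous run of rows above floor_frac * max(counts).
profileWidth <- function(counts, floor_frac) {
  if (!any(counts > 0)) return(0L)
  above <- counts > floor_frac * max(counts)
  r <- rle(above)
  runs <- r$lengths[r$values]
  if (!length(runs)) 0L else max(runs)
}

#' Row profiles of a whole smoke sequence
#'
#' Applies [thresholdAndMask()] and [rowProfile()] to every frame,
#' normalizing widths by the reference frame (frame I by default).
#'
#' @param x a [SmokeSequence-class].
#' @param floor_frac see [rowProfile()].
#' @param reference_frame index of the frame whose width normalizes the
#'   others.
#' @return data.frame: `frame`, `width`, `norm_width`, `total_pixels`.
#' @export
smokeProfiles <- function(x, floor_frac = 0.05, reference_frame = 1L) {
  bins <- thresholdAndMask(x)
  ref <- rowProfile(bins[[reference_frame]], x@leftRightAxis, floor_frac)
  if (ref$width == 0) stop("reference width is zero")
  rows <- lapply(seq_along(bins), function(i) {
    p <- rowProfile(bins[[i]], x@leftRightAxis, floor_frac,
                    reference_width = ref$width)
    data.frame(frame = i, width = p$width, norm_width = p$norm_width,
               total_pixels = sum(p$counts))
  })
  do.call(rbind, rows)
}

#' Detect alternating PID minima and maxima
#'
#' Prominence-filtered local extrema of a PID voltage trace, with
#' alternation enforced by keeping the more extreme of same-type
#' neighbours. Prominence is expressed as a fraction of the trace's voltage
#' range.
#'
#' @param x a [PIDTrace-class] (or numeric voltage vector with `time_s`).
#' @param min_prominence_frac prominence threshold as a fraction of the
#'   voltage range.
#' @param time_s sample times when `x` is a bare numeric vector.
#' @return a [PIDTrace-class] with `minima` and `maxima` filled in.
#' @export
detectPidExtrema <- function(x, min_prominence_frac = 0.02, time_s = NULL) {
  if (is.numeric(x)) {
    if (is.null(time_s)) time_s <- seq_along(x) - 1
    x <- new("PIDTrace", time_s = time_s, volts = x,
             minima = integer(0), maxima = integer(0))
  }
  v <- x@volts
  if (length(v) < 3L) stop("need at least 3 samples")
  prom <- min_prominence_frac * diff(range(v))
  maxI <- findPeaks(v, min_prominence = prom)
  minI <- findPeaks(-v, min_prominence = prom)
  ev <- data.frame(idx = c(maxI, minI),
                   type = rep(c("max", "min"), c(length(maxI), length(minI))))
  ev <- ev[order(ev$idx), , drop = FALSE]
  ## enforce alternation: among same-type neighbours keep the more extreme
  if (nrow(ev) > 1) {
    kept <- 1L                            # positions kept so far, in order
    for (i in 2:nrow(ev)) {
      last <- kept[length(kept)]
      if (ev$type[i] != ev$type[last]) {
        kept <- c(kept, i)
      } else {
        vi <- v[ev$idx[i]]; vl <- v[ev$idx[last]]
        more_extreme <- if (ev$type[i] == "max") vi > vl else vi < vl
        if (more_extreme) kept[length(kept)] <- i
      }
    }
    ev <- ev[kept, , drop = FALSE]
  }
  x@maxima <- as.integer(ev$idx[ev$type == "max"])
  x@minima <- as.integer(ev$idx[ev$type == "min"])
  validObject(x)
  x
}

#' Fluctuation rate and magnitude of a PID trace
#'
#' Over a time window, the fluctuation rate is the average instantaneous
#' frequency of all detected minima and maxima — the mean reciprocal of
#' successive inter-event intervals of the pooled, ordered extrema sequence
#' (`rate_mode = "count"` uses events/duration instead). The magnitude is
#' the mean positive contrast: the average voltage rise from each minimum to
#' its subsequent maximum. Windows with fewer than 2 extrema (rate) or no
#' min-to-max pair (magnitude) yield NA.
#'
#' @param x a [PIDTrace-class] with detected extrema.
#' @param window c(from, to) seconds; `NULL` = whole trace.
#' @param rate_mode `"pooled"` or `"count"`.
#' @return named numeric: `rate` (Hz), `magnitude` (V), `n_events`.
#' @export
fluctuationStats <- function(x, window = NULL, rate_mode = "pooled") {
  ev <- sort(c(x@minima, x@maxima))
  tev <- x@time_s[ev]
  if (!is.null(window)) {
    sel <- tev >= window[1] & tev < window[2]
    ev <- ev[sel]; tev <- tev[sel]
  }
  rate <- NA_real_
  if (length(ev) >= 2L) {
    rate <- if (rate_mode == "pooled") mean(1 / diff(tev))
            else (length(ev) - 1) / (tev[length(tev)] - tev[1])
  }
  mins <- intersect(ev, x@minima)
  mag <- NA_real_
  if (length(mins)) {
    rises <- vapply(mins, function(i) {
      nxt <- x@maxima[x@maxima > i]
      if (!length(nxt)) return(NA_real_)
      x@volts[min(nxt)] - x@volts[i]
    }, numeric(1))
    rises <- rises[!is.na(rises)]
    if (length(rises)) mag <- mean(rises)
  }
  c(rate = rate, magnitude = mag, n_events = length(ev))
}

#' Select analysis windows from antennal speed peaks
#'
#' Systematically selects non-overlapping windows of `window_s` seconds
#' centred on local peaks of the moving-average-smoothed combined antennal
#' speed, spanning a wide range of movement regimes. Peak detection uses the
#' smoothed speed, but downstream analysis uses the unaltered speed. In
#' `control` mode (fixed-antenna recordings) the same number of
#' non-overlapping windows is drawn at random under the given seed. If no
#' peaks are found, evenly spaced windows are returned with a warning.
#'
#' @param speed numeric combined angular speed per frame (deg/s).
#' @param frame_rate frames per second.
#' @param window_s window length (s).
#' @param n_windows maximum number of windows.
#' @param smooth_s moving-average window for peak detection (s).
#' @param min_prominence peak prominence threshold (deg/s) on the smoothed
#'   speed.
#' @param control `TRUE` for seeded random windows.
#' @param seed RNG seed for control mode.
#' @return data.frame: `start_s`, `end_s`, `mean_speed` (from the unaltered
#'   speed).
#' @export
selectSpeedWindows <- function(speed, frame_rate, window_s = 2,
                               n_windows = 20L, smooth_s = 0.5,
                               min_prominence = 5, control = FALSE,
                               seed = 1L) {
  n <- length(speed)
  wlen <- round(window_s * frame_rate)
  if (n <= wlen) stop("speed series shorter than one window")
  starts <- if (control) {
    cand <- withSeed(seed, sample(seq_len(n - wlen), min(5000L, n - wlen)))
    pickNonOverlapping(cand, wlen, n_windows)
  } else {
    sm <- movingAverage(speed, smooth_s, frame_rate)
    peaks <- findPeaks(sm, min_prominence = min_prominence,
                       min_separation = wlen)
    if (!length(peaks)) {
      warning("no speed peaks found; falling back to evenly spaced windows")
      starts <- floor(seq(1, n - wlen, length.out = n_windows))
      starts
    } else {
      cand <- pmin(pmax(peaks - wlen %/% 2, 1L), n - wlen)
      cand <- cand[order(-sm[peaks])]
      pickNonOverlapping(cand, wlen, n_windows)
    }
  }
  starts <- sort(starts)
  data.frame(
    start_s = (starts - 1) / frame_rate,
    end_s = (starts - 1 + wlen) / frame_rate,
    mean_speed = vapply(starts, function(s)
      mean(speed[s:(s + wlen - 1L)], na.rm = TRUE), numeric(1)))
}

pickNonOverlapping <- function(candidates, wlen, n_max) {
  kept <- integer(0)
  for (s in candidates) {
    if (length(kept) >= n_max) break
    if (!length(kept) || all(abs(kept - s) >= wlen)) kept <- c(kept, s)
  }
  kept
}

#' Regress PID fluctuation statistics on antennal speed
#'
#' Ordinary least-squares fits of per-window fluctuation rate and magnitude
#' against the window's mean antennal speed, with Pearson correlations and a
#' seeded bootstrap interval on each slope (resampling windows). The
#' interval is the t-scaled bootstrap-standard-error interval
#' (slope +/- t[0.975, n-2] * SE_boot), which holds its nominal coverage
#' better than the percentile interval at the few tens of windows a single
#' recording yields.
#'
#' @param windows data.frame with `mean_speed`, `rate`, `magnitude`
#'   (NA rows dropped per outcome).
#' @param n_boot bootstrap resamples.
#' @param seed bootstrap seed.
#' @return data.frame, one row per outcome: `outcome`, `slope`,
#'   `intercept`, `r`, `slope_lower`, `slope_upper`, `n`.
#' @export
regressFluctuationsOnSpeed <- function(windows, n_boot = 2000L, seed = 1L) {
  fitOne <- function(outcome, sd_offset) {
    d <- windows[!is.na(windows[[outcome]]) & !is.na(windows$mean_speed), ]
    if (nrow(d) < 3L) stop("need at least 3 windows for ", outcome)
    if (stats::sd(d$mean_speed) == 0) stop("constant predictor")
    fit <- stats::lm(d[[outcome]] ~ d$mean_speed)
    sl <- withSeed(seed + sd_offset, vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(nrow(d), replace = TRUE)
      xs <- d$mean_speed[idx]; ys <- d[[outcome]][idx]
      if (stats::sd(xs) == 0) return(NA_real_)
      stats::cov(xs, ys) / stats::var(xs)
    }, numeric(1)))
    slope <- unname(stats::coef(fit)[2])
    half <- stats::qt(0.975, nrow(d) - 2) * stats::sd(sl, na.rm = TRUE)
    data.frame(outcome = outcome,
               slope = slope,
               intercept = unname(stats::coef(fit)[1]),
               r = stats::cor(d$mean_speed, d[[outcome]]),
               slope_lower = slope - half, slope_upper = slope + half,
               n = nrow(d))
  }
  out <- rbind(fitOne("rate", 0L), fitOne("magnitude", 1L))
  rownames(out) <- NULL
  out
}

#' Per-window PID fluctuation statistics for selected speed windows
#'
#' Convenience wrapper: detects extrema on the PID trace once and computes
#' [fluctuationStats()] in every window of a [selectSpeedWindows()] table.
#'
#' @param pid a [PIDTrace-class] (extrema detected if absent).
#' @param windows data.frame from [selectSpeedWindows()].
#' @param min_prominence_frac see [detectPidExtrema()].
#' @param rate_mode see [fluctuationStats()].
#' @return `windows` with `rate`, `magnitude` and `n_events` columns added.
#' @export
windowFluctuations <- function(pid, windows, min_prominence_frac = 0.02,
                               rate_mode = "pooled") {
  if (!length(pid@minima) && !length(pid@maxima))
    pid <- detectPidExtrema(pid, min_prominence_frac)
  stats <- t(vapply(seq_len(nrow(windows)), function(i)
    fluctuationStats(pid, c(windows$start_s[i], windows$end_s[i]),
                     rate_mode = rate_mode), numeric(3)))
  cbind(windows, as.data.frame(stats))
}
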