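#' Centred moving average with shrinking edge windows
#'
#' Smooths a series with a centred moving-average window. Near the edges the
#' window shrinks symmetrically so the output has the same length as the
#' input and no frames are discarded.
#'
#' @param x numeric vector; may contain `NA` (ignored within each window).
#' @param window_s window length in seconds.
#' @param frame_rate sampling rate in frames per second.
#' @return numeric vector, same length as `x`.
#' @export
movingAverage <- function(x, window_s, frame_rate) {
  stopifnot(is.numeric(x), window_s > 0, frame_rate > 0)
  n <- length(x)
  if (round(window_s * frame_rate) > n)
    stop("smoothing window (", window_s, " s) is longer than the series")
  half <- max(0L, as.integer(floor(window_s * frame_rate / 2)))
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    out[i] <- mean(x[(i - h):(i + h)], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

## Topographic prominence of local maxima. For each candidate peak, walk out
## on both sides until a strictly higher sample (or the series end) is met;
## the prominence is the peak height minus the higher of the two interval
## minima. This matches the usual definition used by signal-processing
## toolboxes and is checked against a brute-force oracle in the tests.
peakProminence <- function(x, idx) {
  n <- length(x)
  vapply(idx, function(i) {
    h <- x[i]
    lmin <- h
    j <- i - 1L
    while (j >= 1L && x[j] <= h) {
      if (x[j] < lmin) lmin <- x[j]
      j <- j - 1L
    }
    leftBase <- if (j >= 1L) lmin else min(x[1:i])
    rmin <- h
    j <- i + 1L
    while (j <= n && x[j] <= h) {
      if (x[j] < rmin) rmin <- x[j]
      j <- j + 1L
    }
    rightBase <- if (j <= n) rmin else min(x[i:n])
    h - max(leftBase, rightBase)
  }, numeric(1))
}

#' Detect local maxima with prominence and separation thresholds
#'
#' Finds indices of local maxima whose topographic prominence reaches
#' `min_prominence`, then greedily enforces a minimum separation, keeping
#' higher peaks first. Plateaus contribute their first sample.
#'
#' @param x numeric vector (`NA` treated as -Inf, i.e. never a peak).
#' @param min_prominence minimum prominence, in the units of `x`.
#' @param min_separation minimum index separation between kept peaks
#'   (0 disables the separation filter).
#' @return integer vector of peak indices, ascending.
#' @export
findPeaks <- function(x, min_prominence = 0, min_separation = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  xx <- x
  xx[is.na(xx)] <- -Inf
  i <- 2:(n - 1L)
  ## a plateau peak is the first sample strictly above its left neighbour
  ## and at least as high as everything until a strict drop
  cand <- i[xx[i] > xx[i - 1L] & xx[i] >= xx[i + 1L]]
  ## drop plateau samples that are followed (after the flat run) by a rise
  keep <- vapply(cand, function(k) {
    j <- k + 1L
    while (j <= n && xx[j] == xx[k]) j <- j + 1L
    j > n || xx[j] < xx[k]
  }, logical(1))
  cand <- cand[keep]
  cand <- cand[is.finite(x[cand])]
  if (!length(cand)) return(integer(0))
  prom <- peakProminence(xx, cand)
  cand <- cand[prom >= min_prominence]
  if (!length(cand) || min_separation <= 0) return(sort(cand))
  ord <- cand[order(-xx[cand], cand)]
  kept <- integer(0)
  for (k in ord) {
    if (!length(kept) || all(abs(kept - k) >= min_separation))
      kept <- c(kept, k)
  }
  sort(kept)
}

## Linear interpolation of invalid frames for short dropouts.
## Runs of invalid frames no longer than max_gap frames are filled per
## column; longer runs (and untouched edges) stay invalid.
interpolateGaps <- function(mat, valid, max_gap) {
  stopifnot(nrow(mat) == length(valid))
  n <- length(valid)
  newValid <- valid
  if (all(valid) || sum(valid) < 2L) return(list(mat = mat, valid = newValid))
  r <- rle(!valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    s <- starts[k]; e <- ends[k]
    if (s == 1L || e == n) next            # edge gaps are not extrapolated
    if (r$lengths[k] > max_gap) next
    for (col in seq_len(ncol(mat))) {
      mat[s:e, col] <- stats::approx(
        x = c(s - 1L, e + 1L), y = mat[c(s - 1L, e + 1L), col],
        xout = s:e)$y
    }
    newValid[s:e] <- TRUE
  }
  list(mat = mat, valid = newValid)
}

## Mean over a window of frames, ignoring NA; windows with more than
## half their frames missing yield NA (excluded from summaries).
windowMean <- function(x, idx, max_missing_frac = 0.5) {
  if (!length(idx)) return(NA_real_)
  v <- x[idx]
  if (mean(is.na(v)) > max_missing_frac) return(NA_real_)
  mean(v, na.rm = TRUE)
}

#' Seeded nonparametric bootstrap for a mean
#'
#' Percentile bootstrap interval for the mean of a sample. Used for
#' group-level window summaries in place of model-based intervals.
#'
#' @param x numeric vector (NAs dropped).
#' @param n_boot number of resamples.
#' @param conf confidence level.
#' @param seed integer seed; the RNG state is restored on exit.
#' @return named numeric: `mean`, `lower`, `upper`.
#' @export
bootstrapMean <- function(x, n_boot = 2000, conf = 0.95, seed = 1L) {
  x <- x[!is.na(x)]
  if (!length(x)) return(c(mean = NA_real_, lower = NA_real_, upper = NA_real_))
  means <- withSeed(seed, {
    vapply(seq_len(n_boot),
           function(i) mean(sample(x, replace = TRUE)), numeric(1))
  })
  a <- (1 - conf) / 2
  q <- stats::quantile(means, c(a, 1 - a), names = FALSE)
  c(mean = mean(x), lower = q[1], upper = q[2])
}

## Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Deterministic seed splitting
#'
#' Fans a single master seed out to `n` sub-seeds so each generated trial
#' or dataset is independently reproducible; all randomness in the
#' simulation scenarios flows from one seed through this scheme.
#'
#' @param seed master seed.
#' @param n number of sub-seeds.
#' @return integer vector of `n` sub-seeds (each below 2^31).
#' @export
splitSeed <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

## Frame indices of a [from, to) time window at a given frame rate,
## clipped to n frames. Frame i covers time (i-1)/rate.
windowFrames <- function(from_s, to_s, frame_rate, n) {
  i0 <- floor(from_s * frame_rate) + 1L
  i1 <- ceiling(to_s * frame_rate)
  i0 <- max(1L, i0); i1 <- min(n, i1)
  if (i1 < i0) integer(0) else seq.int(i0, i1)
}
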