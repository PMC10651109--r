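## Independent brute-force oracles and tiny fixture builders used across
## the suite. These deliberately re-derive quantities from first principles
## and stay independent of the package's implementation paths.

## Moving average by direct looped mean over the shrunken centred window.
bruteMovingAverage <- function(x, half) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)
    mean(x[(i - h):(i + h)])
  }, numeric(1))
}

## All local maxima with topographic prominence from the definition:
## walk to the nearest strictly higher sample on each side; the prominence
## is the height minus the higher of the two interval minima.
brutePeaks <- function(x, min_prominence = 0) {
  n <- length(x)
  out <- integer(0)
  for (i in 2:(n - 1L)) {
    if (!(x[i] > x[i - 1L] && x[i] >= x[i + 1L])) next
    j <- i + 1L
    while (j <= n && x[j] == x[i]) j <- j + 1L
    if (j <= n && x[j] > x[i]) next      # plateau followed by a rise
    left <- i - 1L
    while (left >= 1L && x[left] <= x[i]) left <- left - 1L
    lmin <- min(x[max(left, 1L):i])
    right <- i + 1L
    while (right <= n && x[right] <= x[i]) right <- right + 1L
    rmin <- min(x[i:min(right, n)])
    if (x[i] - max(lmin, rmin) >= min_prominence) out <- c(out, i)
  }
  out
}

## Alternating min/max extrema by a naive pass: prominence-filtered maxima
## of x and of -x, merged in index order, then same-type neighbours
## resolved by keeping the more extreme one.
bruteExtrema <- function(v, prom) {
  mx <- brutePeaks(v, prom)
  mn <- brutePeaks(-v, prom)
  idx <- c(mx, mn)
  typ <- rep(c("max", "min"), c(length(mx), length(mn)))
  o <- order(idx)
  idx <- idx[o]; typ <- typ[o]
  keep_idx <- integer(0); keep_typ <- character(0)
  for (k in seq_along(idx)) {
    m <- length(keep_idx)
    if (m == 0L || typ[k] != keep_typ[m]) {
      keep_idx <- c(keep_idx, idx[k]); keep_typ <- c(keep_typ, typ[k])
    } else {
      better <- if (typ[k] == "max") v[idx[k]] > v[keep_idx[m]]
                else v[idx[k]] < v[keep_idx[m]]
      if (better) keep_idx[m] <- idx[k]
    }
  }
  list(maxima = keep_idx[keep_typ == "max"],
       minima = keep_idx[keep_typ == "min"])
}

## Gaussian kernel density by the direct sum.
bruteKernelDensity <- function(values, bw, q) {
  vapply(q, function(p) mean(stats::dnorm(p, mean = values, sd = bw)),
         numeric(1))
}

## Range as the max pairwise absolute difference.
bruteRange <- function(v) max(abs(outer(v, v, "-")))

## A minimal trial with prescribed head/tip (and optionally leg) paths.
makeTrial <- function(head, antL, antR, legs = NULL, frame_rate = 100,
                      onset = NULL, offset = NULL, stream_x = 0,
                      is_sham = FALSE) {
  n <- nrow(head)
  if (is.null(onset)) { onset <- n / frame_rate * 0.4 }
  if (is.null(offset)) { offset <- n / frame_rate * 0.6 }
  pts <- c(list(head = head, ant_L = antL, ant_R = antR), legs)
  trial("t1", "a1", "colony", frame_rate, pts,
        stimulusProtocol(onset, offset, stream_x = stream_x,
                         is_sham = is_sham))
}

## Constant-position point series.
constPoint <- function(n, x, y, z) cbind(x = rep(x, n), y = rep(y, n),
                                         z = rep(z, n))

## Triangle wave in [0, 1] with given frequency (peaks once per cycle).
triangleWave <- function(t, freq) {
  f <- (t * freq) %% 1
  ifelse(f < 0.5, 2 * f, 2 - 2 * f)
}
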