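## Spectral analysis of angular time series: one-sided FFT amplitude
## spectra for summary figures, and the continuous Morlet wavelet band-power
## statistic — wavelet power averaged in 1 s time bins and fixed frequency
## bands, scaled per band as (P_t - P0)/P0 against the pre-stimulus average.

#' One-sided FFT amplitude spectrum
#'
#' Amplitude spectrum of a uniformly sampled angular series (mean removed).
#' Amplitudes are scaled so a pure sinusoid of amplitude A yields a peak of
#' height A at its frequency; Parseval's identity then reads
#' `sum(amplitude^2) / 2 ~ var(x)` (for odd-length series). NAs are linearly
#' interpolated before transforming. Trial averaging is a plain mean of
#' spectra computed on a shared grid.
#'
#' @param x numeric per-frame series (>= 64 valid frames).
#' @param frame_rate frames per second.
#' @param time_s optional sample times; if given, sampling must be uniform.
#' @return data.frame (`frequency`, `amplitude`), excluding DC.
#' @export
fftSpectrum <- function(x, frame_rate, time_s = NULL) {
  if (!is.null(time_s)) {
    dt <- diff(time_s)
    if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
      stop("non-uniform sampling")
    frame_rate <- 1 / dt[1]
  }
  if (sum(!is.na(x)) < 64L) stop("need at least 64 valid frames")
  x <- fillNA(x)
  x <- x - mean(x)
  n <- length(x)
  X <- stats::fft(x)
  half <- floor(n / 2)
  k <- seq_len(half)                      # excludes DC
  amp <- 2 * Mod(X[k + 1L]) / n
  if (n %% 2 == 0) amp[half] <- amp[half] / 2   # Nyquist is not doubled
  data.frame(frequency = k * frame_rate / n, amplitude = amp)
}

## Linear interpolation over NAs (edges held at nearest valid value).
fillNA <- function(x) {
  if (!anyNA(x)) return(x)
  ok <- which(!is.na(x))
  if (length(ok) < 2L) stop("too few valid samples to interpolate")
  stats::approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
}

#' Continuous Morlet wavelet transform power
#'
#' FFT-implemented continuous wavelet transform with an analytic Morlet
#' mother (centre frequency `omega0`, default 6), on a dyadic scale grid
#' with `voices_per_octave` scales per octave spanning `freq_range`. The
#' series mean is removed and the series zero-padded to the next power of
#' two before transforming; no tapering is applied.
#'
#' @param x numeric series (NAs linearly interpolated).
#' @param frame_rate frames per second.
#' @param freq_range c(min, max) frequency span in Hz.
#' @param voices_per_octave scales per octave.
#' @param omega0 Morlet centre frequency.
#' @return list: `power` (scales x time matrix), `freqs` (Hz, descending in
#'   scale order), `coi_s` (per-sample cone-of-influence e-folding time, s).
#' @export
morletPower <- function(x, frame_rate, freq_range = c(0.5, 10),
                        voices_per_octave = 12L, omega0 = 6) {
  x <- fillNA(x)
  x <- x - mean(x)
  n <- length(x)
  dt <- 1 / frame_rate
  npad <- 2^ceiling(log2(n))
  xp <- c(x, rep(0, npad - n))
  Xf <- stats::fft(xp)
  freqs <- 2^seq(log2(freq_range[1]), log2(freq_range[2]),
                 by = 1 / voices_per_octave)
  fourier_factor <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi)
  scales <- fourier_factor / freqs       # seconds
  omega <- 2 * pi * seq(0, npad - 1) / (npad * dt)
  omega[omega > pi / dt] <- omega[omega > pi / dt] - 2 * pi / dt
  power <- matrix(NA_real_, length(scales), n)
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi <- pi^(-0.25) * sqrt(2 * pi * s / dt) *
      exp(-((s * omega - omega0)^2) / 2) * (omega > 0)
    w <- stats::fft(Xf * psi, inverse = TRUE) / npad
    power[j, ] <- Mod(w[seq_len(n)])^2
  }
  t <- (seq_len(n) - 1) * dt
  coi <- sqrt(2) * max(scales)
  list(power = power, freqs = freqs, scales = scales,
       coi_edge = pmin(t, rev(t)) < coi)
}

#' Wavelet band power scaled to the pre-stimulus baseline
#'
#' Computes the continuous Morlet wavelet power of an angular series,
#' averages it in `bin_s` time bins and the configured frequency bands, and
#' scales each band as `(P_t - P0) / P0`, where `P_t` is the band's mean
#' power in a time bin and `P0` its average over the pre-stimulus bins —
#' expressing power changes as a proportion of the pre-stimulus average.
#' Scaled values are bounded below by -1 and average 0 over the pre-stimulus
#' bins by construction. A band whose `P0` is zero is reported missing with
#' a warning. Bins overlapping the largest scale's cone of influence are
#' flagged (`@edgeBin`) but retained.
#'
#' @param x numeric per-frame angular series (degrees).
#' @param frame_rate frames per second.
#' @param protocol a [StimulusProtocol-class] defining the stimulus window;
#'   the pre-stimulus window has the stimulus length and ends at onset.
#' @param config an [analysisConfig()] list (bands, bin width, wavelet
#'   parameters).
#' @param pre_window_s override of the pre-window length (s).
#' @return a [BandPowerMatrix-class].
#' @export
waveletBandPower <- function(x, frame_rate, protocol,
                             config = analysisConfig(),
                             pre_window_s = NULL) {
  if (length(x) < 2 * frame_rate) stop("need at least 2 s of frames")
  bands <- config$bands
  bin_s <- config$power_bin_s
  wp <- morletPower(x, frame_rate,
                    freq_range = range(bands),
                    voices_per_octave = config$voices_per_octave,
                    omega0 = config$wavelet_omega0)
  n <- ncol(wp$power)
  t <- (seq_len(n) - 1) / frame_rate
  binIdx <- floor(t / bin_s)
  bins <- sort(unique(binIdx))
  ## keep only complete bins
  full <- vapply(bins, function(b) sum(binIdx == b) >= bin_s * frame_rate,
                 logical(1))
  bins <- bins[full]
  nb <- length(bins)
  raw <- matrix(NA_real_, nb, nrow(bands))
  nScales <- numeric(nrow(bands))
  for (k in seq_len(nrow(bands))) {
    inBand <- wp$freqs >= bands[k, 1] & wp$freqs < bands[k, 2]
    nScales[k] <- sum(inBand)
    if (!nScales[k]) next
    bandP <- colMeans(wp$power[inBand, , drop = FALSE])
    raw[, k] <- vapply(bins, function(b) mean(bandP[binIdx == b]),
                       numeric(1))
  }
  binStart <- bins * bin_s
  dur <- protocol@offset - protocol@onset
  preLen <- pre_window_s %||% dur
  preBins <- binStart >= protocol@onset - preLen - 1e-9 &
    binStart + bin_s <= protocol@onset + 1e-9
  if (!any(preBins)) stop("pre-stimulus window contains no complete time bin")
  p0 <- colMeans(raw[preBins, , drop = FALSE])
  zero <- !is.na(p0) & p0 == 0
  if (any(zero)) {
    warning("band(s) with zero pre-stimulus power reported missing: ",
            paste(which(zero), collapse = ", "))
    p0[zero] <- NA_real_
  }
  scaled <- sweep(sweep(raw, 2, p0, "-"), 2, p0, "/")
  edgeBin <- vapply(bins, function(b) any(wp$coi_edge[binIdx == b]),
                    logical(1))
  new("BandPowerMatrix", scaled = scaled, raw = raw, bands = bands,
      p0 = p0, nScales = nScales, binStart = binStart, binWidth = bin_s,
      onset = protocol@onset, offset = protocol@offset, edgeBin = edgeBin)
}

#' Merge frequency bands of a BandPowerMatrix on raw power
#'
#' Bands are merged on raw power, weighted by band occupancy (the number of
#' wavelet scales per band), and then rescaled against the merged
#' pre-stimulus average — not by averaging ratios, which would bias the
#' result toward low-power bands.
#'
#' @param x a [BandPowerMatrix-class].
#' @param groups list of integer vectors of band indices to merge; bands
#'   not listed are dropped.
#' @return a [BandPowerMatrix-class] with merged bands.
#' @export
mergeBands <- function(x, groups) {
  nb <- length(groups)
  raw <- matrix(NA_real_, nrow(x@raw), nb)
  bands <- matrix(NA_real_, nb, 2, dimnames = list(NULL, c("low", "high")))
  p0 <- nS <- numeric(nb)
  for (g in seq_len(nb)) {
    idx <- groups[[g]]
    w <- x@nScales[idx]
    raw[, g] <- as.vector(x@raw[, idx, drop = FALSE] %*% w) / sum(w)
    p0[g] <- sum(x@p0[idx] * w) / sum(w)
    nS[g] <- sum(w)
    bands[g, ] <- c(min(x@bands[idx, 1]), max(x@bands[idx, 2]))
  }
  scaled <- sweep(sweep(raw, 2, p0, "-"), 2, p0, "/")
  new("BandPowerMatrix", scaled = scaled, raw = raw, bands = bands, p0 = p0,
      nScales = nS, binStart = x@binStart, binWidth = x@binWidth,
      onset = x@onset, offset = x@offset, edgeBin = x@edgeBin)
}

#' Pool scaled band power across trials
#'
#' Band-wise mean of the scaled power over a named window (`"during"` the
#' stimulus or `"after"` it, one stimulus length past offset), averaged
#' within trial first and then across trials, with a seeded nonparametric
#' bootstrap interval over trials.
#'
#' @param matrices list of [BandPowerMatrix-class] (>= 2 trials), matching
#'   band layouts.
#' @param window `"during"` or `"after"`.
#' @param merge optional `groups` argument of [mergeBands()] applied to
#'   every trial first.
#' @param n_boot bootstrap resamples.
#' @param seed bootstrap seed.
#' @return data.frame: `band`, `mean`, `lower`, `upper`, `n_trials`.
#' @export
poolBandPower <- function(matrices, window = c("during", "after"),
                          merge = NULL, n_boot = 2000L, seed = 1L) {
  window <- match.arg(window)
  if (length(matrices) < 2L) stop("need at least 2 trials")
  if (!is.null(merge)) matrices <- lapply(matrices, mergeBands, groups = merge)
  perTrial <- vapply(matrices, function(m) {
    dur <- m@offset - m@onset
    from <- if (window == "during") m@onset else m@offset
    to <- if (window == "during") m@offset else m@offset + dur
    sel <- m@binStart >= from - 1e-9 & m@binStart + m@binWidth <= to + 1e-9
    if (!any(sel)) stop("window lies outside the trial's time bins")
    colMeans(m@scaled[sel, , drop = FALSE])
  }, numeric(nrow(matrices[[1]]@bands)))
  perTrial <- matrix(perTrial, nrow = nrow(matrices[[1]]@bands))
  labs <- bandLabels(matrices[[1]])
  out <- lapply(seq_len(nrow(perTrial)), function(k) {
    ci <- bootstrapMean(perTrial[k, ], n_boot = n_boot,
                        seed = seed + k - 1L)
    data.frame(band = labs[k], mean = ci["mean"], lower = ci["lower"],
               upper = ci["upper"], n_trials = sum(!is.na(perTrial[k, ])))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
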