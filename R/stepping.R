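## Walking behaviour from tracked tarsi: step detection as peaks in the
## forward (y) coordinate, the mean normalized instantaneous stepping rate
## of the four reliably tracked front/middle legs (L1, L2, R1, R2), and the
## pairwise leg-speed correlation matrix.

STEPPING_LEGS <- c("L1", "L2", "R1", "R2")

#' Detect single steps of one leg
#'
#' Steps are local maxima of the tarsus forward (y) coordinate passing a
#' prominence threshold and a minimum separation — each forward swing leaves
#' one peak. Detection is invariant to uniform translation and positive
#' scaling of y only insofar as the prominence threshold is in the data's
#' units (default 0.5 mm, consistent with slow walking at about 2 Hz).
#'
#' @param tarsus_y per-frame y coordinate of one tarsus (mm; NA = invalid).
#' @param frame_rate frames per second.
#' @param min_prominence_mm minimum peak prominence (mm).
#' @param min_separation_s minimum time between steps (s).
#' @return numeric vector of step times (s), possibly empty.
#' @export
detectSteps <- function(tarsus_y, frame_rate, min_prominence_mm = 0.5,
                        min_separation_s = 0.15) {
  if (sum(!is.na(tarsus_y)) < 3L) stop("need at least 3 valid frames")
  idx <- findPeaks(tarsus_y, min_prominence = min_prominence_mm,
                   min_separation = min_separation_s * frame_rate)
  (idx - 1) / frame_rate
}

#' Normalized mean stepping rate of the front and middle legs
#'
#' Per leg, the instantaneous rate at a frame is the reciprocal of the
#' inter-step interval enclosing it (zero-order hold); intervals longer than
#' `pause_s` read as 0 so pauses count as non-walking, and frames outside
#' the first/last step are NA. Each leg's rate is normalized by its
#' within-trial mean (or maximum, with `norm = "max"`), and the final series
#' is the per-frame mean of the four normalized legs; a leg with fewer than
#' 2 steps contributes only missing values and is excluded from the mean.
#'
#' @param steps named list of step-time vectors for (at least) legs
#'   `L1, L2, R1, R2`.
#' @param n_frames frames in the trial.
#' @param frame_rate frames per second.
#' @param pause_s gap after which the rate reads 0 (s).
#' @param norm `"mean"` or `"max"` within-trial normalization.
#' @return a [StepSeries-class].
#' @export
steppingRate <- function(steps, n_frames, frame_rate, pause_s = 2,
                         norm = c("mean", "max")) {
  norm <- match.arg(norm)
  legs <- intersect(STEPPING_LEGS, names(steps))
  t <- (seq_len(n_frames) - 1) / frame_rate
  rate <- matrix(NA_real_, n_frames, length(legs),
                 dimnames = list(NULL, legs))
  for (leg in legs) {
    st <- sort(steps[[leg]])
    if (length(st) < 2L) next
    iv <- diff(st)
    r <- ifelse(iv > pause_s, 0, 1 / iv)
    seg <- findInterval(t, st)           # 0 before first step
    inside <- seg >= 1L & seg < length(st)
    rate[inside, leg] <- r[seg[inside]]
  }
  nrm <- rate
  for (leg in legs) {
    m <- if (norm == "mean") mean(rate[, leg], na.rm = TRUE)
         else max(rate[, leg], na.rm = TRUE)
    nrm[, leg] <- if (is.finite(m) && m > 0) rate[, leg] / m else NA_real_
  }
  meanRate <- rowMeans(nrm, na.rm = TRUE)
  meanRate[is.nan(meanRate)] <- NA_real_
  new("StepSeries", stepTimes = steps, rate = rate, meanRate = meanRate,
      frameRate = frame_rate)
}

#' Pairwise leg-speed correlation matrix
#'
#' Pearson correlations of the frame-to-frame 3-D speed magnitudes of all
#' six legs, pooled over valid common frames. The matrix is symmetric with
#' unit diagonal; a leg with constant speed (or too few valid frames) gets
#' NA in its row and column. Under a double-tripod gait, within-tripod
#' pairs (L1-R2-L3 / R1-L2-R3) correlate more strongly than cross-tripod
#' pairs.
#'
#' @param x a [Trial-class] with all six leg points.
#' @return 6 x 6 named numeric matrix.
#' @export
legSpeedCorrelations <- function(x) {
  legs <- intersect(LEG_LABELS, pointLabels(x))
  if (length(legs) < 6L)
    stop("all six legs must be tracked; missing: ",
         paste(setdiff(LEG_LABELS, legs), collapse = ", "))
  fr <- frameRate(x)
  speed <- vapply(LEG_LABELS, function(leg) {
    p <- trackedPoint(x, leg)
    d <- diff(p$xyz)
    s <- c(NA_real_, sqrt(rowSums(d^2)) * fr)
    s[!p$valid] <- NA_real_
    s
  }, numeric(nFrames(x)))
  if (sum(stats::complete.cases(speed)) < 3L)
    stop("need at least 3 common valid frames across all legs")
  sds <- apply(speed, 2, stats::sd, na.rm = TRUE)
  cc <- suppressWarnings(stats::cor(speed, use = "pairwise.complete.obs"))
  cc[sds == 0 | is.na(sds), ] <- NA_real_
  cc[, sds == 0 | is.na(sds)] <- NA_real_
  diag(cc) <- ifelse(sds > 0 & !is.na(sds), 1, NA_real_)
  cc[order(match(rownames(cc), LEG_LABELS)),
     order(match(colnames(cc), LEG_LABELS))]
}
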