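## Two-shelter arena valence assay: shelter occupancy times and the
## preference index PI = (time_odour - time_control) / time_total.

#' Shelter occupancy times of an arena track
#'
#' Time spent inside each shelter zone (tracked centroid inside the zone
#' disc), as frame counts times the frame interval; the total is the
#' session duration. Zones must be disjoint (enforced by the
#' [ArenaTrack-class] validity).
#'
#' @param x an [ArenaTrack-class].
#' @return named numeric: `time_odour`, `time_control`, `time_total`
#'   (seconds).
#' @export
occupancyTimes <- function(x) {
  if (!length(x@x)) stop("track has no frames")
  dt <- if (length(x@time_s) > 1) stats::median(diff(x@time_s))
        else x@duration
  inZone <- function(z) (x@x - z[1])^2 + (x@y - z[2])^2 <= z[3]^2
  c(time_odour = sum(inZone(x@zones$odour)) * dt,
    time_control = sum(inZone(x@zones$control)) * dt,
    time_total = x@duration)
}

#' Preference index
#'
#' `PI = (time_odour - time_control) / time_total`: +1 is full attraction
#' (all time at the odourised shelter), -1 full avoidance, 0 indifference.
#' Swapping the zones negates PI exactly, and PI is invariant to uniform
#' time rescaling.
#'
#' @param time_odour,time_control,time_total occupancy times (s);
#'   `time_total` must be positive and at least the sum of the zone times.
#' @return PI in [-1, 1].
#' @examples
#' preferenceIndex(540, 180, 1800)  # 0.2
#' @export
preferenceIndex <- function(time_odour, time_control, time_total) {
  if (time_total <= 0) stop("time_total must be positive")
  if (time_odour < 0 || time_control < 0)
    stop("occupancy times must be nonnegative")
  if (time_odour + time_control > time_total + 1e-9)
    stop("zone times exceed the total time")
  (time_odour - time_control) / time_total
}

#' Preference summary of one or more arena sessions
#'
#' Per-session occupancy times and PI, plus a seeded bootstrap interval on
#' the group mean PI (the desk equivalent of the assay's
#' certainty-versus-zero test).
#'
#' @param tracks an [ArenaTrack-class] or list of them.
#' @param n_boot bootstrap resamples over animals.
#' @param seed bootstrap seed.
#' @return list: `sessions` (data.frame with times and `pi` per session)
#'   and `group` (named numeric mean/lower/upper, NA interval for a single
#'   session).
#' @export
preferenceSummary <- function(tracks, n_boot = 2000L, seed = 1L) {
  if (!is.list(tracks)) tracks <- list(tracks)
  sessions <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    ti <- occupancyTimes(tracks[[i]])
    data.frame(session = i, time_odour = ti["time_odour"],
               time_control = ti["time_control"],
               time_total = ti["time_total"],
               pi = preferenceIndex(ti["time_odour"], ti["time_control"],
                                    ti["time_total"]))
  }))
  rownames(sessions) <- NULL
  group <- if (nrow(sessions) > 1)
    bootstrapMean(sessions$pi, n_boot = n_boot, seed = seed)
  else c(mean = sessions$pi, lower = NA_real_, upper = NA_real_)
  list(sessions = sessions, group = group)
}
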