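#' @import methods
NULL

#' Number of frames in a tracked object
#' @param x object holding per-frame data.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Frame rate accessor
#' @param x object holding per-frame data.
#' @return frames per second.
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' Trial identifier accessor
#' @param x a [Trial-class] or derived object.
#' @return character id.
#' @export
setGeneric("trialId", function(x) standardGeneric("trialId"))

#' Stimulus protocol accessor
#' @param x a [Trial-class].
#' @return a [StimulusProtocol-class].
#' @export
setGeneric("protocol", function(x) standardGeneric("protocol"))

#' Labels of the tracked points of a trial
#' @param x a [Trial-class].
#' @return character vector of point labels.
#' @export
setGeneric("pointLabels", function(x) standardGeneric("pointLabels"))

#' Coordinates of one tracked point
#' @param x a [Trial-class].
#' @param label point label, e.g. `"head"`, `"ant_L"`, `"L1"`.
#' @return list with `xyz` (n x 3 matrix, mm) and `valid` (logical).
#' @export
setGeneric("trackedPoint", function(x, label) standardGeneric("trackedPoint"))

#' Lateral stream-centre position at given times
#' @param x a [StimulusProtocol-class].
#' @param t numeric vector of times in seconds.
#' @return numeric vector of lateral positions (mm, tunnel frame).
#' @export
setGeneric("streamX", function(x, t) standardGeneric("streamX"))

#' Azimuth angles accessor
#' @param x an [AngleSeries-class].
#' @return n x 2 matrix (columns `L`, `R`), degrees.
#' @export
setGeneric("azimuth", function(x) standardGeneric("azimuth"))

#' Elevation angles accessor
#' @param x an [AngleSeries-class].
#' @return n x 2 matrix (columns `L`, `R`), degrees.
#' @export
setGeneric("elevation", function(x) standardGeneric("elevation"))

#' Combined angular speed accessor
#' @param x a [SpeedSeries-class].
#' @return n x 2 matrix of combined angular speeds, deg/s.
#' @export
setGeneric("combinedSpeed", function(x) standardGeneric("combinedSpeed"))

#' Per-frame values of a change series
#' @param x a [ChangeSeries-class].
#' @return numeric vector of per-frame changes.
#' @export
setGeneric("changeValues", function(x) standardGeneric("changeValues"))

#' Window means of a change series
#' @param x a [ChangeSeries-class].
#' @return named numeric (`pre`, `odour`, `post`).
#' @export
setGeneric("windowMeans", function(x) standardGeneric("windowMeans"))

#' Baseline-scaled wavelet band power accessor
#' @param x a [BandPowerMatrix-class].
#' @return time-bin x band matrix of (P_t - P0)/P0 values.
#' @export
setGeneric("scaledPower", function(x) standardGeneric("scaledPower"))

#' Frequency band labels accessor
#' @param x a [BandPowerMatrix-class].
#' @return character vector like `"[3,5)"`.
#' @export
setGeneric("bandLabels", function(x) standardGeneric("bandLabels"))
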