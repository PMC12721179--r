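#' @import methods
NULL

KIN_COLUMNS <- c("frame",
                 "nose_x", "nose_y", "tail_x", "tail_y",
                 "lf_x", "lf_y", "rf_x", "rf_y",
                 "lr_x", "lr_y", "rr_x", "rr_y")

LIMBS <- c("LF", "RF", "LR", "RR")
REGIONS <- c("M1", "mPFC", "DMS", "DLS")

#' SpikeTrain: one sorted single unit
#'
#' Spike times of one unit together with its anatomical metadata. The region
#' label is restricted to the four recorded areas: primary motor cortex (M1),
#' medial prefrontal cortex (mPFC), and dorsomedial/dorsolateral striatum
#' (DMS/DLS). An optional free-text sublabel carries layer or subregion
#' assignments produced upstream (atlas mapping is not performed here).
#'
#' @slot unitId character unit identifier.
#' @slot region one of \code{"M1"}, \code{"mPFC"}, \code{"DMS"}, \code{"DLS"}.
#' @slot sublabel optional subregion/layer label (\code{NA} if absent).
#' @slot spikeTimes numeric vector of spike times in seconds, sorted
#'   ascending, non-negative.
#' @export
setClass("SpikeTrain",
  representation(unitId = "character", region = "character",
                 sublabel = "character", spikeTimes = "numeric"),
  prototype(sublabel = NA_character_, spikeTimes = numeric(0)))

setValidity("SpikeTrain", function(object) {
  msg <- character(0)
  if (length(object@unitId) != 1L || !nzchar(object@unitId))
    msg <- c(msg, "unitId must be a single non-empty string")
  if (length(object@region) != 1L || !(object@region %in% REGIONS))
    msg <- c(msg, sprintf("region must be one of %s",
                          paste(REGIONS, collapse = ", ")))
  st <- object@spikeTimes
  if (length(st) && (is.unsorted(st) || any(st < 0) || any(!is.finite(st))))
    msg <- c(msg, sprintf(
      "spike times of unit '%s' must be finite, non-negative and sorted",
      object@unitId))
  if (length(msg)) msg else TRUE
})

#' Construct a SpikeTrain
#'
#' @param unitId unit identifier.
#' @param spikeTimes spike times in seconds (sorted ascending).
#' @param region region label (M1, mPFC, DMS or DLS).
#' @param sublabel optional subregion/layer label.
#' @return A \linkS4class{SpikeTrain}.
#' @export
SpikeTrain <- function(unitId, spikeTimes, region, sublabel = NA_character_) {
  new("SpikeTrain", unitId = as.character(unitId),
      region = as.character(region),
      sublabel = as.character(sublabel),
      spikeTimes = as.numeric(spikeTimes))
}

#' GaitSession: one recording session
#'
#' Bundles per-frame kinematics (six tracked features at the video frame
#' rate: nose, tail base, and the four limbs, in mm), the session's single
#' units, and the session clock. An optional \code{groundTruth} list carries
#' generator-side truth (bout onsets, per-limb phase, body speed) for
#' synthetic sessions; it is ignored by all analysis code paths.
#'
#' @slot sessionId character session identifier.
#' @slot frameRate video frame rate in Hz (80 by default).
#' @slot kinematics data.frame with columns \code{frame, nose_x, nose_y,
#'   tail_x, tail_y, lf_x, lf_y, rf_x, rf_y, lr_x, lr_y, rr_x, rr_y};
#'   coordinates in mm, frames 0-based, strictly increasing and gapless.
#' @slot units list of \linkS4class{SpikeTrain}.
#' @slot duration session duration in seconds.
#' @slot groundTruth list (possibly empty) of generator ground truth.
#' @export
setClass("GaitSession",
  representation(sessionId = "character", frameRate = "numeric",
                 kinematics = "data.frame", units = "list",
                 duration = "numeric", groundTruth = "list"),
  prototype(frameRate = 80, groundTruth = list()))

setValidity("GaitSession", function(object) {
  msg <- character(0)
  kin <- object@kinematics
  if (!all(KIN_COLUMNS %in% names(kin)))
    msg <- c(msg, sprintf("kinematics is missing column(s): %s",
                          paste(setdiff(KIN_COLUMNS, names(kin)),
                                collapse = ", ")))
  else {
    fr <- kin$frame
    if (length(fr) && (fr[1L] != 0L || any(diff(fr) != 1)))
      msg <- c(msg, "frame indices must be 0-based, strictly increasing and gapless")
    if (!all(vapply(kin[KIN_COLUMNS], function(v) all(is.finite(v)), logical(1))))
      msg <- c(msg, "all kinematic coordinates must be finite")
  }
  if (length(object@duration) != 1L || !is.finite(object@duration) ||
      object@duration < 1)
    msg <- c(msg, "duration must be a single finite value >= 1 s")
  for (u in object@units) {
    if (!is(u, "SpikeTrain")) { msg <- c(msg, "units must contain SpikeTrain objects"); break }
    v <- validObject(u, test = TRUE)
    if (is.character(v)) msg <- c(msg, v)
    else if (length(u@spikeTimes) && max(u@spikeTimes) > object@duration)
      msg <- c(msg, sprintf("unit '%s' has spikes after session end (%.3f s)",
                            u@unitId, object@duration))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GaitSession
#'
#' @param sessionId session identifier.
#' @param kinematics per-frame coordinate table (see class docs for columns).
#' @param units list of \linkS4class{SpikeTrain} objects.
#' @param frameRate video frame rate in Hz.
#' @param duration session duration in seconds; defaults to the span of the
#'   frame clock.
#' @param groundTruth optional generator ground-truth list.
#' @return A validated \linkS4class{GaitSession}.
#' @export
GaitSession <- function(sessionId, kinematics, units = list(), frameRate = 80,
                        duration = nrow(kinematics) / frameRate,
                        groundTruth = list()) {
  new("GaitSession", sessionId = as.character(sessionId),
      frameRate = as.numeric(frameRate),
      kinematics = as.data.frame(kinematics), units = units,
      duration = as.numeric(duration), groundTruth = groundTruth)
}

#' TrialTensor: decoder-ready pseudo-population activity
#'
#' A trials x units x classes array of firing rates (Hz). Element
#' \code{[t, u, k]} is the rate of unit \code{u} on the \code{t}-th sampled
#' trial of class \code{k}. For the time task a trial is a walking bout and
#' the classes are the 15 non-overlapping 0.2 s bins tiling -1.5..+1.5 s
#' around onset; for the speed task the classes are the four 50 mm/s speed
#' ranges (50-250 mm/s); for the phase task the twelve 30 degree gait-phase
#' bins.
#'
#' @slot task one of \code{"time"}, \code{"speed"}, \code{"phase"}.
#' @slot rates numeric array trials x units x classes, all >= 0.
#' @slot classValues physical class centres (s, mm/s, or degrees).
#' @slot unitIds character vector of pooled unit identifiers.
#' @slot sessionIds per-unit session of origin.
#' @export
setClass("TrialTensor",
  representation(task = "character", rates = "array",
                 classValues = "numeric", unitIds = "character",
                 sessionIds = "character"))

setValidity("TrialTensor", function(object) {
  msg <- character(0)
  if (!(object@task %in% c("time", "speed", "phase")))
    msg <- c(msg, "task must be 'time', 'speed' or 'phase'")
  d <- dim(object@rates)
  if (length(d) != 3L) msg <- c(msg, "rates must be a 3-d array")
  else {
    if (d[3L] != length(object@classValues))
      msg <- c(msg, "third dimension must match classValues")
    if (d[2L] != length(object@unitIds))
      msg <- c(msg, "second dimension must match unitIds")
    expected <- c(time = 15L, speed = 4L, phase = 12L)[object@task]
    if (!is.na(expected) && d[3L] != expected)
      msg <- c(msg, sprintf("%s task requires %d classes, got %d",
                            object@task, expected, d[3L]))
  }
  if (any(object@rates < 0)) msg <- c(msg, "rates must be non-negative")
  if (length(msg)) msg else TRUE
})

#' DecodingResult: aggregated decoder performance
#'
#' @slot task decoded variable (\code{"time"}, \code{"speed"}, \code{"phase"}).
#' @slot confusion row-normalised confusion matrix (actual x predicted).
#' @slot classAccuracy per-class accuracy (diagonal of \code{confusion}).
#' @slot overallAccuracy mean of the per-class accuracies.
#' @slot errorMetric RMSE in physical units (time/speed) or mean absolute
#'   angular error in degrees (phase).
#' @slot errorMetricBins RMSE expressed in bin counts (NA for phase).
#' @slot drawAccuracy per-draw overall accuracies.
#' @slot drawClassAccuracy draws x classes accuracy matrix.
#' @slot shuffleBand 2 x classes matrix of shuffle-null 2.5/97.5 percentiles,
#'   or a 0-row matrix when no shuffle control was run.
#' @slot classValues physical class centres.
#' @slot nUnits units per draw.
#' @export
setClass("DecodingResult",
  representation(task = "character", confusion = "matrix",
                 classAccuracy = "numeric", overallAccuracy = "numeric",
                 errorMetric = "numeric", errorMetricBins = "numeric",
                 drawAccuracy = "numeric", drawClassAccuracy = "matrix",
                 shuffleBand = "matrix", classValues = "numeric",
                 nUnits = "integer"))

setValidity("DecodingResult", function(object) {
  msg <- character(0)
  rs <- rowSums(object@confusion)
  if (any(abs(rs[rs > 0] - 1) > 1e-9))
    msg <- c(msg, "confusion rows must sum to 1")
  if (any(object@classAccuracy < -1e-12 | object@classAccuracy > 1 + 1e-12))
    msg <- c(msg, "accuracies must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

# ---- accessors & show ------------------------------------------------------

#' @describeIn GaitSession-class number of units in the session
#' @param object,x a \code{GaitSession}
#' @export
setMethod("length", "GaitSession", function(x) length(x@units))

#' Accessors for package classes
#'
#' \code{sessionId}, \code{frameRate}, \code{kinematics}, \code{units},
#' \code{duration} extract the corresponding \linkS4class{GaitSession}
#' slots; \code{spikeTimes}, \code{unitId}, \code{region} the
#' \linkS4class{SpikeTrain} slots; \code{confusionMatrix},
#' \code{overallAccuracy}, \code{classAccuracy}, \code{drawAccuracy},
#' \code{errorMetric}, \code{shuffleBand} the \linkS4class{DecodingResult}
#' slots.
#'
#' @param object an object of the documented class.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sessionId", function(object) standardGeneric("sessionId"))
#' @rdname accessors
#' @export
setMethod("sessionId", "GaitSession", function(object) object@sessionId)

#' @rdname accessors
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setMethod("frameRate", "GaitSession", function(object) object@frameRate)

#' @rdname accessors
#' @export
setGeneric("kinematics", function(object) standardGeneric("kinematics"))
#' @rdname accessors
#' @export
setMethod("kinematics", "GaitSession", function(object) object@kinematics)

#' @rdname accessors
#' @export
setGeneric("units", function(object) standardGeneric("units"))
#' @rdname accessors
#' @export
setMethod("units", "GaitSession", function(object) object@units)

#' @rdname accessors
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))
#' @rdname accessors
#' @export
setMethod("duration", "GaitSession", function(object) object@duration)

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setMethod("groundTruth", "GaitSession", function(object) object@groundTruth)

#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(object) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setMethod("spikeTimes", "SpikeTrain", function(object) object@spikeTimes)

#' @rdname accessors
#' @export
setGeneric("unitId", function(object) standardGeneric("unitId"))
#' @rdname accessors
#' @export
setMethod("unitId", "SpikeTrain", function(object) object@unitId)

#' @rdname accessors
#' @export
setGeneric("region", function(object) standardGeneric("region"))
#' @rdname accessors
#' @export
setMethod("region", "SpikeTrain", function(object) object@region)

#' @rdname accessors
#' @export
setGeneric("confusionMatrix", function(object) standardGeneric("confusionMatrix"))
#' @rdname accessors
#' @export
setMethod("confusionMatrix", "DecodingResult", function(object) object@confusion)

#' @rdname accessors
#' @export
setGeneric("overallAccuracy", function(object) standardGeneric("overallAccuracy"))
#' @rdname accessors
#' @export
setMethod("overallAccuracy", "DecodingResult", function(object) object@overallAccuracy)

#' @rdname accessors
#' @export
setGeneric("classAccuracy", function(object) standardGeneric("classAccuracy"))
#' @rdname accessors
#' @export
setMethod("classAccuracy", "DecodingResult", function(object) object@classAccuracy)

#' @rdname accessors
#' @export
setGeneric("drawAccuracy", function(object) standardGeneric("drawAccuracy"))
#' @rdname accessors
#' @export
setMethod("drawAccuracy", "DecodingResult", function(object) object@drawAccuracy)

#' @rdname accessors
#' @export
setGeneric("errorMetric", function(object) standardGeneric("errorMetric"))
#' @rdname accessors
#' @export
setMethod("errorMetric", "DecodingResult", function(object) object@errorMetric)

#' @rdname accessors
#' @export
setGeneric("shuffleBand", function(object) standardGeneric("shuffleBand"))
#' @rdname accessors
#' @export
setMethod("shuffleBand", "DecodingResult", function(object) object@shuffleBand)

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain '%s' [%s%s]: %d spikes\n", object@unitId,
              object@region,
              if (is.na(object@sublabel)) "" else paste0("/", object@sublabel),
              length(object@spikeTimes)))
})

setMethod("show", "GaitSession", function(object) {
  cat(sprintf("GaitSession '%s': %.1f s at %g fps, %d frames, %d units\n",
              object@sessionId, object@duration, object@frameRate,
              nrow(object@kinematics), length(object@units)))
  if (length(object@groundTruth))
    cat(sprintf("  ground truth: %s\n",
                paste(names(object@groundTruth), collapse = ", ")))
})

setMethod("show", "TrialTensor", function(object) {
  d <- dim(object@rates)
  cat(sprintf("TrialTensor (%s task): %d trials x %d units x %d classes\n",
              object@task, d[1L], d[2L], d[3L]))
})

setMethod("show", "DecodingResult", function(object) {
  cat(sprintf("DecodingResult (%s task, %d units/draw, %d draws)\n",
              object@task, object@nUnits, length(object@drawAccuracy)))
  cat(sprintf("  overall accuracy %.3f (chance %.3f); error metric %.3f %s\n",
              object@overallAccuracy, 1 / length(object@classValues),
              object@errorMetric,
              switch(object@task, time = "s RMSE", speed = "mm/s RMSE",
                     phase = "deg MAE")))
})
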