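#' @import methods
NULL

#' The 17 posterior electrode labels used for color decoding
#'
#' Standard 10-20 labels of the parieto-occipital electrodes over visual
#' cortex to which all multivariate analyses are restricted.
#'
#' @return character vector of 17 channel names.
#' @export
posteriorChannels <- function() {
  c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2")
}

.EVENTS <- c("item1", "item2", "cue", "impulse")

#' EpochSet: epoched multichannel EEG for one event type
#'
#' Container for a trials x channels x time numeric array, time-locked to one
#' event (`item1`, `item2`, `cue` or `impulse`), with its channel names,
#' sampling rate, and time axis in milliseconds relative to event onset.
#' `trialIds` align the rows to a trial table.
#'
#' @slot data numeric array, trials x channels x time.
#' @slot channelNames character, unique channel labels.
#' @slot fs sampling rate in Hz.
#' @slot timesMs numeric time axis, strictly increasing, uniform at `1000/fs`.
#' @slot event one of `"item1"`, `"item2"`, `"cue"`, `"impulse"`.
#' @slot trialIds integer trial identifiers, one per row of `data`.
#'
#' @export
setClass("EpochSet",
  representation(
    data = "array",
    channelNames = "character",
    fs = "numeric",
    timesMs = "numeric",
    event = "character",
    trialIds = "integer"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a 3-d array (trials x channels x time)")
  else {
    if (d[2] != length(object@channelNames))
      msg <- c(msg, "channel dimension does not match channelNames")
    if (d[3] != length(object@timesMs))
      msg <- c(msg, "time dimension does not match timesMs")
    if (d[1] != length(object@trialIds))
      msg <- c(msg, "trial dimension does not match trialIds")
  }
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channelNames must be unique")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@timesMs) > 1L) {
    steps <- diff(object@timesMs)
    if (any(steps <= 0))
      msg <- c(msg, "timesMs must be strictly increasing")
    else if (any(abs(steps - 1000 / object@fs) > 1e-6))
      msg <- c(msg, "timesMs must be uniform at 1000/fs")
  }
  if (length(object@event) != 1L || !(object@event %in% .EVENTS))
    msg <- c(msg, sprintf("event must be one of: %s",
                          paste(.EVENTS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an EpochSet
#'
#' @param data trials x channels x time numeric array.
#' @param channelNames character vector of channel labels.
#' @param fs sampling rate (Hz).
#' @param timesMs time axis in ms relative to event onset.
#' @param event event label (`"item1"`, `"item2"`, `"cue"`, `"impulse"`).
#' @param trialIds integer ids aligning trials to a trial table; defaults to
#'   `seq_len(nrow)`.
#' @return an [EpochSet-class] object.
#' @export
EpochSet <- function(data, channelNames, fs, timesMs, event,
                     trialIds = seq_len(dim(data)[1])) {
  new("EpochSet", data = data, channelNames = as.character(channelNames),
      fs = as.numeric(fs), timesMs = as.numeric(timesMs),
      event = as.character(event), trialIds = as.integer(trialIds))
}

#' @describeIn EpochSet-class the trials x channels x time array.
#' @param object,x an `EpochSet`.
#' @export
setGeneric("epochData", function(object) standardGeneric("epochData"))
#' @rdname EpochSet-class
#' @export
setMethod("epochData", "EpochSet", function(object) object@data)

#' @describeIn EpochSet-class channel labels.
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname EpochSet-class
#' @export
setMethod("channelNames", "EpochSet", function(object) object@channelNames)

#' @describeIn EpochSet-class sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname EpochSet-class
#' @export
setMethod("samplingRate", "EpochSet", function(object) object@fs)

#' @describeIn EpochSet-class time axis in ms.
#' @export
setGeneric("timesMs", function(object) standardGeneric("timesMs"))
#' @rdname EpochSet-class
#' @export
setMethod("timesMs", "EpochSet", function(object) object@timesMs)

#' @describeIn EpochSet-class event label.
#' @export
setGeneric("eventLabel", function(object) standardGeneric("eventLabel"))
#' @rdname EpochSet-class
#' @export
setMethod("eventLabel", "EpochSet", function(object) object@event)

#' @describeIn EpochSet-class trial identifiers.
#' @export
setGeneric("trialIds", function(object) standardGeneric("trialIds"))
#' @rdname EpochSet-class
#' @export
setMethod("trialIds", "EpochSet", function(object) object@trialIds)

#' @describeIn EpochSet-class number of trials.
#' @export
setMethod("nrow", "EpochSet", function(x) dim(x@data)[1])

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "EpochSet [%s]: %d trials x %d channels x %d samples @ %g Hz (%g..%g ms)\n",
    object@event, d[1], d[2], d[3], object@fs,
    min(object@timesMs), max(object@timesMs)))
})

#' SimConfig: parameters of the synthetic retro-cue experiment
#'
#' Holds every parameter of the forward model that generates trial tables,
#' epoched signals and behavioral reports. Defaults reproduce the study
#' conditions: 30 participants, 1536 trials, 17 posterior channels at 500 Hz,
#' 48 equidistant wheel colors.
#'
#' @slot nParticipants,nTrials counts.
#' @slot channelNames simulated channel labels.
#' @slot fs sampling rate (Hz); must exceed twice the alpha band's upper edge.
#' @slot epochWindows named list of `c(start_ms, end_ms)` per event.
#' @slot nWheelColors number of equidistant wheel colors (divides 360).
#' @slot tuningWidthDeg FWHM-like width (degrees) of channel color tuning.
#' @slot snrItem evoked amplitude of a memory item at its own presentation.
#' @slot snrCuedImpulse,snrUncuedImpulse evoked amplitudes at impulse.
#' @slot alphaAmpCued,alphaAmpUncued 8-12 Hz carrier amplitudes from cue onward.
#' @slot noiseSd additive Gaussian noise SD.
#' @slot spatialCorr 0..1 decay of the Toeplitz channel-noise correlation.
#' @slot reportKappa von Mises concentration of report noise.
#' @slot repulsionAmpDeg amplitude (degrees) of repulsion from the uncued color.
#' @slot primaryAttractionDeg amplitude (degrees) of pull toward primaries.
#' @slot primariesDeg the three primary hue angles.
#' @slot seed base seed.
#' @export
setClass("SimConfig",
  representation(
    nParticipants = "integer", nTrials = "integer",
    channelNames = "character", fs = "numeric",
    epochWindows = "list", nWheelColors = "integer",
    tuningWidthDeg = "numeric",
    snrItem = "numeric", snrCuedImpulse = "numeric",
    snrUncuedImpulse = "numeric",
    alphaAmpCued = "numeric", alphaAmpUncued = "numeric",
    noiseSd = "numeric", spatialCorr = "numeric",
    reportKappa = "numeric", repulsionAmpDeg = "numeric",
    primaryAttractionDeg = "numeric", primariesDeg = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nParticipants < 1L) msg <- c(msg, "nParticipants must be >= 1")
  if (object@nTrials < 2L) msg <- c(msg, "nTrials must be >= 2")
  if (object@nWheelColors < 2L)
    msg <- c(msg, "nWheelColors must be >= 2 (equal steps of 360/n degrees)")
  amps <- c(object@snrItem, object@snrCuedImpulse, object@snrUncuedImpulse,
            object@alphaAmpCued, object@alphaAmpUncued, object@noiseSd)
  if (any(amps < 0)) msg <- c(msg, "all amplitudes must be >= 0")
  if (object@fs <= 24) msg <- c(msg, "fs must exceed 2 x 12 Hz")
  if (object@spatialCorr < 0 || object@spatialCorr >= 1)
    msg <- c(msg, "spatialCorr must be in [0, 1)")
  if (!all(.EVENTS %in% names(object@epochWindows)))
    msg <- c(msg, "epochWindows must name all of item1, item2, cue, impulse")
  else {
    for (ev in .EVENTS) {
      w <- object@epochWindows[[ev]]
      if (length(w) != 2L || !(w[1] <= 0 && 0 <= w[2]))
        msg <- c(msg, sprintf("epoch window '%s' must satisfy start <= 0 <= end", ev))
    }
  }
  if (length(object@primariesDeg) != 3L)
    msg <- c(msg, "primariesDeg must contain exactly 3 angles")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' Defaults match the study conditions of the emulated retro-cue experiment:
#' 30 participants completing 1536 trials; 17 posterior channels sampled at
#' 500 Hz; epochs from -150 ms to the onset of the next stimulus (1100 ms for
#' item1/item2/cue, 600 ms for the impulse); 48 equidistant wheel colors.
#' Signal amplitudes follow the qualitative ordering the experiment reports:
#' strong stimulus-evoked coding, cued > uncued evoked coding at impulse, and
#' a sustained alpha carrier for the cued item only.
#'
#' @param nParticipants,nTrials cohort and per-participant trial counts.
#' @param channelNames simulated channels (default the 17 posterior labels).
#' @param fs sampling rate in Hz.
#' @param epochWindows named list of `c(start, end)` ms windows per event.
#' @param nWheelColors number of equidistant wheel colors.
#' @param tuningWidthDeg width (degrees) of the simulated channel color tuning.
#' @param snrItem evoked amplitude at item presentation.
#' @param snrCuedImpulse,snrUncuedImpulse evoked amplitudes at impulse.
#' @param alphaAmpCued,alphaAmpUncued alpha carrier amplitudes from cue onward.
#' @param noiseSd additive noise SD.
#' @param spatialCorr channel-noise correlation decay in [0, 1).
#' @param reportKappa von Mises concentration of report noise.
#' @param repulsionAmpDeg repulsion amplitude away from the uncued color (deg).
#' @param primaryAttractionDeg pull toward the nearest primary hue (deg).
#' @param primariesDeg the three primary hue angles (deg).
#' @param seed base random seed.
#' @return a validated [SimConfig-class] object.
#' @export
#' @examples
#' cfg <- simConfig(nParticipants = 2, nTrials = 64)
#' cfg
simConfig <- function(nParticipants = 30, nTrials = 1536,
                      channelNames = posteriorChannels(), fs = 500,
                      epochWindows = list(item1 = c(-150, 1100),
                                          item2 = c(-150, 1100),
                                          cue = c(-150, 1100),
                                          impulse = c(-150, 600)),
                      nWheelColors = 48, tuningWidthDeg = 60,
                      snrItem = 1.2, snrCuedImpulse = 0.8,
                      snrUncuedImpulse = 0.35,
                      alphaAmpCued = 0.8, alphaAmpUncued = 0,
                      noiseSd = 1, spatialCorr = 0.3,
                      reportKappa = 8, repulsionAmpDeg = 5,
                      primaryAttractionDeg = 8,
                      primariesDeg = c(30, 150, 270), seed = 1L) {
  new("SimConfig",
      nParticipants = as.integer(nParticipants), nTrials = as.integer(nTrials),
      channelNames = channelNames, fs = fs, epochWindows = epochWindows,
      nWheelColors = as.integer(nWheelColors),
      tuningWidthDeg = tuningWidthDeg, snrItem = snrItem,
      snrCuedImpulse = snrCuedImpulse, snrUncuedImpulse = snrUncuedImpulse,
      alphaAmpCued = alphaAmpCued, alphaAmpUncued = alphaAmpUncued,
      noiseSd = noiseSd, spatialCorr = spatialCorr,
      reportKappa = reportKappa, repulsionAmpDeg = repulsionAmpDeg,
      primaryAttractionDeg = primaryAttractionDeg,
      primariesDeg = primariesDeg, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d participants x %d trials, %d channels @ %g Hz, %d wheel colors\n",
    object@nParticipants, object@nTrials, length(object@channelNames),
    object@fs, object@nWheelColors))
  cat(sprintf("  evoked: item %.2f, impulse cued %.2f / uncued %.2f; alpha cued %.2f / uncued %.2f; noise %.2f\n",
              object@snrItem, object@snrCuedImpulse, object@snrUncuedImpulse,
              object@alphaAmpCued, object@alphaAmpUncued, object@noiseSd))
})

#' DecodingResult: window-of-interest decoding output for one participant
#'
#' Accuracy is in arbitrary units with chance level 0: the cosine-weighted,
#' mean-centered, sign-reversed Mahalanobis distance profile. The tuning curve
#' holds the 16 mean-centered sign-reversed distances ordered by signed
#' angular difference from the true color bin (-180 to +157.5 degrees).
#'
#' @slot accuracy mean accuracy over trials, repetitions and color spaces.
#' @slot trialAccuracy per-trial accuracies.
#' @slot tuningCurve named numeric of length 16, sums to 0.
#' @slot label which color was decoded (e.g. `"cued"`).
#' @slot nReps,nFolds cross-validation settings used.
#' @export
setClass("DecodingResult",
  representation(accuracy = "numeric", trialAccuracy = "numeric",
                 tuningCurve = "numeric", label = "character",
                 nReps = "integer", nFolds = "integer"))

setValidity("DecodingResult", function(object) {
  msg <- character()
  if (length(object@tuningCurve) != 16L)
    msg <- c(msg, "tuningCurve must have 16 entries")
  else {
    scale <- max(abs(object@tuningCurve), 1)
    if (abs(sum(object@tuningCurve)) > 1e-8 * scale * 16)
      msg <- c(msg, "tuningCurve must sum to 0 (mean-centered distances)")
  }
  if (abs(object@accuracy - mean(object@trialAccuracy)) >
      1e-8 * max(1, abs(object@accuracy)))
    msg <- c(msg, "accuracy must equal the mean of trialAccuracy")
  if (length(msg)) msg else TRUE
})

#' @describeIn DecodingResult-class mean decoding accuracy (A.U., chance 0).
#' @param object a `DecodingResult` or `TimecourseResult`.
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))
#' @rdname DecodingResult-class
#' @export
setMethod("accuracy", "DecodingResult", function(object) object@accuracy)

#' @describeIn DecodingResult-class per-trial accuracies.
#' @export
setGeneric("trialAccuracy", function(object) standardGeneric("trialAccuracy"))
#' @rdname DecodingResult-class
#' @export
setMethod("trialAccuracy", "DecodingResult", function(object) object@trialAccuracy)

#' @describeIn DecodingResult-class 16-point tuning curve ordered by signed
#'   angular distance from the true bin.
#' @export
setGeneric("tuningCurve", function(object) standardGeneric("tuningCurve"))
#' @rdname DecodingResult-class
#' @export
setMethod("tuningCurve", "DecodingResult", function(object) object@tuningCurve)

setMethod("show", "DecodingResult", function(object) {
  cat(sprintf("DecodingResult [%s]: accuracy %.4f A.U. over %d trials (%d folds x %d reps x 3 spaces)\n",
              object@label, object@accuracy, length(object@trialAccuracy),
              object@nFolds, object@nReps))
})

#' TimecourseResult: sliding-window decoding output for one participant
#'
#' @slot accuracy decoding accuracy per output time point (A.U., chance 0).
#' @slot similarity 16 x timepoints matrix of mean-centered sign-reversed
#'   distances ordered by angular difference; each column sums to 0.
#' @slot timesMs output time axis.
#' @slot label decoded color label.
#' @export
setClass("TimecourseResult",
  representation(accuracy = "numeric", similarity = "matrix",
                 timesMs = "numeric", label = "character"))

setValidity("TimecourseResult", function(object) {
  msg <- character()
  if (length(object@accuracy) != length(object@timesMs))
    msg <- c(msg, "accuracy and timesMs lengths differ")
  if (nrow(object@similarity) != 16L ||
      ncol(object@similarity) != length(object@timesMs))
    msg <- c(msg, "similarity must be 16 x length(timesMs)")
  else {
    scale <- max(abs(object@similarity), 1)
    if (max(abs(colSums(object@similarity))) > 1e-8 * scale * 16)
      msg <- c(msg, "similarity columns must sum to 0")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname TimecourseResult-class
#' @param object a `TimecourseResult`.
#' @export
setMethod("accuracy", "TimecourseResult", function(object) object@accuracy)
#' @rdname TimecourseResult-class
#' @export
setMethod("timesMs", "TimecourseResult", function(object) object@timesMs)

#' @describeIn TimecourseResult-class 16 x time pattern-similarity matrix.
#' @export
setGeneric("similarityMatrix",
           function(object) standardGeneric("similarityMatrix"))
#' @rdname TimecourseResult-class
#' @export
setMethod("similarityMatrix", "TimecourseResult",
          function(object) object@similarity)

setMethod("show", "TimecourseResult", function(object) {
  cat(sprintf("TimecourseResult [%s]: %d time points (%g..%g ms), peak accuracy %.4f A.U.\n",
              object@label, length(object@timesMs), min(object@timesMs),
              max(object@timesMs), max(object@accuracy)))
})

#' ColorRDM: representational dissimilarity matrix over 16 color bins
#'
#' Symmetric, zero-diagonal, non-negative 16 x 16 matrix of Mahalanobis
#' distances between bin-average spatio-temporal patterns, averaged over
#' subsampling repetitions.
#'
#' @slot values 16 x 16 dissimilarity matrix.
#' @slot centers bin center angles (degrees).
#' @slot nReps subsampling repetitions averaged.
#' @export
setClass("ColorRDM",
  representation(values = "matrix", centers = "numeric", nReps = "integer"))

setValidity("ColorRDM", function(object) {
  v <- object@values
  msg <- character()
  if (!all(dim(v) == c(16L, 16L))) msg <- c(msg, "values must be 16 x 16")
  else {
    if (max(abs(v - t(v))) > 1e-8 * max(abs(v), 1))
      msg <- c(msg, "values must be symmetric")
    if (any(diag(v) != 0)) msg <- c(msg, "diagonal must be zero")
    if (any(v < 0)) msg <- c(msg, "values must be non-negative")
  }
  if (length(object@centers) != 16L) msg <- c(msg, "centers must have 16 angles")
  if (length(msg)) msg else TRUE
})

#' @describeIn ColorRDM-class the 16 x 16 distance matrix.
#' @param object a `ColorRDM`.
#' @export
setGeneric("rdmValues", function(object) standardGeneric("rdmValues"))
#' @rdname ColorRDM-class
#' @export
setMethod("rdmValues", "ColorRDM", function(object) object@values)

setMethod("show", "ColorRDM", function(object) {
  cat(sprintf("ColorRDM: 16 x 16, mean off-diagonal distance %.4f (%d reps)\n",
              mean(object@values[row(object@values) != col(object@values)]),
              object@nReps))
})
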