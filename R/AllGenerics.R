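#' Accessors for rotadapt S4 containers
#'
#' Small accessor generics so downstream code never touches slots directly:
#' `channelNames()`, `samplingRate()`, `markers()`, `signalData()`,
#' `epochData()`, `tfPower()`, `accuracySeries()`.
#'
#' @param object an object of one of the rotadapt S4 classes.
#' @return The corresponding component (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("markers", function(object) standardGeneric("markers"))
#' @rdname accessors
#' @export
setGeneric("signalData", function(object) standardGeneric("signalData"))
#' @rdname accessors
#' @export
setGeneric("epochData", function(object) standardGeneric("epochData"))
#' @rdname accessors
#' @export
setGeneric("tfPower", function(object) standardGeneric("tfPower"))
#' @rdname accessors
#' @export
setGeneric("accuracySeries", function(object)
  standardGeneric("accuracySeries"))

#' @rdname accessors
#' @export
setMethod("channelNames", "EEGRecording", function(object) object@channels)
#' @rdname accessors
#' @export
setMethod("channelNames", "EEGEpochs", function(object) object@channels)
#' @rdname accessors
#' @export
setMethod("channelNames", "TimeFrequencyArray",
          function(object) object@channels)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGEpochs", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("markers", "EEGRecording", function(object) object@markers)
#' @rdname accessors
#' @export
setMethod("signalData", "EEGRecording", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("epochData", "EEGEpochs", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("tfPower", "TimeFrequencyArray", function(object) object@power)
#' @rdname accessors
#' @export
setMethod("accuracySeries", "DecodingResult",
          function(object) object@accuracy)

#' @describeIn EEGRecording-class compact summary
#' @param object an `EEGRecording`.
#' @export
setMethod("show", "EEGRecording", function(object) {
  cat(sprintf(
    "EEGRecording: subject %d, %s task\n  %d channels x %d samples @ %g Hz (%.1f s), %d markers\n",
    object@subject, object@task, nrow(object@data), ncol(object@data),
    object@fs, ncol(object@data) / object@fs, nrow(object@markers)))
})

#' @describeIn EEGEpochs-class compact summary
#' @param object an `EEGEpochs`.
#' @export
setMethod("show", "EEGEpochs", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "EEGEpochs: subject %d, %s task, aligned to '%s'\n  %d trials x %d channels x %d samples, window [%g, %g] s @ %g Hz\n",
    object@subject, object@task, object@alignment, d[1], d[2], d[3],
    object@window[1], object@window[2], object@fs))
})

#' @describeIn TimeFrequencyArray-class compact summary
#' @param object a `TimeFrequencyArray`.
#' @export
setMethod("show", "TimeFrequencyArray", function(object) {
  d <- dim(object@power)
  cat(sprintf(
    "TimeFrequencyArray (%s): subject %d, %s task, aligned to '%s'\n  %d trials x %d channels x %d freqs (%g-%g Hz) x %d bins (%g to %g s)\n  %d/%d (freq, bin) cells valid\n",
    object@unit, object@subject, object@task, object@alignment,
    d[1], d[2], d[3], min(object@freqs), max(object@freqs), d[4],
    min(object@times), max(object@times),
    sum(object@valid), length(object@valid)))
})

#' @describeIn StateSpaceFit-class compact summary
#' @param object a `StateSpaceFit`.
#' @export
setMethod("show", "StateSpaceFit", function(object) {
  cat(sprintf(
    "StateSpaceFit: A (retention) = %.4f, B (adaptation) = %.4f, R2 = %.4f\n  %d usable trial pairs%s\n",
    object@A, object@B, object@R2, object@nPairs,
    if (is.finite(object@intercept))
      sprintf(", intercept = %.4f", object@intercept) else ""))
})

#' @describeIn DecodingResult-class compact summary
#' @param object a `DecodingResult`.
#' @export
setMethod("show", "DecodingResult", function(object) {
  cat(sprintf(
    "DecodingResult: %d time bins (%g to %g s), %d permutations, %s correction\n  accuracy %.3f-%.3f, chance %.3f, threshold %.3f, %d significant bins\n",
    length(object@times), min(object@times), max(object@times),
    object@nPerm, object@mode, min(object@accuracy), max(object@accuracy),
    object@chance[1], object@threshold[1], sum(object@significant)))
})

#' Tidy a DecodingResult into a table
#'
#' @param result a [DecodingResult-class] object.
#' @return data.frame with columns `time_ms`, `accuracy`, `chance`,
#'   `threshold`, `significant`.
#' @export
decodingTable <- function(result) {
  stopifnot(is(result, "DecodingResult"))
  data.frame(time_ms = round(result@times * 1000),
             accuracy = result@accuracy,
             chance = rep_len(result@chance, length(result@accuracy)),
             threshold = rep_len(result@threshold, length(result@accuracy)),
             significant = result@significant)
}
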