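#' EEGRecording: continuous multichannel EEG with event markers
#'
#' Continuous signal for one subject in one task: a channels x samples
#' matrix (microvolts), the sampling rate, and the event markers the
#' epoching step aligns to. Marker sample indices are 1-based in memory;
#' the on-disk sidecar dialect is 0-based (see [writeDataset()]).
#'
#' @slot channels character, unique channel names (10--20 montage).
#' @slot fs numeric(1), sampling rate in Hz.
#' @slot data numeric matrix, channels x samples, in microvolts.
#' @slot markers data.frame with columns `label` (character), `sample`
#'   (integer, 1-based index into the recording) and `trial` (integer).
#' @slot subject integer(1) subject id.
#' @slot task character(1), `"visual"` or `"memory"`.
#'
#' @export
setClass("EEGRecording",
  representation(channels = "character", fs = "numeric", data = "matrix",
                 markers = "data.frame", subject = "integer",
                 task = "character"))

setValidity("EEGRecording", function(object) {
  msg <- NULL
  if (anyDuplicated(object@channels))
    msg <- c(msg, "channel names must be unique")
  if (nrow(object@data) != length(object@channels))
    msg <- c(msg, "data must have one row per channel")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  req <- c("label", "sample", "trial")
  if (!all(req %in% names(object@markers)))
    msg <- c(msg, "markers must have columns label, sample, trial")
  else if (nrow(object@markers) &&
           (min(object@markers$sample) < 1L ||
            max(object@markers$sample) > ncol(object@data)))
    msg <- c(msg, "marker sample indices must lie within the recording")
  if (!object@task %in% .TASKS)
    msg <- c(msg, "task must be 'visual' or 'memory'")
  if (is.null(msg)) TRUE else msg
})

#' EEGEpochs: event-aligned EEG segments
#'
#' Fixed-length segments cut around one marker label, all with an identical
#' sample count. Trials whose marker sits too close to a recording edge are
#' dropped at construction (see [epochByEvent()]).
#'
#' @slot data numeric array, trials x channels x samples, microvolts.
#' @slot alignment character(1), the marker label epochs are aligned to.
#' @slot window numeric(2), epoch window in seconds relative to the event.
#' @slot times numeric, per-sample time offsets (s) relative to the event.
#' @slot fs numeric(1), sampling rate in Hz.
#' @slot channels character, channel names (dimension 2 of `data`).
#' @slot trials data.frame keying each epoch back to its trial.
#' @slot subject integer(1) subject id.
#' @slot task character(1) task label.
#'
#' @export
setClass("EEGEpochs",
  representation(data = "array", alignment = "character", window = "numeric",
                 times = "numeric", fs = "numeric", channels = "character",
                 trials = "data.frame", subject = "integer",
                 task = "character"))

setValidity("EEGEpochs", function(object) {
  msg <- NULL
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a trials x channels x samples array")
  else {
    if (d[2] != length(object@channels))
      msg <- c(msg, "dimension 2 of data must match channels")
    if (d[3] != length(object@times))
      msg <- c(msg, "dimension 3 of data must match times")
    if (d[1] != nrow(object@trials))
      msg <- c(msg, "dimension 1 of data must match the trial key table")
  }
  if (length(object@window) != 2L || diff(object@window) <= 0)
    msg <- c(msg, "window must be (start, end) with end > start")
  if (is.null(msg)) TRUE else msg
})

#' TimeFrequencyArray: per-trial Morlet power, raw or dB-normalized
#'
#' Power sampled on a 50 ms bin grid for each trial, channel and integer
#' frequency. Bins where the wavelet would overrun the epoch are invalid
#' (NA) and carry `FALSE` in the `valid` mask; they are excluded from all
#' averages, never zero-filled.
#'
#' @slot power numeric array, trials x channels x frequencies x time bins;
#'   microvolts squared, or dB after [dbNormalize()].
#' @slot freqs numeric, frequency axis in Hz.
#' @slot times numeric, bin centers in seconds relative to the event.
#' @slot valid logical matrix, frequencies x time bins: bin has full
#'   wavelet support inside the epoch.
#' @slot channels character, channel names.
#' @slot alignment character(1), inherited from the epochs.
#' @slot unit character(1), `"uV^2"` or `"dB"`.
#' @slot baselineWindow numeric, the (start, end) seconds of the dB
#'   baseline, or numeric(0) before normalization.
#' @slot trials data.frame keying dimension 1 back to trials.
#' @slot subject integer(1) subject id.
#' @slot task character(1) task label.
#'
#' @export
setClass("TimeFrequencyArray",
  representation(power = "array", freqs = "numeric", times = "numeric",
                 valid = "matrix", channels = "character",
                 alignment = "character", unit = "character",
                 baselineWindow = "numeric", trials = "data.frame",
                 subject = "integer", task = "character"))

setValidity("TimeFrequencyArray", function(object) {
  msg <- NULL
  d <- dim(object@power)
  if (length(d) != 4L)
    msg <- c(msg, "power must be trials x channels x freqs x bins")
  else {
    if (d[2] != length(object@channels))
      msg <- c(msg, "dimension 2 must match channels")
    if (d[3] != length(object@freqs))
      msg <- c(msg, "dimension 3 must match freqs")
    if (d[4] != length(object@times))
      msg <- c(msg, "dimension 4 must match times")
    if (!all(dim(object@valid) == d[3:4]))
      msg <- c(msg, "valid mask must be freqs x bins")
  }
  if (!object@unit %in% c("uV^2", "dB"))
    msg <- c(msg, "unit must be 'uV^2' or 'dB'")
  if (is.null(msg)) TRUE else msg
})

#' StateSpaceFit: estimated retention and adaptation rates
#'
#' Result of regressing the hand angle at trial t+1 on the hand angle and
#' reaching error at trial t (no intercept by default), per subject and
#' task, over the adaptation trials.
#'
#' @slot A numeric(1), retention rate estimate (coefficient of x_t).
#' @slot B numeric(1), adaptation rate estimate (coefficient of e_t).
#' @slot intercept numeric(1), intercept estimate (NA when not fitted).
#' @slot R2 numeric(1), coefficient of determination of the one-step-ahead
#'   predictions.
#' @slot predicted numeric, predicted hand angle series (one value per
#'   usable trial pair).
#' @slot residuals numeric, observed minus predicted.
#' @slot nPairs integer(1), number of usable (t, t+1) pairs.
#'
#' @export
setClass("StateSpaceFit",
  representation(A = "numeric", B = "numeric", intercept = "numeric",
                 R2 = "numeric", predicted = "numeric",
                 residuals = "numeric", nPairs = "integer"))

setValidity("StateSpaceFit", function(object) {
  msg <- NULL
  if (length(object@predicted) != length(object@residuals))
    msg <- c(msg, "predicted and residuals must have equal length")
  if (is.finite(object@R2) && object@R2 > 1 + 1e-12)
    msg <- c(msg, "R2 cannot exceed 1")
  if (is.null(msg)) TRUE else msg
})

#' DecodingResult: per-time-point LOSO accuracy with permutation inference
#'
#' @slot accuracy numeric, decoding accuracy per time bin (fraction in
#'   0..1).
#' @slot times numeric, bin centers in seconds.
#' @slot null numeric matrix, permutations x bins: LOSO accuracy under
#'   label permutation (kept for audit).
#' @slot nullStat numeric, the summarized null per the correction mode:
#'   length nPerm (max mode) or a permutations-long column per bin is
#'   summarized per bin (perbin mode gives a bins-long threshold).
#' @slot chance numeric, median of the null (scalar in max mode, per bin
#'   otherwise).
#' @slot threshold numeric, 95th percentile of the null (scalar in max
#'   mode, per bin otherwise).
#' @slot significant logical, accuracy strictly above the threshold.
#' @slot mode character(1), `"max"` or `"perbin"`.
#' @slot nPerm integer(1), number of permutations.
#'
#' @export
setClass("DecodingResult",
  representation(accuracy = "numeric", times = "numeric", null = "matrix",
                 nullStat = "numeric", chance = "numeric",
                 threshold = "numeric", significant = "logical",
                 mode = "character", nPerm = "integer"))

setValidity("DecodingResult", function(object) {
  msg <- NULL
  if (length(object@accuracy) != length(object@times))
    msg <- c(msg, "accuracy and times must have equal length")
  if (length(object@significant) != length(object@accuracy))
    msg <- c(msg, "significant must match accuracy")
  if (any(object@accuracy < 0 | object@accuracy > 1))
    msg <- c(msg, "accuracy must lie in [0, 1]")
  if (any(object@chance < 0 | object@chance > 1) ||
      any(object@threshold < 0 | object@threshold > 1))
    msg <- c(msg, "chance and threshold must lie in [0, 1]")
  if (!object@mode %in% c("max", "perbin"))
    msg <- c(msg, "mode must be 'max' or 'perbin'")
  if (is.null(msg)) TRUE else msg
})
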