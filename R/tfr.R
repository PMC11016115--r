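#' Preprocess a continuous EEG recording
#'
#' Zero-phase band-pass (0.05--100 Hz by default: fourth-order Butterworth
#' low-pass plus a closed-form biquad high-pass for the very low edge) and
#' a 50 Hz band-stop notch, applied per channel.
#'
#' @param rec an [EEGRecording-class].
#' @param band passband edges in Hz (default c(0.05, 100)).
#' @param notch notch center frequency in Hz (default 50; `NULL` skips).
#' @return the filtered recording.
#' @export
preprocessRaw <- function(rec, band = c(0.05, 100), notch = 50) {
  stopifnot(is(rec, "EEGRecording"))
  if (rec@fs <= 2 * band[2])
    stop("fs = ", rec@fs, " Hz is too low for a ", band[2],
         " Hz passband edge")
  dat <- rec@data
  for (ci in seq_len(nrow(dat))) {
    x <- butterLowpass(dat[ci, ], rec@fs, band[2])
    x <- butterHighpass(x, rec@fs, band[1])
    if (!is.null(notch)) x <- butterNotch(x, rec@fs, notch)
    dat[ci, ] <- x
  }
  rec@data <- dat
  rec
}

#' Artifact-removal hook
#'
#' Declared no-op: the synthetic recordings are artifact-free, and the
#' interface accepts an externally cleaned recording in place of its
#' input. Kept so the pipeline has an explicit slot where an ICA-based
#' cleaning step would sit for real data.
#'
#' @param rec an [EEGRecording-class].
#' @return `rec`, unchanged.
#' @export
removeArtifacts <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  rec
}

#' Epoch a recording around one event label
#'
#' One epoch per marker with the given label, each spanning
#' `window[1]..window[2]` seconds around the marker sample (end
#' exclusive, so a (-2, 2) window at fs Hz has exactly 4*fs samples).
#' Markers closer to a recording edge than the window requires are
#' dropped with a warning.
#'
#' @param rec an [EEGRecording-class].
#' @param eventLabel marker label to align to (e.g. `"feedback"`,
#'   `"move_onset"`).
#' @param window epoch window in seconds (default c(-2, 2)).
#' @param channels optional channel subset.
#' @return an [EEGEpochs-class].
#' @export
epochByEvent <- function(rec, eventLabel, window = c(-2, 2),
                         channels = NULL) {
  stopifnot(is(rec, "EEGRecording"))
  mk <- rec@markers[rec@markers$label == eventLabel, , drop = FALSE]
  if (nrow(mk) == 0L)
    stop("no markers with label '", eventLabel, "' in the recording")
  if (is.null(channels)) channels <- rec@channels
  chIdx <- match(channels, rec@channels)
  if (anyNA(chIdx))
    stop("channels not in the recording: ",
         paste(channels[is.na(chIdx)], collapse = ", "))
  fs <- rec@fs
  off <- seq(round(window[1] * fs), round(window[2] * fs) - 1L)
  nS <- ncol(rec@data)
  ok <- mk$sample + off[1] >= 1L & mk$sample + off[length(off)] <= nS
  if (any(!ok))
    warning(sum(!ok), " epoch(s) dropped: marker closer than the window ",
            "to a recording edge")
  mk <- mk[ok, , drop = FALSE]
  if (nrow(mk) == 0L) stop("all epochs fall outside the recording")
  dat <- array(NA_real_,
               dim = c(nrow(mk), length(chIdx), length(off)))
  for (i in seq_len(nrow(mk)))
    dat[i, , ] <- rec@data[chIdx, mk$sample[i] + off, drop = FALSE]
  new("EEGEpochs", data = dat, alignment = eventLabel, window = window,
      times = off / fs, fs = fs, channels = channels,
      trials = data.frame(trial = mk$trial, sample = mk$sample),
      subject = rec@subject, task = rec@task)
}

#' Morlet time-frequency power
#'
#' Complex Morlet wavelet power per trial, channel and integer frequency,
#' sampled every `step` seconds. The default mode uses fixed
#' `nCycles`-cycle wavelets (Gaussian envelope SD `nCycles / (2 pi f)`,
#' truncated at 3 SD); the alternative `"fixed_window"` mode uses a
#' constant `windowLen` envelope at all frequencies (a fixed short window
#' cannot resolve the lowest frequencies, which is why it is not the
#' default). Bins whose wavelet support overruns the epoch are invalid
#' (NA), flagged in the `valid` mask, and excluded from all downstream
#' averages.
#'
#' @param epochs an [EEGEpochs-class].
#' @param freqs frequencies in Hz (default 1:30).
#' @param step bin step in seconds (default 0.05); bin centers sit at
#'   multiples of `step` relative to the alignment event.
#' @param mode `"cycles"` (default) or `"fixed_window"`.
#' @param nCycles wavelet cycles in `"cycles"` mode (default 3).
#' @param windowLen envelope length in seconds in `"fixed_window"` mode
#'   (default 0.2; envelope SD = windowLen / 6 so the window spans
#'   +/- 3 SD).
#' @return a [TimeFrequencyArray-class] with unit `"uV^2"`.
#' @export
morletTFR <- function(epochs, freqs = 1:30, step = 0.05,
                      mode = c("cycles", "fixed_window"), nCycles = 3,
                      windowLen = 0.2) {
  stopifnot(is(epochs, "EEGEpochs"))
  mode <- match.arg(mode)
  fs <- epochs@fs
  if (max(freqs) > fs / 2)
    stop("requested frequency above the Nyquist rate fs/2 = ", fs / 2)
  sigmas <- switch(mode,
    cycles = nCycles / (2 * pi * freqs),
    fixed_window = rep(windowLen / 6, length(freqs)))
  tm <- epochs@times
  # bin centers: multiples of `step` that fall on the epoch's sample grid
  kLo <- ceiling(tm[1] / step)
  kHi <- floor(tm[length(tm)] / step)
  centers <- (kLo:kHi) * step
  centerIdx <- round((centers - tm[1]) * fs) + 1L
  pw <- cpp_morlet_power(epochs@data, fs, as.numeric(freqs),
                         as.numeric(sigmas), as.integer(centerIdx - 1L))
  halfL <- pmax(1L, round(3 * sigmas * fs))
  valid <- outer(halfL, centerIdx,
                 function(h, c) c - h >= 1L & c + h <= length(tm))
  new("TimeFrequencyArray", power = pw, freqs = as.numeric(freqs),
      times = centers, valid = valid, channels = epochs@channels,
      alignment = epochs@alignment, unit = "uV^2",
      baselineWindow = numeric(0), trials = epochs@trials,
      subject = epochs@subject, task = epochs@task)
}

#' Decibel baseline normalization
#'
#' Converts raw power to dB relative to the mean power in a pre-event
#' baseline window, per trial, channel and frequency:
#' `10 * log10(P(ch, f, t) / mean(P(ch, f, baseline)))`. The conventional
#' baselines are (-1.5, -1.0) s for reach-onset-aligned and (-0.1, 0) s
#' for feedback-aligned maps. Frequencies with no valid baseline bin
#' (their wavelet overruns the epoch everywhere in the window) come out
#' all-NA rather than being normalized against a partial baseline of
#' zero bins.
#'
#' @param tf a raw-power [TimeFrequencyArray-class].
#' @param baselineWindow (start, end) seconds of the baseline, inclusive
#'   of bins whose centers fall inside.
#' @return the dB-normalized [TimeFrequencyArray-class].
#' @export
dbNormalize <- function(tf, baselineWindow) {
  stopifnot(is(tf, "TimeFrequencyArray"))
  if (tf@unit == "dB") stop("map is already dB-normalized")
  eps <- 1e-9
  binIn <- tf@times >= baselineWindow[1] - eps &
    tf@times <= baselineWindow[2] + eps
  if (!any(binIn))
    stop("baseline window [", baselineWindow[1], ", ", baselineWindow[2],
         "] s contains no time bins of the epoch")
  pw <- tf@power
  d <- dim(pw)
  for (fi in seq_len(d[3])) {
    base <- which(binIn & tf@valid[fi, ])
    if (length(base) == 0L) { pw[, , fi, ] <- NA_real_; next }
    bp <- pw[, , fi, base, drop = FALSE]
    m <- apply(bp, c(1, 2), mean)          # trials x channels
    if (any(m <= 0, na.rm = TRUE))
      stop("non-positive baseline power; cannot dB-normalize")
    pw[, , fi, ] <- 10 * log10(sweep(pw[, , fi, , drop = FALSE],
                                     c(1, 2), m, `/`))
  }
  tf@power <- pw
  tf@unit <- "dB"
  tf@baselineWindow <- as.numeric(baselineWindow)
  tf
}

#' Average a dB map into canonical bands
#'
#' Arithmetic mean of dB values over each band's frequency bins (inclusive
#' edges, so a shared edge bin belongs to both adjacent bands) and,
#' optionally, over trials. Only valid bins enter the averages.
#'
#' @param tf a dB [TimeFrequencyArray-class].
#' @param bands named list of (low, high) Hz pairs
#'   (default [canonicalBands()]).
#' @param averageTrials average over trials (default TRUE).
#' @return long data.frame: `subject`, `task`, `alignment`, `channel`,
#'   `band`, `time_s`, `time_ms`, `db` (plus `trial` when
#'   `averageTrials = FALSE`).
#' @export
bandAverage <- function(tf, bands = canonicalBands(),
                        averageTrials = TRUE) {
  stopifnot(is(tf, "TimeFrequencyArray"))
  if (tf@unit != "dB")
    stop("band averaging operates on dB-normalized maps")
  d <- dim(tf@power)
  rows <- list()
  for (bn in names(bands)) {
    fIdx <- which(tf@freqs >= bands[[bn]][1] & tf@freqs <= bands[[bn]][2])
    if (length(fIdx) == 0L) stop("band '", bn, "' has no frequency bins")
    sub <- tf@power[, , fIdx, , drop = FALSE]
    # NA power encodes invalid bins; average what is valid (an all-NA
    # frequency column yields NaN -> NA)
    bandDb <- colMeans(aperm(sub, c(3, 1, 2, 4)), na.rm = TRUE)
    bandDb[is.nan(bandDb)] <- NA_real_
    dim(bandDb) <- c(d[1], d[2], d[4])
    for (ci in seq_len(d[2])) {
      if (averageTrials) {
        v <- colMeans(matrix(bandDb[, ci, ], nrow = d[1]), na.rm = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = tf@subject, task = tf@task, alignment = tf@alignment,
          channel = tf@channels[ci], band = bn, time_s = tf@times,
          db = v)
      } else {
        for (tr in seq_len(d[1]))
          rows[[length(rows) + 1L]] <- data.frame(
            subject = tf@subject, task = tf@task,
            alignment = tf@alignment, trial = tf@trials$trial[tr],
            channel = tf@channels[ci], band = bn, time_s = tf@times,
            db = bandDb[tr, ci, ])
      }
    }
  }
  out <- do.call(rbind, rows)
  out$time_ms <- round(out$time_s * 1000)
  rownames(out) <- NULL
  out
}

#' Average band power over an electrode group
#'
#' Collapses a [bandAverage()] table over the electrodes of a named
#' group (e.g. parietal = P3, Pz, P4) by arithmetic mean in dB space.
#'
#' @param bandTable a [bandAverage()] table (possibly row-bound over
#'   recordings).
#' @param groups named list of channel vectors
#'   (default `list(parietal = c("P3", "Pz", "P4"))`).
#' @return long data.frame like the input with `channel` replaced by
#'   `group`.
#' @export
groupAverage <- function(bandTable,
                         groups = list(parietal = .PARIETAL)) {
  rows <- list()
  for (gn in names(groups)) {
    sub <- bandTable[bandTable$channel %in% groups[[gn]], , drop = FALSE]
    if (nrow(sub) == 0L) stop("group '", gn, "' matches no electrodes")
    agg <- stats::aggregate(
      db ~ subject + task + alignment + band + time_s + time_ms,
      data = sub, FUN = mean, na.action = stats::na.pass)
    agg$group <- gn
    rows[[length(rows) + 1L]] <- agg
  }
  out <- do.call(rbind, rows)
  out[order(out$group, out$band, out$subject, out$task, out$time_s), ]
}
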