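# cosine-tapered (Tukey) window on [0, 1]; alpha = total taper fraction.
# Flat plateau so a configured dB effect holds as a window average, with
# smooth ramps at the edges.
tukeyWindow <- function(n, alpha = 0.2) {
  if (n == 1L) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  a2 <- alpha / 2
  lo <- t < a2
  hi <- t > 1 - a2
  w[lo] <- 0.5 * (1 + cos(pi * (t[lo] / a2 - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * ((t[hi] - 1 + a2) / a2)))
  w
}

#' Default task-modulated oscillatory effects
#'
#' The two effects the study design motivates: a post-feedback parietal
#' delta increase and a pre-movement beta decrease at C3 and Fz, both
#' stronger in the visually-guided task. `dbDiff` is the expected
#' decibel difference (visual minus memory) of band power against each
#' signal's own pre-event baseline; magnitudes default to +/- 3 dB.
#'
#' @param deltaDb dB difference of the post-feedback parietal delta
#'   effect (default +3).
#' @param betaDb dB difference of the pre-movement beta effect
#'   (default -3, a stronger desynchronization in the visually-guided
#'   task).
#' @return list of effect specifications for [eegParams()].
#' @export
defaultEEGEffects <- function(deltaDb = 3, betaDb = -3) {
  list(
    list(name = "feedback_delta_parietal", band = c(1, 4),
         channels = .PARIETAL, align = "feedback", window = c(0, 1),
         dbDiff = deltaDb),
    list(name = "premove_beta_central", band = c(13, 30),
         channels = c("C3", "Fz"), align = "move_onset",
         window = c(-1, 0), dbDiff = betaDb))
}

#' EEG generator parameters
#'
#' Montage, sampling rate, 1/f background and task-modulated effects for
#' the synthetic EEG. Trials are laid out on a continuous timeline at
#' `trialPeriod` seconds per trial with `pad` seconds of lead-in/out so
#' every event marker has at least the epoch half-width of signal on both
#' sides.
#'
#' @param channels montage names (default: a 20-channel 10--20 montage
#'   including Fz, C3, P3, Pz, P4).
#' @param fs sampling rate in Hz (default 500; must be at least twice the
#'   30 Hz analysis ceiling).
#' @param bgExponent 1/f^a background exponent (default 1).
#' @param bgRms background RMS amplitude in microvolts (default 10).
#' @param effects list of effect specifications (see
#'   [defaultEEGEffects()]); each needs `band` (Hz pair), `channels`,
#'   `align` (marker label), `window` (s pair relative to the event) and
#'   `dbDiff` (visual minus memory, dB). Optional `taper` (Tukey fraction,
#'   default 0.25) and `bandwidthFactor` (fractional widening of the
#'   modulated band beyond the nominal edges, default 1/3 to match the
#'   analyzer's 3-cycle wavelet resolution).
#' @param trialPeriod seconds allotted per trial on the continuous
#'   timeline (default 8).
#' @param pad lead-in/out seconds (default 3).
#' @return validated list of class `"eegParams"`.
#' @export
eegParams <- function(channels = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4",
                                   "F8", "T7", "C3", "Cz", "C4", "T8",
                                   "P7", "P3", "Pz", "P4", "P8", "O1",
                                   "O2", "Oz"),
                      fs = 500, bgExponent = 1, bgRms = 10,
                      effects = defaultEEGEffects(),
                      trialPeriod = 8, pad = 3) {
  if (fs < 2 * 30)
    stop("fs must be at least twice the 30 Hz analysis ceiling")
  if (anyDuplicated(channels)) stop("channel names must be unique")
  for (ef in effects) {
    if (!all(ef$channels %in% channels))
      stop("effect '", ef$name, "' names channels missing from the montage")
    if (!ef$align %in% .EVENTS)
      stop("effect alignment must be one of ",
           paste(.EVENTS, collapse = ", "))
    if (length(ef$band) != 2L || ef$band[1] >= ef$band[2])
      stop("effect band must be (low, high) Hz")
  }
  if (trialPeriod < 5.5)
    stop("trialPeriod too short for the memory-guided event sequence")
  structure(list(channels = channels, fs = fs, bgExponent = bgExponent,
                 bgRms = bgRms, effects = effects,
                 trialPeriod = trialPeriod, pad = pad),
            class = "eegParams")
}

# 1/f^a background: white Gaussian noise shaped in the frequency domain,
# zero-mean, scaled to the requested RMS
pinkNoise <- function(n, fs, exponent, rms, nChannels = 1L) {
  f <- c(0, seq_len(n - 1L))
  f <- pmin(f, n - f) * fs / n          # two-sided frequency magnitude
  h <- 1 / pmax(f, 0.1)^(exponent / 2)  # 0.1 Hz floor keeps variance finite
  h[1] <- 0                             # no DC
  w <- matrix(rnorm(n * nChannels), n, nChannels)
  y <- Re(stats::mvfft(stats::mvfft(w) * h, inverse = TRUE)) / n
  sc <- rms / sqrt(colMeans(y^2))
  sweep(y, 2, sc, `*`)
}

#' Simulate one subject x task EEG recording
#'
#' Continuous 1/f-background signal per channel with four event markers
#' per trial (target on, go, movement onset, feedback) and, for each
#' configured effect, an event-locked modulation of the in-band signal
#' component. Effects are realized by multiplying the band-passed
#' component of the background by a Tukey-tapered gain inside the effect
#' window on visually-guided recordings (10^(dbDiff/20) at the plateau),
#' leaving memory-guided recordings untouched, so the expected
#' task difference of baseline-normalized band power equals `dbDiff` dB
#' at the window plateau for both signs of the effect.
#'
#' @param trialsSub trial rows of one subject x task, in trial order
#'   (from [simulateBehavior()]`$trials`).
#' @param params [eegParams()].
#' @param seed integer seed (deterministic per subject x task).
#' @return an [EEGRecording-class].
#' @export
simulateEEGRecording <- function(trialsSub, params = eegParams(),
                                 seed = 1) {
  stopifnot(inherits(params, "eegParams"))
  subject <- unique(trialsSub$subject)
  task <- unique(trialsSub$task)
  if (length(subject) != 1L || length(task) != 1L)
    stop("trialsSub must contain exactly one subject x task")
  trialsSub <- trialsSub[order(trialsSub$trial), , drop = FALSE]
  fs <- params$fs
  nTrials <- nrow(trialsSub)
  dur <- 2 * params$pad + nTrials * params$trialPeriod
  n <- round(dur * fs)

  # event times on the continuous timeline
  t0 <- params$pad + (seq_len(nTrials) - 1L) * params$trialPeriod
  evTimes <- data.frame(
    target_on = t0 + trialsSub$t_target_on_s,
    go = t0 + trialsSub$t_go_s,
    move_onset = t0 + trialsSub$t_move_onset_s,
    feedback = t0 + trialsSub$t_feedback_s)
  latest <- max(evTimes$feedback - t0)
  if (latest + 2 > params$trialPeriod + params$pad)
    stop("trialPeriod too short: feedback events lack 2 s of tail signal")
  markers <- data.frame(
    label = rep(.EVENTS, each = nTrials),
    sample = as.integer(round(unlist(evTimes[.EVENTS]) * fs) + 1L),
    trial = rep(trialsSub$trial, times = length(.EVENTS)))
  markers <- markers[order(markers$sample), ]
  rownames(markers) <- NULL

  set.seed(deriveSeed(seed, paste("eeg", subject, task)))
  bg <- pinkNoise(n, fs, params$bgExponent, params$bgRms,
                  nChannels = length(params$channels))

  if (task == "visual") {
    for (ef in params$effects) {
      g <- 10^(ef$dbDiff / 20)
      taper <- if (is.null(ef$taper)) 0.25 else ef$taper
      bwf <- if (is.null(ef$bandwidthFactor)) 1 / 3 else ef$bandwidthFactor
      # widen the modulated band by the analyzer's spectral resolution
      # (3-cycle Morlet wavelets have fractional bandwidth ~ f/3), so the
      # measured in-band power ratio matches the configured gain instead
      # of being diluted by unmodulated leakage from just outside the band
      modBand <- c(ef$band[1] * (1 - bwf), ef$band[2] * (1 + bwf))
      modBand[1] <- max(modBand[1], 0.2)
      modBand[2] <- min(modBand[2], 0.45 * fs)
      wlen <- round(diff(ef$window) * fs)
      wshape <- tukeyWindow(wlen, taper)
      evs <- round(evTimes[[ef$align]] * fs) + 1L
      for (ch in ef$channels) {
        ci <- match(ch, params$channels)
        bandcomp <- butterBandpass(bg[, ci], fs, modBand)
        for (s0 in evs) {
          idx <- s0 + round(ef$window[1] * fs) + seq_len(wlen) - 1L
          idx <- idx[idx >= 1L & idx <= n]
          if (length(idx) < wlen) next
          bg[idx, ci] <- bg[idx, ci] + (g - 1) * wshape * bandcomp[idx]
        }
      }
    }
  }

  new("EEGRecording", channels = params$channels, fs = fs,
      data = t(bg), markers = markers,
      subject = as.integer(subject), task = task)
}

#' Simulate EEG for all (or selected) subject x task cells
#'
#' Thin iterator over [simulateEEGRecording()]. Note a full 8-subject
#' dataset holds 16 multichannel recordings; for long designs consider
#' generating and analyzing one recording at a time instead.
#'
#' @param trials trial table from [simulateBehavior()].
#' @param params [eegParams()].
#' @param seed integer seed.
#' @param subjects,tasks optional subsets.
#' @return named list of [EEGRecording-class] objects
#'   (`"s<subject>_<task>"`).
#' @export
simulateEEG <- function(trials, params = eegParams(), seed = 1,
                        subjects = NULL, tasks = NULL) {
  if (is.null(subjects)) subjects <- sort(unique(trials$subject))
  if (is.null(tasks)) tasks <- .TASKS
  out <- list()
  for (s in subjects) for (tk in tasks) {
    sub <- trials[trials$subject == s & trials$task == tk, , drop = FALSE]
    if (nrow(sub) == 0L) stop("missing trials for subject ", s, " ", tk)
    out[[sprintf("s%d_%s", s, tk)]] <-
      simulateEEGRecording(sub, params, seed)
  }
  out
}
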