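# shared helpers: independent oracles and small builders

# wrap a samples x features x bins array as a decoding dataset
makeDecodingDataset <- function(X, nSubjects = dim(X)[1] / 2) {
  structure(list(X = X, y = rep(c(1, -1), nSubjects),
                 subjects = rep(seq_len(nSubjects), each = 2),
                 times = seq(0, by = 0.05,
                             length.out = dim(X)[3]),
                 band = "delta", electrodes = paste0("e", seq_len(dim(X)[2])),
                 alignment = "feedback", window = c(0, 1)),
            class = "decodingDataset")
}

# brute-force within-subject two-way sums of squares via explicit loops
# over cell and marginal means (independent of the package path)
bruteForceRmAnovaSS <- function(value, subject, f1, f2) {
  s <- factor(subject); a <- factor(f1); b <- factor(f2)
  ns <- nlevels(s); na <- nlevels(a); nb <- nlevels(b)
  g <- mean(value)
  mS <- tapply(value, s, mean); mA <- tapply(value, a, mean)
  mB <- tapply(value, b, mean)
  mSA <- tapply(value, list(s, a), mean)
  mSB <- tapply(value, list(s, b), mean)
  mAB <- tapply(value, list(a, b), mean)
  ssA <- 0; for (i in seq_len(na)) ssA <- ssA + ns * nb * (mA[i] - g)^2
  ssB <- 0; for (j in seq_len(nb)) ssB <- ssB + ns * na * (mB[j] - g)^2
  ssSA <- 0
  for (k in seq_len(ns)) for (i in seq_len(na))
    ssSA <- ssSA + nb * (mSA[k, i] - mS[k] - mA[i] + g)^2
  ssSB <- 0
  for (k in seq_len(ns)) for (j in seq_len(nb))
    ssSB <- ssSB + na * (mSB[k, j] - mS[k] - mB[j] + g)^2
  ssAB <- 0
  for (i in seq_len(na)) for (j in seq_len(nb))
    ssAB <- ssAB + ns * (mAB[i, j] - mA[i] - mB[j] + g)^2
  ssS <- 0; for (k in seq_len(ns)) ssS <- ssS + na * nb * (mS[k] - g)^2
  ssT <- sum((value - g)^2)
  list(ssA = unname(ssA), ssB = unname(ssB), ssAB = unname(ssAB),
       ssS = unname(ssS), ssSA = unname(ssSA), ssSB = unname(ssSB),
       ssRes = unname(ssT - ssA - ssB - ssAB - ssS - ssSA - ssSB),
       ssT = unname(ssT))
}

# normal-equation solve of the two-regressor no-intercept state-space fit
normalEquationAB <- function(handAngles, rotation) {
  n <- length(handAngles)
  x <- handAngles[-n]; e <- rotation[-n] - x; y <- handAngles[-1]
  s11 <- sum(x * x); s12 <- sum(x * e); s22 <- sum(e * e)
  b1 <- sum(x * y); b2 <- sum(e * y)
  det <- s11 * s22 - s12 * s12
  c(A = (s22 * b1 - s12 * b2) / det, B = (s11 * b2 - s12 * b1) / det)
}

# a bare continuous recording around a given channel x sample matrix
makeRecording <- function(data, fs, markers = NULL, task = "visual") {
  if (is.null(markers))
    markers <- data.frame(label = character(0), sample = integer(0),
                          trial = integer(0))
  new("EEGRecording",
      channels = paste0("ch", seq_len(nrow(data))), fs = fs, data = data,
      markers = markers, subject = 1L, task = task)
}

# single-trial epochs object around a plain signal vector
makeEpoch <- function(x, fs, window = c(-2, 2)) {
  new("EEGEpochs", data = array(x, c(1, 1, length(x))),
      alignment = "feedback", window = window,
      times = seq(window[1], by = 1 / fs, length.out = length(x)),
      fs = fs, channels = "Pz",
      trials = data.frame(trial = 1L, sample = NA_integer_),
      subject = 1L, task = "visual")
}

# band-power long table for synthetic feature matrices:
# vals[subject, task, electrode, bin]
makeBandTable <- function(vals, electrodes, times, band = "delta",
                          alignment = "feedback") {
  d <- dim(vals)
  out <- expand.grid(subject = seq_len(d[1]),
                     task = c("visual", "memory"),
                     channel = electrodes, time_s = times,
                     stringsAsFactors = FALSE)
  out$band <- band
  out$alignment <- alignment
  out$db <- vals[cbind(out$subject, match(out$task, c("visual", "memory")),
                       match(out$channel, electrodes),
                       match(out$time_s, times))]
  out$time_ms <- round(out$time_s * 1000)
  out
}
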