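test_that("preprocessing keeps the passband and removes DC and 50 Hz", {
  fs <- 500
  t <- seq(0, 30, by = 1 / fs)
  x10 <- sin(2 * pi * 10 * t)
  x50 <- sin(2 * pi * 50 * t)
  dc <- rep(100, length(t))
  rec <- makeRecording(rbind(x10, x50, dc), fs)
  out <- signalData(preprocessRaw(rec))
  i <- 5000:10000
  expect_gt((max(out[1, i]) - min(out[1, i])) / 2, 0.98)   # 10 Hz kept
  att <- 20 * log10(max(abs(out[2, i])))
  expect_lt(att, -20)                                      # 50 Hz notched
  expect_lt(abs(mean(out[3, i])), 1)                       # DC removed
  expect_error(preprocessRaw(makeRecording(rbind(x10), 150)), "too low")
})

test_that("epoching slices the recording at the marker offsets", {
  fs <- 500
  n <- 20 * fs
  ramp <- matrix(seq_len(n), nrow = 1)    # sample-index signal
  mk <- data.frame(label = "feedback",
                   sample = c(3 * fs, 10 * fs, 19.5 * fs), trial = 1:3)
  rec <- makeRecording(ramp, fs, mk)
  expect_warning(ep <- epochByEvent(rec, "feedback"), "dropped")
  expect_equal(dim(epochData(ep))[1], 2L)   # the 19.5 s marker is too late
  expect_equal(dim(epochData(ep))[3], 4L * fs)
  # content equals a direct slice: epoch spans [marker - 2 s, marker + 2 s)
  expect_equal(epochData(ep)[1, 1, ],
               as.numeric((3 * fs - 2 * fs):(3 * fs + 2 * fs - 1)))
  expect_equal(epochData(ep)[2, 1, ],
               as.numeric((10 * fs - 2 * fs):(10 * fs + 2 * fs - 1)))
  expect_error(epochByEvent(rec, "go"), "no markers")
  expect_error(epochByEvent(rec, "feedback", channels = "Oz"),
               "not in the recording")
})

test_that("Morlet power peaks at the stimulus frequency and scales as A^2", {
  fs <- 500
  tt <- seq(-2, 2 - 1 / fs, by = 1 / fs)
  ep <- makeEpoch(sin(2 * pi * 10 * tt), fs)
  tf <- morletTFR(ep)
  expect_equal(tf@freqs, 1:30)
  expect_equal(diff(tf@times), rep(0.05, length(tf@times) - 1))
  pw <- tfPower(tf)[1, 1, , ]
  interior <- which(colSums(!tf@valid) == 0)
  expect_true(all(apply(pw[, interior], 2, which.max) == 10))
  ep2 <- makeEpoch(2 * sin(2 * pi * 10 * tt), fs)
  pw2 <- tfPower(morletTFR(ep2))[1, 1, , ]
  expect_equal(mean(pw2[10, interior] / pw[10, interior]), 4,
               tolerance = 0.01)
  expect_error(morletTFR(ep, freqs = 1:300), "Nyquist")
})

test_that("a 20 Hz burst's Morlet time course matches an STFT oracle", {
  fs <- 500
  tt <- seq(-2, 2 - 1 / fs, by = 1 / fs)
  set.seed(91)
  burst <- exp(-((tt - 0.25) / 0.18)^2)  # smooth 0.5 s-scale envelope
  x <- burst * sin(2 * pi * 20 * tt) + 0.05 * rnorm(length(tt))
  tf <- morletTFR(makeEpoch(x, fs))
  p20 <- tfPower(tf)[1, 1, 20, ]
  ok <- tf@valid[20, ]
  # independent short-time Fourier spectrogram at 20 Hz
  win <- 125   # 0.25 s window
  sg <- signal::specgram(x, n = win, Fs = fs, overlap = win - 25)
  f20 <- which.min(abs(sg$f - 20))
  stftP <- abs(sg$S[f20, ])^2
  # sg$t marks each window's first sample; shift to centers, epoch time
  stftT <- sg$t + (win - 1) / 2 / fs - 2
  stftAt <- approx(stftT, stftP, xout = tf@times[ok])$y
  keep <- is.finite(stftAt)
  expect_gt(cor(p20[ok][keep], stftAt[keep]), 0.95)
})

test_that("dB normalization matches its defining formula", {
  fs <- 500
  tt <- seq(-2, 2 - 1 / fs, by = 1 / fs)
  # truly stationary (deterministic, single-component) signal: power at
  # each frequency is constant over bins up to discrete-grid ripple, so
  # the mean dB over its own baseline is ~0
  tfs <- morletTFR(makeEpoch(sin(2 * pi * 10 * tt), fs))
  tfsdb <- dbNormalize(tfs, c(-1.5, -1.0))
  binIn <- tfsdb@times >= -1.5 & tfsdb@times <= -1.0
  base <- binIn & tfsdb@valid[10, ]
  expect_lt(abs(mean(tfPower(tfsdb)[1, 1, 10, base])), 1e-6)
  # a power ratio of 10 reads +10 dB (logarithm identity)
  set.seed(101)
  tf <- morletTFR(makeEpoch(rnorm(length(tt)), fs))
  raw <- tfPower(tf)
  tfx <- tf
  base <- which(binIn & tf@valid[8, ])
  m <- mean(raw[1, 1, 8, base])
  tfx@power[1, 1, 8, base[1] + 20L] <- 10 * m
  dbx <- tfPower(dbNormalize(tfx, c(-1.5, -1.0)))
  expect_equal(dbx[1, 1, 8, base[1] + 20L], 10, tolerance = 1e-9)
  # random map: bin-by-bin equality with the direct formula
  tfdb <- dbNormalize(tf, c(-1.5, -1.0))
  db <- tfPower(tfdb)
  for (fi in c(3, 12)) {
    bset <- which(binIn & tf@valid[fi, ])
    m <- mean(raw[1, 1, fi, bset])
    expect_equal(db[1, 1, fi, ], 10 * log10(raw[1, 1, fi, ] / m),
                 tolerance = 1e-12)
  }
  expect_error(dbNormalize(tfdb, c(-1.5, -1)), "already")
  expect_error(dbNormalize(tf, c(5, 6)), "no time bins")
})

test_that("dB maps are invariant under global signal rescaling", {
  fs <- 500
  tt <- seq(-2, 2 - 1 / fs, by = 1 / fs)
  set.seed(111)
  x <- rnorm(length(tt))
  db1 <- tfPower(dbNormalize(morletTFR(makeEpoch(x, fs)), c(-0.1, 0)))
  db2 <- tfPower(dbNormalize(morletTFR(makeEpoch(7.3 * x, fs)),
                             c(-0.1, 0)))
  expect_equal(db1, db2, tolerance = 1e-9)
})

test_that("band averages use inclusive edges and honor the dB scale", {
  fs <- 500
  nb <- 81
  freqs <- 1:30
  # hand-built dB map: power = frequency index, constant over time
  pw <- array(rep(freqs, each = 2 * 1), c(2, 1, 30, nb))
  tf <- new("TimeFrequencyArray", power = pw, freqs = as.numeric(freqs),
            times = seq(-2, 2, by = 0.05), valid = matrix(TRUE, 30, nb),
            channels = "Pz", alignment = "feedback", unit = "dB",
            baselineWindow = c(-0.1, 0),
            trials = data.frame(trial = 1:2, sample = NA),
            subject = 1L, task = "visual")
  bt <- bandAverage(tf)
  expect_equal(unique(bt$db[bt$band == "delta"]), mean(1:4))   # 4 bins
  expect_equal(unique(bt$db[bt$band == "theta"]), mean(4:8))   # shared 4 Hz
  expect_equal(unique(bt$db[bt$band == "alpha"]), mean(8:13))
  expect_equal(unique(bt$db[bt$band == "beta"]), mean(13:30))
  # constant map: every series is the constant
  tf@power <- array(2.5, c(2, 1, 30, nb))
  btc <- bandAverage(tf)
  expect_true(all(btc$db == 2.5))
  # aggregation oracle with random values, including trial averaging
  set.seed(121)
  tf@power <- array(rnorm(2 * 30 * nb), c(2, 1, 30, nb))
  bt2 <- bandAverage(tf)
  d1 <- bt2$db[bt2$band == "delta"]
  oracle <- sapply(seq_len(nb), function(b)
    mean(tf@power[, 1, 1:4, b]))
  expect_equal(d1, oracle, tolerance = 1e-12)
  # band average after trial average == trial average of band averages
  perTrial <- bandAverage(tf, averageTrials = FALSE)
  d2 <- with(perTrial[perTrial$band == "delta", ],
             tapply(db, time_s, mean))
  expect_equal(as.numeric(d2), oracle, tolerance = 1e-12)
  # group averaging collapses electrodes
  tf3 <- tf
  tf3@channels <- "P3"
  btp <- rbind(bandAverage(tf), bandAverage(tf3))
  btp$channel[btp$channel == "Pz"] <- "Pz"
  g <- groupAverage(btp, list(parietal = c("Pz", "P3")))
  expect_equal(nrow(g), 4 * nb)
})

test_that("artifact hook returns its input untouched", {
  rec <- makeRecording(matrix(rnorm(1000), 2), 500)
  expect_identical(removeArtifacts(rec), rec)
})
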