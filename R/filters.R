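# Internal zero-phase IIR filtering.
#
# signal::filtfilt is unusable at very low normalized cutoffs (the 0.05 Hz
# high-pass edge at fs = 500 has W = 2e-4; its transient spans tens of
# seconds and the stock padding leaves it in the output). This helper
# demeans, pads by odd reflection scaled to the filter's time constant,
# runs signal::filter forward and backward, and restores the mean through
# the filter's squared DC gain.

# one forward-backward pass of an (b, a) filter with odd-reflection padding
zeroPhaseFilter <- function(b, a, x, npad) {
  n <- length(x)
  if (n < 4L) stop("too few samples to filter (need >= 4)")
  npad <- min(n - 1L, as.integer(npad))
  mu <- mean(x)
  xc <- x - mu
  xp <- c(2 * xc[1] - rev(xc[2:(npad + 1L)]),
          xc,
          2 * xc[n] - rev(xc[(n - npad):(n - 1L)]))
  flt <- signal::Arma(b = b, a = a)
  y <- signal::filter(flt, xp)
  y <- rev(signal::filter(flt, rev(y)))
  g0 <- (sum(b) / sum(a))^2   # two-pass DC gain
  y[(npad + 1L):(npad + n)] + mu * g0
}

# Butterworth low-pass, zero phase; cutoff in Hz
butterLowpass <- function(x, fs, cutoff, order = 4) {
  flt <- signal::butter(order, cutoff / (fs / 2), type = "low")
  zeroPhaseFilter(flt$b, flt$a, x, npad = ceiling(3 * fs / cutoff))
}

# RBJ biquad high-pass: designed in closed form because signal::butter is
# numerically degenerate at W ~ 1e-4
biquadHighpass <- function(f0, fs, Q = 1 / sqrt(2)) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  cw <- cos(w0)
  b <- c((1 + cw) / 2, -(1 + cw), (1 + cw) / 2)
  a <- c(1 + alpha, -2 * cw, 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

butterHighpass <- function(x, fs, cutoff) {
  bq <- biquadHighpass(cutoff, fs)
  # padding capped: the 0.05 Hz time constant exceeds any realistic epoch
  npad <- min(ceiling(1.5 * fs / cutoff), 60 * fs)
  zeroPhaseFilter(bq$b, bq$a, x, npad = npad)
}

# band-stop notch (Butterworth order 2 per edge), zero phase
butterNotch <- function(x, fs, center = 50, halfwidth = 2) {
  flt <- signal::butter(2, c(center - halfwidth, center + halfwidth) / (fs / 2),
                        type = "stop")
  zeroPhaseFilter(flt$b, flt$a, x, npad = ceiling(3 * fs / halfwidth))
}

# band-pass, zero phase; band = c(low, high) Hz
butterBandpass <- function(x, fs, band, order = 4) {
  flt <- signal::butter(order, band / (fs / 2), type = "pass")
  zeroPhaseFilter(flt$b, flt$a, x, npad = ceiling(3 * fs / band[1]))
}
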