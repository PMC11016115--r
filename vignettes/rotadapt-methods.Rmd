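---
title: "Models and methods behind rotadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rotadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rotadapt simulates and analyzes a gradual visuomotor-rotation experiment
in which the same subjects reach under two regimes: a visually-guided
task (reach to a visible target as soon as it appears) and a
memory-guided task (the target is flashed for 0.2 s and the reach starts
on a go signal 2 s later, toward the remembered location). During the
adaptation phase the cursor is rotated counterclockwise around the start
circle by an amount that grows by 0.2° per trial up to a 20° ceiling, so
the perturbation stays below awareness and adaptation is dominated by
implicit, error-driven learning. This vignette documents the models, the
estimation choices, the synthetic-data generator, and the numerical
decisions, in that order.

## The behavioral model

### Trial-by-trial state space

The internal state $x_t$ (identified with the observed hand angle, in
degrees, positive in the compensatory direction) evolves as

$$e_t = r_t - x_t, \qquad x_{t+1} = A\,x_t + B\,e_t,$$

where $r_t$ is the imposed cursor rotation and $e_t$ the reaching error
(the angle between cursor and target). $A \in [0,1]$ is the retention
rate — how much of the state survives to the next trial — and
$B \in [0,1]$ the adaptation rate — the fraction of the experienced
error corrected on the next trial. Under a constant rotation $r$ the
noiseless fixed point is $B r / (1 - A + B)$.

`estimateStateSpace()` fits $A$ and $B$ by least squares, regressing
$x_{t+1}$ on the two regressors $(x_t, e_t)$ with **no intercept**. A
regression of $x_{t+1}$ on $e_t$ alone cannot identify two coefficients,
so the two-regressor form implied by the model equation is the one
implemented; an `intercept = TRUE` switch exists for sensitivity
analysis. Fits are per subject and task (the reported spread of fit
quality across subjects presupposes per-subject fits), $R^2$ is the
ordinary coefficient of determination of the one-step-ahead predictions,
and excluded trials are dropped pairwise: a pair $(t, t+1)$ enters only
if both trials survived screening.

### Kinematic measures

Cursor trajectories are sampled at 60 Hz and low-pass filtered at 20 Hz
with a zero-phase fourth-order Butterworth filter. Zero-phase (forward–
backward) filtering is used because any one-pass filter would lag the
peak-velocity sample on which the hand angle is evaluated. The hand
angle is the signed angle between the start-center→target ray and the
start-center→hand ray at the sample of peak y-velocity; reaction time is
the time from the go signal to the first sample **strictly** above
20 mm/s of y-velocity; movement time is the duration of the contiguous
supra-threshold interval containing the global velocity peak (robust to
pre-go jitter). Trials whose velocity never crosses the threshold have
no defined RT/MT and are excluded with a reason code, never imputed.

### Outlier screening

A trial is excluded when its hand angle deviates from a centered
5-trial moving mean by more than 3 standard deviations. The SD in this
rule is the per-series (subject × task) SD of hand angles, not a
5-sample moving SD: a 5-sample SD estimate is so noisy that a $k = 3$
rule would either flag several percent of perfectly clean Gaussian
trials (if the window excludes the trial) or could never flag anything
(if it includes it — the deviation of one of $n$ points from their mean
is bounded by $(n-1)/\sqrt{n} \approx 1.79$ SDs). With the series-SD
reading, a couple of gross errors among thousands of clean trials are
flagged and nothing else, which is the regime the screening rule is
meant for. Flags are computed once on the raw series, so excluding
flagged trials never changes the flags of the others. Whether the
moving mean is centered or trailing is not determined by the protocol;
centered was chosen, shrunk at the edges.

### Group statistics

Behavioral contrasts use paired $t$ tests with Cohen's $d$ and two-way
repeated-measures ANOVA (task × block) fitted through `stats::aov()`
with subject-by-effect error strata and no sphericity correction, so the
degrees of freedom are the integer textbook values. Effect sizes are
partial $\eta^2 = SS_\text{effect} / (SS_\text{effect} +
SS_\text{error})$. Two $d$ conventions are implemented because the
convention is genuinely ambiguous in this literature: the default
$d_z = \bar{d} / SD(d)$ (consistent with $t = d_z\sqrt{n}$) and an
`average_sd` variant dividing by the mean of the two condition SDs; the
convention used is recorded in every output row. $p$ values are
computed but are never used as acceptance surfaces for the simulated
data, since they are data-dependent.

## EEG analysis

### Time–frequency decomposition

Epochs of ±2 s are cut around reach onset (preparatory activity) and
feedback onset (visuomotor processing). Power is computed at 1–30 Hz in
1 Hz steps, every 50 ms, with complex Morlet wavelets. A literal
"200 ms analysis window" cannot resolve 1 Hz, so the default mode uses
fixed **3-cycle** wavelets (Gaussian envelope SD $= 3/(2\pi f)$,
truncated at ±3 SD); a `fixed_window` mode with a constant 200 ms
envelope at all frequencies is available for comparison. Time bins whose
wavelet support overruns the epoch are marked invalid and excluded from
every average — never zero-filled. This matters at 1 Hz, whose wavelet
spans ±1.4 s: reach-aligned maps have no valid 1 Hz baseline bins in the
(−1.5, −1.0) s window, so the 1 Hz row is dropped there and the delta
band average uses 2–4 Hz.

Power is converted to dB per trial, channel and frequency against the
mean power in a pre-event baseline — (−1.5, −1.0) s for reach-aligned
and (−0.1, 0) s for feedback-aligned maps — using $10\log_{10}$ (a power
ratio). Trial averaging is performed **after** the dB conversion (the
order is not dictated by anything upstream; per-trial baselining is the
common ERSP choice and is flagged as a sensitivity point). Band averages
are arithmetic means of dB values over the band's frequency bins with
inclusive edges (a shared edge bin such as 4 Hz belongs to both
adjacent bands) and, when requested, over an electrode group such as
parietal = {P3, Pz, P4}.

### Decoding and permutation inference

The task type is decoded from the band-power time courses with one
linear maximum-margin classifier per 50 ms bin under leave-one-subject-
out cross-validation: train on the other subjects' 2(n−1) samples
(features standardized by the training fold's mean and SD), predict the
held-out subject's two samples, pool correct predictions over folds.
The classifier is a standard soft-margin SVM with cost fixed at 1,
solved by a deterministic SMO implementation in compiled code (the
permutation loop refits the classifier millions of times, which rules
out per-fit calls into a general-purpose library; the compiled solver is
cross-checked against libsvm in the test suite). Decision ties predict
the visually-guided label so that runs are bit-reproducible. Features
are the dB values of one band at one electrode group's electrodes
(3 features for parietal, 1 for C3 or Fz); the group-of-three choice for
the parietal analysis mirrors pooling the three parietal electrodes into
one decoder.

Chance and significance come from a permutation null: each permutation
independently flips each subject's pair of task labels with probability
½ — the shuffle that respects the paired, two-samples-per-subject
structure — and the LOSO accuracy curve is recomputed. By default the
null statistic is each permutation's **maximum** accuracy over the
analysis window, which controls the family-wise error across time bins;
an uncorrected per-bin mode exists for comparison. The chance level is
the median of the null and the threshold its 95th percentile;
significance requires the true accuracy to be **strictly** greater than
the threshold.

## The synthetic-data generator

The generator emulates the study conditions: 8 subjects × 2 tasks ×
180 trials in 6 blocks of 30 (baseline, 4 adaptation blocks, washout),
targets uniform on ±10° at 8 cm, the 0.2°/trial rotation ramp capped at
20°, cursor sampling at 60 Hz. Behavior is driven by the state-space
learner itself (motor noise enters the executed hand angle, and hence
the error the learner experiences); reaches are 100 mm minimum-jerk
movements — smooth, analytic, with a well-defined peak velocity of
$1.875\,D/T$ — of 0.3 s duration, so the cursor crosses the 80 mm
feedback radius without stopping. Reaction times are truncated-normal
draws per task, 0.30 s (visual) vs 0.40 s (memory) ± 0.05 s by default:
the direction of the RT difference is a design fact, its size a chosen,
configurable parameter. Default learner rates (A = 0.95/0.90,
B = 0.25/0.15 for visual/memory) place the visually-guided task above
the memory-guided one, with motor noise of 2°, a typical hand-angle
variability for tablet reaching. Two 40° hand-angle outliers per full
dataset are injected at random non-adjacent slots (optional flag) to
exercise the exclusion rule at the scale of a couple of trials in
thousands.

EEG is generated per subject × task as 20 channels (10–20 montage) of
$1/f$ background noise at 500 Hz, RMS 10 µV, with four markers per
trial (target on, go, movement onset, feedback) laid out on a
continuous timeline. Task-modulated oscillations are injected by
**multiplying the band-limited component of the background** by a
Tukey-tapered gain inside the effect window of visually-guided
recordings, leaving memory-guided recordings untouched. Multiplicative
gain — rather than adding windowed noise bursts — was chosen because
(i) it realizes *decreases* (the pre-movement beta desynchronization)
just as naturally as increases, (ii) it preserves the in-band spectral
shape exactly, so the expected dB difference equals the configured
value at every frequency bin, and (iii) the flat Tukey plateau makes
the configured value hold as a window average, which a Hann taper would
systematically undershoot. The modulated band is widened beyond the
nominal band edges by the analyzer's spectral resolution (3-cycle
wavelets have fractional bandwidth ≈ f/3); without this, power leaking
into the band's bins from just outside would dilute a 3 dB effect to
roughly 2 dB. The default effects are the two the design motivates: a
+3 dB post-feedback parietal delta increase and a −3 dB pre-movement
beta decrease at C3 and Fz, both expressed as visual-minus-memory
differences. Magnitudes are configurable; ±3 dB is a moderate, clearly
super-threshold effect for an 8-subject decoding analysis.

One caveat the tests make explicit: with the conventional (−0.1, 0) s
feedback baseline, the *measured* delta difference is attenuated to
about 2.3 dB for a 3 dB modulation, because 1–2 Hz wavelets (±0.7–1.4 s
support) smear post-feedback effect power into the baseline bins. This
is measurement physics shared with any real ERSP analysis, not a
generator defect, so the generator-recovery test measures the injected
modulation against a far (−1.5, −1.0) s baseline, where it reads back
at 3 ± 0.5 dB, and the decoding analyses use the conventional baseline,
where the attenuated effect is still decisively decodable.

What the generator does *not* emulate: feedback corrections within a
reach, eye movements, artifacts (blinks, line noise beyond the 1/f
background), electrode drift, cross-trial spectral nonstationarity, or
any coupling between behavioral error and EEG power. Passing tests
therefore demonstrate that the analysis chain measures what it claims
on signals with known ground truth — not that real data would show
these effects.

## Numerical choices

- **Very-low-frequency filtering.** The 0.05 Hz high-pass edge of the
  EEG band-pass has a normalized cutoff of 2×10⁻⁴ at 500 Hz; stock
  zero-phase filtering is numerically unusable there (the filter's
  transient spans tens of seconds). The package filters with an
  internal zero-phase routine: demean, odd-reflection padding scaled to
  the filter's time constant, forward–backward application, and
  restoration of the mean through the filter's squared DC gain; the
  high-pass biquad is designed in closed form.
- **Determinism.** Every random stage derives its stream from the
  top-level seed by a fixed arithmetic derivation, so stages re-run
  independently and identical configurations produce identical tables.
  Prediction ties in the decoder and working-set ties in the SMO solver
  break toward the first index.
- **Degenerate inputs.** Constant-zero hand-angle series make the
  state-space design rank-deficient and are reported as unidentifiable;
  zero baseline power is an error rather than an infinite dB value;
  markers too close to a recording edge drop their epochs with a
  warning; a zero difference variance with a nonzero mean difference in
  the paired t test is an explicit error.
- **Problem sizes in the test suite.** The acceptance-style tests run
  the full behavioral design (8 × 2 × 180), 500-replicate parameter
  recovery, 200-dataset decoder calibration with 200-permutation nulls,
  and 50 + 30 end-to-end EEG experiments at a reduced simulation scale
  (30 trials per task, the three parietal channels, 250 Hz, 200
  permutations). These sizes were chosen so the whole loop —
  generation, time–frequency analysis, decoding, inference — is
  exercised at Monte-Carlo tolerances; a +3 dB effect over 30 trials is
  detected with probability near 1, so the reduced scale does not trade
  away power.

## Known limitations

- The state space is single-rate; fast/slow two-rate models, Kalman or
  EM estimation, and explicit-strategy decomposition are out of scope.
- The internal state is identified with the observed hand angle, as in
  the regression-based estimation itself; no latent-state smoothing is
  performed.
- dB baselining is per trial; baselining the trial-averaged power is a
  plausible alternative the package does not currently expose.
- The decoder is linear with a fixed cost; no kernels, no trial-level
  decoding, no temporal generalization.
- The washout block is always visually guided (as in the protocol), so
  task differences in the aftereffect conflate task with washout
  context; the simulation inherits this design property.
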