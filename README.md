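# rotadapt

Simulation and analysis of **gradual visuomotor rotation adaptation**
with EEG decoding, for sensorimotor-learning researchers who want a
fully tested, ground-truth-controlled version of a common experimental
analysis chain: two reaching tasks (visually- vs memory-guided), a
cursor rotation that creeps up by 0.2° per trial to a 20° ceiling, a
trial-by-trial state-space model of implicit adaptation, Morlet
time–frequency analysis of task-modulated oscillations, and
per-time-point task decoding with permutation inference.

## The models at the core

**Behavior.** The internal state x_t (the hand angle, compensatory-
positive) follows the single-rate state-space model

    e_t = r_t − x_t
    x_{t+1} = A·x_t + B·e_t

where r_t is the imposed rotation, A is the retention rate and B the
adaptation rate. `estimateStateSpace()` recovers A and B by regressing
x_{t+1} on (x_t, e_t) without intercept, per subject and task. Reach
kinematics (hand angle at peak y-velocity, RT/MT from a 20 mm/s
y-velocity threshold, 3 SD / 5-trial moving-mean outlier screening) are
computed from 60 Hz trajectories filtered with a zero-phase 20 Hz
Butterworth low-pass.

**EEG.** Recordings are band-passed 0.05–100 Hz with a 50 Hz notch,
epoched ±2 s around reach onset and feedback, decomposed 1–30 Hz with
3-cycle complex Morlet wavelets every 50 ms, dB-normalized against
pre-event baselines, and averaged into delta/theta/alpha/beta bands.
A linear SVM decodes the task type from band power at each 50 ms bin
under leave-one-subject-out cross-validation; chance (median) and the
significance threshold (95th percentile) come from a paired label-flip
permutation null with max-statistic correction across time.

**Generator.** `makeDesign()` / `simulateBehavior()` /
`simulateEEG()` produce the whole synthetic experiment — learner-driven
minimum-jerk trajectories and event-marked 20-channel 1/f EEG with
configurable task-modulated band effects (default: +3 dB post-feedback
parietal delta, −3 dB pre-movement central beta, visual − memory) — so
every analysis can be checked against known ground truth.

## Worked example

```r
library(rotadapt)

sched  <- buildRotationSchedule()          # 0.2 deg/trial up to 20 deg
design <- makeDesign(8, seed = 1)          # 8 subjects x 2 tasks x 180
beh    <- simulateBehavior(design, seed = 1)
kin    <- computeKinematics(beh$trials, beh$trajectories)
sum(kin$excluded)
#> [1] 2

ad  <- sched$phase == "adaptation"
sub <- kin[kin$subject == 1 & kin$task == "visual", ]
fit <- estimateStateSpace(sub$hand_angle_deg[ad], sched$rotation_deg[ad],
                          excluded = sub$excluded[ad])
fit
#> StateSpaceFit: A (retention) = 0.9529, B (adaptation) = 0.2310, R2 = 0.9133
#>   119 usable trial pairs
```

The subject's reaches were generated with A = 0.95, B = 0.25 plus 2° of
motor noise; the fit recovers rates of that magnitude and an R² typical
of a well-behaved subject. Decoding works the same way from simulated
EEG:

```r
rec <- simulateEEGRecording(
  beh$trials[beh$trials$subject == 1 & beh$trials$task == "visual", ],
  eegParams(), seed = 1)
rec
#> EEGRecording: subject 1, visual task
#>   20 channels x 723000 samples @ 500 Hz (1446.0 s), 720 markers
```

`runPipeline(defaultPipelineConfig(), "out/")` chains every stage —
generation, kinematics, fits, rmANOVA/t tests, time–frequency, decoding
— into one artifact directory with a plain-text report; identical
configurations yield identical tables.

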