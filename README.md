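# dyadkin

Imitation-accuracy analysis for actor/imitator dyads recorded with a
multi-tracker 6-DOF motion capture system.

When one person copies another's object-directed actions — here, moving
balls between the pegs of a 4 × 4 pegboard — how faithfully and how quickly
do they do it, and does it matter whether they watch the actor face-to-face
or through a video feed? `dyadkin` answers this with time-series coupling:
for each kinematic variable it shifts the imitator's trace relative to the
actor's, sample by sample over lags of −5 to +5 s, and takes the lag of the
absolute-maximum Pearson correlation,

```
r(ℓ) = corr( actor[t], imitator[t + ℓ] ),    ℓ ∈ [−5 s, +5 s]
```

with |r|max measuring imitation *accuracy* and its lag measuring imitation
*delay* (positive lag = imitator follows). Per-trial correlations are
variance-stabilised with the Fisher transformation, Z = ½ ln((1 + r)/(1 − r)),
averaged across the ten trials of each crossed condition (feedback:
face-to-face/video × difficulty: simple/complex), and compared with
within-subject 2 × 2 tests: univariate contrast F tests (df 1, n − 1) per
variable and Hotelling multivariate tests (df 3, n − 3) for the
joint-angle and grip-position triples.

The seven dependent variables per person are derived from the raw tracker
positions: arm joint angles q1 (shoulder elevation from vertical), q2
(horizontal shoulder–elbow direction vs the y axis), q3 (elbow angle by the
cosine rule), grip aperture (3D index–thumb distance) and 3D grip position
(index–thumb midpoint). Before derivation the recordings pass a fixed
cleaning pipeline: acceleration-based despiking (> 3 SD in the
twice-differenced trace), zero-phase 4th-order Butterworth low-pass at
15 Hz, a 13° in-plane rotation for the video-condition actor's angled
board, a 111 ms latency shift for the video-condition imitator, and
movement-based trial segmentation (> 100 mm index-finger excursions lasting
> 5 s; shorter excursions are false starts).

Because no recorded dyad data ship with the package, a synthetic generator
(`synth_dyad()`) builds full ground-truth sessions: an actor performing
minimum-jerk ball transports over the pegboard and an imitator that is a
lagged, noisy, gain-perturbed copy — including, in the video condition, the
rotated board frame and the video latency the pipeline is built to remove.

## Worked example

```r
library(dyadkin)
d   <- synth_dyad("face_to_face", "simple", seed = 42)   # ground truth: lag 0.67 s, 5 mm noise
fit <- dyad_coupling(d$actor, d$imitator)                # preprocess + segment + lag scan
print(fit)
```

```
Dyad coupling fit: sim1, face_to_face / simple
  10 trials, lag scan +/- 5 s at 240 Hz
       dv r_abs_mean z_mean lag_mean_s
       q1     0.9833 2.4504     0.6737
       q2     0.8499 1.3475     0.6658
       q3     0.9173 1.5812     0.6700
 aperture     0.3941 0.4214     0.4138
   grip_x     0.9954 3.1692     0.6696
   grip_y     0.9968 3.2831     0.6683
   grip_z     0.9948 3.0180     0.6696
```

Each row is one dependent variable: `r_abs_mean` is the across-trial mean
absolute-maximum correlation between actor and imitator (grip position is
almost perfectly copied; aperture, whose few-mm range is comparable to the
copying noise, couples weakly), `z_mean` its Fisher-Z mean, and
`lag_mean_s` the mean lag at maximum — recovering the generator's imposed
0.67 s delay to a few milliseconds. `coef(fit)`, `summary(fit)` and
`plot(fit)` give the coefficient matrix, trial diagnostics and per-trial
box plots. Fits for every person × condition feed
`build_condition_table()` and then `rm_2x2_test(table, "grip_position", "Z")`
for the 2 × 2 feedback-by-difficulty tests.

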