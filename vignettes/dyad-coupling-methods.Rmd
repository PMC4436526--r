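---
title: "Measuring imitation accuracy in dyads: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring imitation accuracy in dyads: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadkin)
```

`dyadkin` quantifies how accurately and how quickly an imitator copies an
actor's object-directed movements, from continuous 240 Hz recordings of
seven 6-DOF trackers per person (head, shoulder, elbow, wrist, thumb,
index, little finger; x/y/z in mm, azimuth/elevation/roll in degrees). This
vignette explains the model behind every pipeline stage, the parameters
that matter, what the synthetic generator does and does not emulate, and
the numerical decisions that were genuinely open.

## The coupling model

The unit of analysis is one trial of one actor/imitator pair on one
kinematic variable. Accuracy is not defined as pointwise error — the
imitator is always behind the actor by a variable reaction delay — but as
the best achievable linear correspondence over time shifts: the imitator's
series is shifted relative to the actor's, sample by sample across lags of
−5 to +5 s (±1200 samples), and at each lag a Pearson correlation is
computed on the overlapping samples. The absolute maximum |r| over lags
measures how faithfully the movement *shape* was copied; the lag at that
maximum measures the imitation delay. Positive lag means the imitator
follows the actor.

Two choices here were open and are fixed as follows:

* **Overlap-only correlation.** At lag ℓ only the `n − |ℓ|` overlapping
  samples enter, with that overlap's own means and variances. Zero-padding
  would shrink correlations toward zero at large lags; global
  normalisation would let level differences between overlap windows
  masquerade as coupling. Lags whose overlap falls below
  `min_overlap_frac` (default 0.5) of the trial are undefined (NaN): on a
  20 s trial a ±5 s scan otherwise produces spuriously high |r| from
  near-empty overlaps.
* **Tie-breaking.** Equal |r| is resolved toward the smallest |lag|, then
  toward the negative lag — the most parsimonious alignment. Ties occur in
  practice only on degenerate (constant or perfectly periodic) inputs.

Per-trial correlations are aggregated per condition with the Fisher
transformation Z = ½ ln((1 + r)/(1 − r)). The transform is applied to the
*absolute* maximum r (so Z ≥ 0) and — by default — per trial, before
averaging (`z_before_mean = TRUE` in `dyad_coupling()`). Averaging r first
and transforming once is the other defensible reading of
"mean r converted to Z"; it is one flag away. Perfect correlations, which
noiseless synthetic dyads do produce, are clipped to 1 − 1e−7 before the
transform, with a warning count.

## The seven dependent variables

Joint angles compress the nine arm-marker coordinates into three series,
all via arc cosine with arguments clamped to [−1, 1] (clamping only
absorbs round-off at collinear configurations; its effect is below
1e−15):

* `q1 = acos((z_S − z_E)/|ES|)` — shoulder elevation from the downward
  vertical; an elbow directly below the shoulder gives 0°.
* `q2 = acos((y_S − y_E)/|EO|)` with |EO| the horizontal (x, y) magnitude
  of the shoulder–elbow displacement — the horizontal direction of the
  upper arm against the y axis.
* `q3 = acos((|SW|² − |ES|² − |EW|²)/(2·|ES|·|EW|))` — the cosine-rule
  elbow angle. Note the convention: this expression yields 0° for a fully
  extended arm and 90° for a right angle at the elbow, i.e. 180° minus the
  triangle's interior angle. It is often *called* the inner elbow angle;
  the formula is implemented as printed and the naming discrepancy is
  noted here rather than silently "fixed".

Grip aperture is the 3D index–thumb distance; grip position their
per-axis midpoint. All seven series have exactly the recording's length,
so trial windows index into them unchanged. Angles are reported in
degrees; no wrist rotation is modelled (a 6-DOF wrist tracker exists, but
`q3` deliberately ignores forearm roll).

## The preprocessing pipeline

Order is fixed: despike → low-pass filter → rotation (actor, video
condition) → latency shift (imitator, video condition) → trial
segmentation. Orientation channels are unwrapped to continuous angles
before anything differentiates them, are despiked and filtered like
positions, but are *not* rotated — the rotation formulas involve x and y
positions only.

**Despiking** (threshold 3 SD). Electromagnetic trackers emit isolated
single-sample glitches. These are located in the twice-differenced series
(acceleration), where a single-sample spike of amplitude A appears as a
(+A, −2A, +A) triplet. Samples whose acceleration deviates more than 3 SD
from the acceleration mean are flagged — the SD taken over the whole
continuous session, since despiking precedes trial definition — and each
flagged sample is repaired in the original series by linear interpolation
across the bracket two samples either side (replacing the flag and its
immediate neighbours). Because one spike contaminates three consecutive
acceleration samples, contiguous supra-threshold runs are merged and
flagged once, at the run's largest deviation; the second difference is
left-aligned and the stencil centre maps back to the original series as
index + 1. Detection is a single pass. A sanity check on the threshold: a
sinusoid's acceleration extremes sit at √2 ≈ 1.41 SD from its mean, so
clean oscillatory movement is never flagged. If the repaired samples
exceed 10% of the series a warning marks the series as likely corrupt.

**Filtering** (Butterworth, order 4, cutoff 15 Hz, fs 240 Hz). Applied
forward and backward for zero phase shift, so the amplitude response acts
twice: the half-power cutoff becomes a half-*amplitude* point (ratio
0.50 at 15 Hz), and 60 Hz — two octaves up — is attenuated below 1e−2.
Edges use odd-reflection padding of length 3·(order + 1) with DC
steady-state initial conditions, so a constant series passes through
bit-for-bit to 1e−9; the padding choice affects only edge samples.
Voluntary arm movement lives below ~10 Hz, so the passband is generous.

**Rotation** (13°). In the video condition the actor's board is angled
13° for the camera; `x' = x cos13 − y sin13`, `y' = y cos13 + x sin13`
per sample restores the task frame. In a standard right-handed frame
these formulas are a counterclockwise rotation even though the protocol
describes the correction as clockwise; the axis orientation of the
recording frame is not observable from the data, so the printed formulas
are taken as authoritative and their inverse is what the synthetic
generator applies when it stores a video-condition actor.

**Latency shift** (111 ms). The video chain delays what the imitator
sees; their data are advanced by `round(0.111 × 240) = 27` samples, the
vacated tail repeated from the final sample. Sub-sample resampling is
deliberately avoided — a 0.36 ms residual is far below any behavioural
delay of interest.

**Trial segmentation** (100 mm, 5 s). Trials are timed to the actor's
movement, not the trial clock: maximal runs with the index fingertip more
than 100 mm (3D) from the start marker, lasting more than 5 s, are
trials; shorter excursions are false starts; at most the first 10 windows
are kept. The actor's windows are applied to the paired imitator, who was
instructed to start with the actor.

## The 2 × 2 condition tests

Per person and crossed condition (feedback × difficulty) the mean Z and
mean lag per variable form the condition table (`build_condition_table()`
refuses incomplete designs). `rm_2x2_test()` computes within-subject
effects from per-person contrasts: for each effect (feedback margin,
difficulty margin, their interaction) the univariate F is the squared
paired t on the n contrast values (df 1, n − 1; partial η² =
F/(F + n − 1)), and the multivariate test on a variable triple is the
one-sample Hotelling T² on the n × 3 contrast matrix, reported as
F = (n − p)/(p(n − 1))·T² with df (p, n − p) — (3, 9) at n = 12 — and
partial η² = T²/(T² + n − 1), which equals the Pillai trace. With a single
within-subject contrast per effect all classical multivariate statistics
coincide, so the choice of "which MANOVA statistic" is moot; the tests are
validated against `aov()` error strata and the `anova.mlm` Pillai route.
Single-df within-subject effects need no sphericity correction, and none
is applied.

## What the synthetic generator emulates

`synth_actor()` builds the full session: 10 trials of 20 s with 5 s rests
(58 800 samples at 240 Hz). Each trial samples a legal move sequence —
10 moves between adjacent pegs, one ball (simple) or all three balls
(complex), destinations unoccupied — and threads the grip position through
minimum-jerk segments (`s(τ) = 10τ³ − 15τ⁴ + 6τ⁵`) with via-points 30 mm
above the taller peg of each transport, because the task requires low
arcs touching the pegs. Motion fills a uniformly drawn 85–95% of the
trial, split evenly across segments: the protocol never states movement
speed, so segment durations are free parameters of the generator. The
aperture opens and closes around grasps (40 mm on the ball, 10 mm on the
start marker); fingertips sit at ±aperture/2 along x around the grip
position; wrist and little finger ride at fixed offsets; the elbow comes
from two-link inverse kinematics (upper arm 300 mm, forearm 260 mm,
shoulder essentially static 150 mm behind and 400 mm above the board,
elbow-down solution) — plausible adult dimensions chosen once, needed
only to produce smooth in-range joint angles. Orientation channels are
low-amplitude smoothed signals driven by each tracker's velocity; they
make all 42 channels analysable but are not biomechanically meaningful.

`synth_imitator()` is the behavioural model: each channel delayed by the
(sample-rounded) true lag, scaled by a gain about its mean, plus Gaussian
noise low-passed at 6 Hz so the copying error itself has kinematic
smoothness; vacated edges hold the rest posture. The per-feedback
scenario defaults (`dyad_scenario()`) are the study conditions: lag
0.67 s and 5 mm noise face-to-face, lag 0.79 s and 12 mm noise under
video — lags taken from the observed grip-position condition means, noise
chosen once as a plausible hand-path copying error with video worse than
face-to-face. Video dyads additionally store the actor in the
13°-rotated frame and add the 111 ms latency to the imitator, so the
full preprocessing chain is exercised end to end.

Ground truth records the effective (rounded) lag, noise, gain, move
sequences and trial windows, the latter defined by task geometry: the
interval the index finger is beyond the 100 mm start radius in the
noiseless trajectory. The start marker sits 128 mm from the nearest peg,
so rest and play are cleanly separated by the detection radius.

What the generator does **not** emulate — and what passing tests
therefore cannot show about real data: muscle dynamics and speed–accuracy
structure in the actor; imitator errors that are anything other than
additive filtered noise (no segment omissions, anticipations of known
move patterns, or spatial distortions); soft-iron/drift distortions of
the electromagnetic field beyond single-sample spikes; camera optics.
Real-data conclusions rest on the pipeline's correctness, which the
synthetic route verifies, not on the generator's realism.

## Numerical choices and degenerate inputs

* Lag-scan sums use globally centred series with prefix sums plus a
  per-lag overlap product — numerically safe and exact to 1e−10 against a
  definitional per-lag Pearson loop; r is clamped to [−1, 1].
* Zero-variance overlaps, and windows shorter than the scan, yield NaN
  and are excluded from trial averages with a message; an everywhere-NaN
  curve is an error.
* Degenerate arm configurations (zero-length |ES|, |EW| or horizontal
  projection) yield NaN samples and a warning above 1% incidence.
* `fisher_z()` refuses |r| ≥ 1 outright; aggregation clips at 1 − 1e−7.
* The CSV writer emits 17 significant digits, enough for lossless
  double round trips; the reader is header-driven, rejects ragged rows,
  non-numeric cells and non-finite values with the offending location,
  and never imputes gaps (the tracker streams continuously; a gap means
  a broken file).

## Problem sizes in the tests

The shipped tests generate everything at run time. Full-scale sessions
(10 × 20 s) are used where the contract demands them — lag recovery
across true lags 0.1/0.3/1.0 s and the face-to-face-vs-video direction
recovery over 10 seeded replicates — while structural checks (move rules,
surfaces, noise monotonicity) run on reduced sessions of 2 × 8 s trials,
which exercise identical code paths. Test calibration of the
within-subject tests uses 1000 simulated null tables at n = 12, matching
the design's person count; the expected 5% rejection is checked within
±2 percentage points.

## Known limitations

* The lag scan assumes one dominant alignment per trial; systematically
  varying delay within a trial (speeding up after a slow start) is
  summarised by a single compromise lag.
* |r|max is biased upward for short windows and slowly varying signals;
  comparisons are therefore always within-design, between conditions of
  identical trial structure.
* The q3 convention (0° = straight arm) must be kept in mind when
  comparing with goniometric conventions.
* Orientation channels pass through the full pipeline but their synthetic
  counterparts are placeholders; tests make no biomechanical claims
  about them.
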