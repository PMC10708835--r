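---
title: "Methods: predicting lower-limb joint torque from sEMG and joint angles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting lower-limb joint torque from sEMG and joint angles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gaittorque)
```

## The problem

During walking, the net torque at the hip, knee and ankle in the sagittal
plane is normally obtained by inverse dynamics, which needs force-plate
measurements of the ground reaction force. Outside the laboratory those are
unavailable. `gaittorque` predicts the torque from two signals that *are*
wearable: surface electromyography (sEMG) of five leg muscles — gluteus
maximus (GMX), rectus femoris (RF), biceps femoris (BF), tibialis anterior
(TA) and gastrocnemius (GC) — and the three joint angles. Two regressors are
compared on a leave-one-gait-cycle-out protocol: a stacked LSTM sequence
model and exponential-kernel Gaussian process regression (GPR).

## Signal pathway

Raw sEMG (2000 Hz) is band-pass filtered to 20–450 Hz with a 4th-order
Butterworth design applied forward and backward (`bandpass_zero_lag()`), so
the filter has zero phase lag. Seven features are then computed on sliding
windows: five time-domain features — mean absolute value, root mean square,
zero crossings (strict sign changes), slope sign changes (strict interior
extrema) and waveform length — on a 150 ms (300-sample) window, and two
frequency-domain features — mean and median frequency of the one-sided
rectangular-window periodogram with the DC bin excluded — on a 128 ms
(256-sample) window.

Two windowing choices are deliberate and worth stating:

* **Hop = 20 samples (10 ms).** The feature series then lands natively on
  the 100 Hz kinematic grid, so no second resampling step is needed.
* **Right-aligned (causal) windows.** The feature stamped at time *t* uses
  only samples up to *t*. Combined with the one-step (10 ms) prediction
  horizon this keeps the whole pipeline causal: the torque at *t* + 10 ms is
  predicted from data available at *t*.

The 35 sEMG features plus the three joint angles form a 38-dimensional input
row per 100 Hz time step. Every column (inputs and torque targets alike) is
peak-normalized — divided by its maximum *absolute* value over the
**training rows only** — which prevents test-set leakage and is well defined
for signed signals. The three reported metrics are invariant under this
common positive rescaling, so evaluating on normalized or physical-unit
torque gives identical numbers.

ZC and SSC use strict inequalities and no amplitude deadband. The
non-strict sign conventions sometimes printed for these features would count
every non-crossing pair (for ZC) or every flat plateau (for SSC); the strict
forms are the standard definitions, and an explicit deadband of zero is the
only defensible default when none is specified.

## Models

**LSTM.** Three stacked LSTM layers of 32, 16 and 8 units; the first two
emit full hidden sequences, the third only its last hidden state, followed
by a sigmoid layer and an affine map to one output. Inputs are sequences of
5 time steps (50 ms). The forward pass implements the standard gate
equations (forget/input/output gates through the sigmoid, candidate cell
through tanh, cell update `c_t = f ⊙ c_{t-1} + i ⊙ c̃`, output
`h_t = o ⊙ tanh(c_t)`) with `c_0 = h_0 = 0`; the backward pass is exact
backpropagation through time, written out by hand and verified against
central finite differences to a relative error below 1e-5. Training is
full-batch Adam for 500 epochs, initial learning rate 0.005 multiplied by
0.2 every 125 epochs, with global-L2-norm gradient clipping at 1. Choices
the training description leaves open were resolved as follows: loss is mean
squared error (the standard regression loss); clipping is interpreted as
global-norm scaling (per-tensor clipping is a config alternative); the
learning-rate drop is periodic rather than one-shot, matching the
deep-learning-toolbox idiom of a piecewise schedule; weights are
Glorot-uniform (input), orthogonal (recurrent) and zero (bias), seeded;
batches are full-batch since the training sets are only ~430 samples.
Everything runs in 64-bit floats so the gradient check is meaningful.

**GPR.** One-step inputs (the feature row at *t* predicts the torque at
*t* + 10 ms). The kernel is the exponential (Ornstein–Uhlenbeck) covariance
`k(x, x') = σ_f² exp(−‖x − x'‖/ℓ)` on standardized inputs, with a constant
basis and additive Gaussian noise σ². The basis coefficient β is profiled
out by generalized least squares inside every likelihood evaluation — the
standard treatment of fixed basis functions. Hyperparameters maximize the
log marginal likelihood through a Cholesky factorization (never an explicit
determinant), with analytic gradients and L-BFGS-B from five starts: a
data-driven start (ℓ at the median pairwise distance, σ_f² = var(y),
σ² = 0.1 var(y)), a noise-dominated start (σ² = var(y)) because the
likelihood surface has a separate all-noise mode, and seeded random
perturbations. The length scale is bounded below by the 1st percentile of
pairwise distances: scales below the close-pair spacing make the kernel
indistinguishable from observation noise and are not identifiable. On
factorization failure a diagonal jitter of 1e-10 σ_f² grows tenfold up to
1e-4 σ_f².

Predictions report both latent and observation 95 % intervals; the plotted
band is the observation interval (mean ± 1.96 √(latent variance + σ²)),
which is the band that should contain ~95 % of new measured torque samples.
Whether published torque-prediction intervals are latent or observation
intervals is usually ambiguous; the observation interval is the one that can
be checked against held-out data, and coverage calibration is asserted in
the test suite.

## Synthetic study conditions

No public gait dataset accompanies the protocol this package implements, so
a generator (`make_gait_dataset()`) produces trials with the statistical
structure the analysis needs. Defaults emulate slow treadmill walking: 4
subjects × 5 gait cycles, cycle period 1.1 s (a typical stride time at
0.8 m/s; the speed–period mapping is a configurable default, not a measured
value), sEMG at 2000 Hz, kinematics and torques at 100 Hz.

* **Kinematics.** Each joint angle is a truncated 4-harmonic Fourier series
  with per-subject random amplitudes and phases inside physiological
  excursion bounds (hip ±15–25°, knee 30 ± 20–30°, ankle ±8–15°). The
  series' derivatives are analytic, and the trajectory is exactly periodic.
* **Torques.** Inverse dynamics of a planar three-link chain (thigh, shank,
  foot; per-subject segment parameters jittered ±10 %) hanging from the
  hip: `τ = M(q) q̈ + C(q, q̇) + G(q)` assembled from analytic COM Jacobians
  and Christoffel symbols. The chain is a swing-limb proxy — ground
  reaction forces are deliberately not modeled, since the pipeline only
  needs a dynamically consistent torque signal to learn. Angles are in
  radians internally (degrees in configs), flexion positive.
* **sEMG.** Each muscle's activation envelope mixes the rectified torque of
  its joint (with flexor/extensor sign) and a Gaussian burst at a
  muscle-typical gait phase (weights 0.6/0.4). The envelope multiplies a
  unit-variance Gaussian carrier band-limited to 20–450 Hz, plus baseline
  noise at 1/40 of the full-activation amplitude (≈32 dB, typical of modern
  wireless sensors). The carrier is a variance-preserving mixture of a
  20–80 Hz and a 250–450 Hz sub-band whose balance moves linearly with
  activation — a stylized version of the upward spectral shift that motor
  unit recruitment produces in real sEMG. Without this shift the spectral
  features (ZC, SSC, MNF, MDF — 20 of the 38 input dimensions) would carry
  only single-window estimation noise, which an isotropic kernel cannot
  down-weight, and the generator would fail its purpose of producing
  feature sets that are informative about torque.

What the generator does **not** emulate: cycle-to-cycle kinematic
variability (cycles repeat exactly; only the sEMG noise differs), fatigue
drift, motion artifacts, crosstalk between muscles, load sharing among
synergists, and ground-contact dynamics. Passing the packaged performance
bounds therefore shows that the pipeline is implemented correctly and can
extract torque information from realistic signal *structure*; it does not
certify performance on real recordings.

## Evaluation

Of the 5 cycles per subject, 4 train and the last is held out (configurable;
a leave-one-cycle-out sweep is available by looping over `test_cycle`).
Supervised samples whose input window or target straddles the train/test cut
are dropped from both sides, and the test suite audits exhaustively that no
training sample touches a held-out row. Metrics per subject × joint × model:
NRMSE (RMSE over the true range, in percent, with the range taken from the
true series), Pearson R, and R² = 1 − SSE/SST (which can be negative for a
predictor worse than the mean). Per-joint averages over subjects are
appended as an "average" row, and one LSTM plus one GPR model is trained per
subject and joint — 12 of each under the default conditions.

## Problem sizes and numerical notes

Default-scale fits are modest by design: ~437 training rows per subject,
38-dimensional inputs, 500 LSTM epochs, exact (non-sparse) GPR at N ≈ 436.
A full default run (24 models) completes in a few minutes on one CPU core.
Degenerate inputs are handled explicitly: constant feature columns hit a
standardization scale floor rather than dividing by zero; a constant window
yields NaN spectral features (zero non-DC power) and an error in the
standalone spectral functions; predictive variances are clamped at zero
after round-off; and self-distances in the kernel are floored to exactly
zero before the square root, which would otherwise amplify cancellation
error on the kernel diagonal.

Reproducibility is end to end: one master seed per dataset derives
per-subject seeds; model initialization and optimizer restarts are seeded;
two runs from the same configuration produce bit-identical CSV outputs.

## Known limitations

* The exactly periodic kinematics make the held-out cycle an in-distribution
  repetition; real gait has stride-to-stride variability that would lower
  all metrics.
* The isotropic exponential kernel cannot learn per-dimension relevance;
  its accuracy on these inputs depends on the spectral features carrying
  real signal (see above).
* The swing-limb torque proxy omits ground reaction forces, so absolute
  torque magnitudes are not comparable to stance-phase inverse dynamics.
* Single-joint (scalar-output) models only; no inter-subject transfer.
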