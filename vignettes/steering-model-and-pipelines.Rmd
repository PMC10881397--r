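---
title: "Goal-directed steering: the network model and the analysis pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Goal-directed steering: the network model and the analysis pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flysteer)
```

# The scientific problem

A walking fly can hold an arbitrary goal heading for minutes, steering
back after perturbations. The circuit thought to implement this reads
the head-direction system's sinusoidal activity map through three
columnar output populations — PFL3R, PFL3L and PFL2 — whose
head-direction maps are anatomically shifted by +67.5, −67.5 and 180
degrees relative to the reference map. Each population also receives a
shared, sinusoidal goal input. Summed population outputs converge on
descending neurons: PFL3 directly onto DNa02 (the steering command,
right minus left), and PFL2 plus PFL3 onto DNa03, which feeds DNa02
with a strong weight. Because PFL2's map points at the *anti-goal*,
PFL2 activity rises with |directional error| and, through the shared
expansive nonlinearity, raises the gain of the steering command
exactly when the animal is far from its goal — an adaptive-gain
controller that is gentle near the goal and vigorous near the
anti-goal.

`flysteer` implements this model and the analysis pipelines used to
relate it to tethered-fly data: circular statistics for goal direction
and consistency, spherical-treadmill kinematics preprocessing, path
segmentation, cue-jump classification, sinusoidal bump fitting for
columnar calcium imaging, and membrane-potential analyses including
IPSP detection. A synthetic-data module generates behaviour, imaging
and electrophysiology fixtures with recorded ground truth, so every
pipeline is exercised by parameter-recovery tests.

# The network model

## Inputs and populations

Each population has `nUnits` units (default 1000) whose preferred
directions `h` uniformly tile 360°. Unit inputs are

- head-direction input: `cos(theta - theta0 - h + shift)` with `shift`
  = +67.5° (PFL3R), −67.5° (PFL3L) or 180° (PFL2); `theta0` is the
  arbitrary, fly-specific offset of the head-direction map;
- goal input: `A cos(theta_g - theta0 - h)`, identical across the
  three populations (default amplitude `A = 1`).

The sum is scaled by the factor `S` (0–1) and passed through the
calibrated activation. Descending neurons take weighted sums of
population outputs — weights 1 (PFL3→DNa02, PFL3→DNa03), 4
(PFL2→DNa03) and 12 (DNa03→DNa02), the connectome-derived ratios —
through the same activation. Steering is
`d(theta)/dt = gain * (DNa02R − DNa02L) + epsilon`, positive =
clockwise.

## Population scaling

There are 12 cells per PFL class in the brain; the model's `nUnits` is
a discretization resolution, not a cell count. Summed population
outputs are therefore scaled by `12 / nUnits`. This keeps the
per-connection weights meaningful whatever the resolution: with raw
sums over 1000 units the direct PFL3 pathway would outweigh the fixed
DNa03→DNa02 weight by almost two orders of magnitude, the indirect
pathway would become negligible, and — decisively — the claim that
discretizing to 12 units changes nothing could not hold, since raw
sums scale with the unit count. With per-capita scaling the 12-vs-1000
summed-activity curves agree to a fraction of a percent
(`test-model-network.R` asserts < 1% of the curve range).

## Activation calibration

All units share one nonlinearity, by default an exponential linear
unit: `ELU(m) = m` for `m ≥ 0`, `exp(m) − 1` below. Per cell type, the
input ensemble — all head directions, goal directions, the configured
`calibrationS` values (default 0–1 in steps of 0.25) and all units —
is mapped affinely onto [−1, 1] before the ELU, and the output is
mapped onto [0, 1]. Because the preferred-direction grid tiles the
circle uniformly, the ensemble extrema depend only on the directional
error, so calibration sweeps a 1° error grid rather than the full
(theta, theta_g) product.

Two consequences are worth knowing:

- The calibration ensemble defines the model variant. An ablated run
  (direct- or indirect-pathway-only) is its own model, so
  `simulateClosedLoop(pathway = "direct")` recalibrates DNa02 over the
  ablated ensemble; `openLoopProfiles()`'s per-pathway drive
  decomposition instead keeps the full-model calibration and zeroes
  the other pathway's term, which answers a different question (how
  much each pathway contributes inside the intact model).
- Alternative activations: `"relu"` preserves the drive's sign
  structure but clips a dead zone around the goal to exactly zero.
  A logistic centred on the calibrated range would be odd-symmetric,
  making every population sum amplitude-independent and abolishing
  the error signal entirely; the package's `"sigmoid"` is therefore
  an expansive logistic with its inflection at the calibrated
  maximum. `"identity"` gives the linear reference case in which the
  bilateral PFL2 term cancels exactly out of the DNa02 difference.

## Steering gain and integration

The proportionality constant between the DNa02 difference and turning
velocity is not constrained by anatomy; the default calibrates it so
the peak noise-free open-loop drive at `S = 1` is 200 deg/s, the order
of fast fly turns. Integration is explicit Euler at `dt = 0.1` s (a
10 Hz update), heading wrapped after every step. The noise term is a
frozen sample: Gaussian draws low-pass filtered at 2 Hz with a
second-order Butterworth applied forward-backward (zero phase; the
filter family is a package choice, stated here because only the
cutoff is conventionally reported), then rescaled to an exact sample
SD of 10 deg/s. Equal seeds give bit-identical traces.

## What the closed loop shows

With noise off, the full model converges from 60° of error to under 5°
within 10 s across the working range of `S`, monotonically. With the
indirect pathway removed (and the ablated model calibrated on its own
ensemble), the near-goal slope of the drive is no longer throttled by
PFL2, and at high `S` the heading overshoots, reversing the sign of
the error — the instability the adaptive gain exists to prevent. In
the sweep over `S` and noise seeds, the consistency of heading rho
(computed over the full 100 s run; no transient is excluded) rises
with `S`, and correlates positively with the bump-amplitude range
measured from the model's own PFL2 units by the same sinusoid fit the
imaging pipeline uses.

# Analysis pipelines

## Circular statistics

All angles are degrees in (−180, 180], 0° = facing the cue, positive
clockwise; radians exist only inside trig calls. The goal direction is
the two-argument-arctangent mean of unit vectors, consistency rho the
mean resultant length. A resultant below 1e−9 flags the mean as
undefined rather than returning an arbitrary angle. Binned argmaxes
everywhere break ties toward the smallest bin.

## Kinematics

Ball positions are unwrapped, low-pass filtered (second-order
Butterworth; the corner is interpreted as a fraction of Nyquist at the
acquisition rate and exposed as `butterCorner` because the units of
the conventional "0.003" are ambiguous), differentiated, clipped at
20 rad/s, smoothed by local quadratic regression over 33 ms (a
Savitzky-Golay filter; exact equivalence to any particular loess
implementation is not promised and tests use signals where reasonable
smoothers agree), resampled to 60 Hz and converted via the 4.5 mm ball
radius. Cumulative speed (|forward| + |sideways| + |rotational|, ball
rad/s) above 0.67 rad/s defines mobility. Heading out-of-range values
are clamped to ±180 as acquisition convention dictates, with a wrap
option; circular statistics re-wrap internally regardless.

## Goal, segments, jumps

The sliding goal/consistency uses a centred 30 s window, excluding
immobile samples and the 5 s after each cue jump; empty windows are
missing. Segmentation breaks at downward rho crossings of 0.88, lumps
dips shorter than 0.5 s, discards segments with rho pinned at 1
(frozen cue; detected with a 1e−9 tolerance because rolling sums are
floating point) and segments without 2 s of continuous mobility.
Jumps are excluded without 1 s of continuous pre-jump mobility;
corrected means heading returned to within 30° (±90° jumps) or 60°
(180° jumps) of its 15 s pre-jump circular mean within 10 s; the
"fast" variant (40°/75° within 4 s) selects rapid responders for the
lag analyses; high rho means mean pre-jump consistency ≥ 0.88 over
mobile samples.

## Imaging

dF/F uses the bottom-decile mean as baseline; the z layer is the
median/raw-MAD normalization, so median 0 and MAD 1 per ROI hold by
construction. The bump is fit per frame as `a sin(x − u) + c` by
linear least squares on a sin/cos basis (closed form, deterministic;
amplitude is non-negative by construction, so no fold is ever
needed); ROI centres sit uniformly over one brain-space cycle with
+180 rightmost, whatever the ROI count. Fits with 3-parameter
adjusted r² below 0.1 are invalid and excluded downstream. The neural
goal is the head-direction bin (5° wide) on the small-amplitude side
of the opposing-bin pair with the largest amplitude difference.
Phase-versus-heading coupling differentiates within 1.5 s bins using
shortest-arc differences, with the phase series lagged 200 ms behind
heading by default.

## Electrophysiology

Baseline Vm: 50 ms median filter then 20 ms local quadratic smoothing.
Spike detection (a method this package supplies; the upstream
convention does not specify one) thresholds the residual at 4 robust
SDs with a 1 mV floor and 2 ms refractory. IPSPs: despike (25 ms
median, 20 ms smoothing), take the derivative, detrend against a
500 ms median filter, find negative peaks of both traces (20 ms
minimum separation) and accept a detrended peak only when a
derivative peak falls within the preceding 30 ms. Thresholds are
per-cell: 2 and 3 noise MADs, re-estimated by iterated masking of
detected events because event-laden traces inflate a single-pass MAD.
The Brown-Forsythe comparison of jump-evoked dVm distributions is the
median-centred Levene F test; the goal-offset analysis bins segments
(rho ≥ 0.7) by theta_g − theta_p into 72° bins, recomputes 20° tuning
curves over theta − theta_p, optionally min-subtracts, and mirrors
PFL3L offsets before pooling.

# The synthetic-data module

Generators emulate the experimental protocol: 600 s trials, a cue
jump every 60 s cycling +90°, 180°, −90°, closed-loop yaw gain 0.7.
Behaviour comes either from the network model in closed loop (linking
behavioural recovery to `S`) or from a scripted mean-reverting
angular process toward the goal (default reversion 1.5 /s, angular
noise 30 deg/√s, giving consistency around 0.95 — a typical
well-fixating fly), so behaviour-pipeline tests do not depend on
model correctness. Forward velocity is autoregressive noise around
8 mm/s (translation statistics are not constrained by the emulated
experiments; these are plausible walking values). Calcium fixtures
are sinusoidal bumps phase-locked opposite to heading with a chosen
amplitude law and Gaussian noise on the z scale; photon statistics,
bleaching and motion artefacts are not modelled, so passing recovery
tests demonstrates correctness of the analysis logic, not robustness
to every imaging nuisance. Vm fixtures combine cosine tuning,
heading-modulated Poisson IPSPs (instant drop, tau 15 ms, amplitudes
0.5–2 mV — plausible ranges, as no reference values exist), optional
spikes and smoothed noise. The IPSP rate law is fixed so the rate is
highest when heading equals the preferred direction; only the sign
convention matters to the analyses and it is recorded in the ground
truth. Every generator is seed-deterministic.

# Known limitations

- At IPSP rates ≥ 14 Hz the 500 ms median detrending tracks the
  events themselves, individual deflections shallow, and detection
  becomes a systematic undercount (about −30% at 14 Hz and worse at
  20 Hz even with oracle thresholds); within the 2–8 Hz range typical
  of the quiescent recordings the rate estimate stays within 10% of
  truth. This is a property of the published detection scheme, which
  the package reproduces deliberately.
- The Brown-Forsythe test is conservative at small group sizes (true
  type-I error ~0.033 at 15 per group, ~0.044 at 50); the calibration
  test uses 50 per group.
- The model's rate units and steering gain are conventions; only
  curve shapes, signs and orderings are meaningful, and the package's
  qualitative claims hold over a wide range of gains.
- Off-grid `theta0` values break the rotational symmetry of the unit
  grid at the 1e−11 level for 1000 units (trapezoid-rule error of a
  piecewise-smooth integrand); all invariance tests pass at 1e−9.

# Problem sizes used in the test suite

Closed-loop runs are 10 s (convergence) and 100 s (sweeps) at 10 Hz;
the sweep uses 50 seeds at S ∈ {0, 0.2, 0.5, 0.8}. Synthetic trials
are 120–600 s at 60 Hz; Vm fixtures 60 s at 1 kHz; Monte-Carlo
calibrations use 300–1000 replicates. These sizes put every
statistical assertion comfortably past its noise floor while keeping
the default suite fast on a laptop.
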