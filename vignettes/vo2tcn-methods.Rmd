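---
title: "Predicting oxygen uptake from wearable signals: model and methods"
author: "vo2tcn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting oxygen uptake from wearable signals: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vo2tcn)
```

## The prediction problem

Oxygen uptake (VO2, ml/min) is the reference measure of aerobic metabolic
rate, but measuring it requires breath-by-breath gas exchange equipment.
During cycling exercise, VO2 responds to work-rate changes with
approximately mono-exponential kinetics (time constant typically 20-30 s in
healthy adults) that are asymmetric between exercise onset and recovery.
Wearable signals — heart rate (HR), heart-rate reserve (HRR), breathing
frequency, and minute ventilation (VE) — track metabolic rate but with
their own, generally slower, kinetics, particularly during recovery.

`vo2tcn` predicts second-by-second VO2 from the 1 Hz feature set
\{work rate, VE, breathing frequency, HR, HRR\} with a temporal
convolutional network (TCN).  Because an instantaneous ("no history")
predictor cannot distinguish the on-transient from the off-transient state
of the system, it systematically overestimates VO2 during recovery; a
model with an adequate receptive field resolves this by construction.

## Network architecture

The model is a stack of residual blocks, each a sequence of
(dilated causal 1-D convolution, layer normalization, ReLU, dropout)
repetitions.  Dilation factors double across the convolution layers
(1, 2, 4, ..., 2^(N-1)), giving the receptive field

    RF = 1 + (k - 1)(2^N - 1)

for kernel size `k` and dilation depth `N` (in seconds at 1 Hz).  Layers
are grouped into residual blocks as successive pairs of dilations; when N
is odd the first three dilations form one block.  The skip path of the
first block is a biased 1x1 convolution because the channel count changes
from the number of input features to the number of filters; later blocks
use identity skips.  After the last block, the final time step is spliced
out and mapped to a scalar by a biased dense layer with linear activation.

Design details the architecture fixes, and why:

* **Parameter accounting.** Per convolution layer the trainable tensor is
  `k * c_in * f + f` (biased convolution) plus `2f` (layer-norm gain and
  offset); the first-block skip holds `c_in * f + f`; the head holds
  `f + 1`.  This accounting reproduces the parameter counts of all five
  reference configurations of this architecture family exactly
  (e.g. 19,921 for f = 24, k = 8, N = 5 with five input features), which
  is how the remaining ambiguities (biases present everywhere, one
  normalization per convolution, skip only in the first block) were fixed.
  `count_parameters()` is tested against the built model for all 200 grid
  configurations.
* **Layer normalization over channels.** Normalizing across the channel
  dimension at each time step keeps the network strictly causal (no
  statistic mixes time); gain and offset are per-channel (2f parameters,
  which the parameter accounting confirms).
* **No activation after the residual addition** — parameter-neutral and
  common TCN practice; the parameter counts cannot distinguish it.
* **Dropout after every convolution's activation**, matching the stated
  repetition order of the block.
* **Initialization.** Uniform fan-in initialization,
  U(-1/sqrt(fan_in), 1/sqrt(fan_in)), with a recorded seed; layer-norm
  gain 1, offset 0.

The no-history configuration (k = 1, receptive field 1 s) is expressible
in the same family and serves as the point-wise baseline.

## Preprocessing

Raw breath-by-breath VO2 is cleaned with a sliding 5-breath median filter
(centred windows that shrink symmetrically at the edges, preserving series
length) and linearly interpolated to the 1 Hz grid.  Two HR sources can be
time-aligned by maximizing their cross-correlation over integer lags (ties
break toward the smallest magnitude; resolution 1 s).  Garment ventilation
estimates are calibrated per session by ordinary least squares against the
reference.  HRR is `(HR - HR_rest) / (HR_max - HR_rest)`, unclipped.

Features are scaled with statistics of the *training* sessions only:
z-scores for VE, breathing frequency, HR, HRR, and the VO2 target; min-max
to [0, 1] for work rate (its distribution is bimodal under the binary
protocols, so a z-score would be misleading).  The target is standardized
for the loss — validation losses around 0.02-0.03 are therefore
dimensionless — and predictions are inverse-transformed to ml/min for all
reporting.  Length-RF windows are extracted at stride 1 s over the whole
session — warm-up included, since the warm-up is ordinary cycling and
discarding it would only shrink the training pool; the first prediction
exists at t = RF (the cold start), and evaluation excludes earlier
seconds.

## Training

Adam with learning rate 0.0005, dropout 0.2, minibatch 32, up to 100
epochs; the epoch with the lowest validation MSE is kept.  Splits are at
participant level: every participant's sessions belong to exactly one of
train/validation/test, and a leakage assertion enforces it.  The
hyperparameter grid spans filters \{2, 4, 8, 16, 24\}, kernel size 1-8,
and dilation depth 1-5 (200 configurations); `grid_search_tcn()` ranks
configurations by best validation MSE and `within_pct_of_min()` supports
the "within 5% of the minimum" shortlist rule.

At desk scale (the bundled tests and examples) the same procedure runs
with reduced epochs (10-15) and a proportionally raised learning rate
(0.0015), because a 6-participant cohort provides ~250 minibatches per
epoch rather than tens of thousands; these are the only training settings
that differ from the full-scale procedure.

## The synthetic cardiorespiratory simulator

No public dataset accompanies the protocol design this package targets, so
the simulator generates the full study design: per participant, a
ramp-incremental test (25 W baseline for 4 min, then 25 W/min to a
participant-specific peak) and three pseudorandom binary sequence (PRBS)
tests whose work rates are derived from that participant's own ramp.

* **PRBS protocols.** A 4-stage linear feedback shift register with taps
  \{4, 3\} and all-ones seed generates the period-15 m-sequence (any
  maximal tap set is accepted; the period and the *balance* property —
  counts of high and low units differ by exactly one — are what matter
  physiologically, since they concentrate input power across frequencies).
  Units last 30 s; a session is a 210 s warm-up (the tail of one period)
  plus two full periods: 1110 s.  Bit 1 maps to the high work rate.
* **Kinetics.** Every channel relaxes toward its target with first-order
  dynamics integrated exactly at 1 Hz, using `tau_on` when the target is
  above the current value and `tau_off` otherwise.  VO2 time constants are
  drawn uniformly from 20-30 s; HR, VE, and breathing frequency are slower
  (30-55 s onset) with recovery a further 1.3x slower, reproducing the
  slower off-transients of HR and ventilation that penalize no-history
  predictors.  An optional pure delay stands in for the cardiodynamic
  phase (default 0).
* **Coupling.** The VO2 steady state is linear in work rate
  (`vo2_baseline + vo2_gain * wr`, gain ~10 ml/min/W).  HR, VE, and
  breathing-frequency targets are driven by the *metabolic demand* — they
  rise linearly with the fraction of the VO2 reserve engaged — because
  ventilation follows metabolic gas flux and HR tracks %VO2 reserve, not
  external work.  Peak VE itself scales with the participant's absolute
  VO2 reserve through the ventilatory equivalent for O2 (drawn around
  0.0275 L per ml/min, ~7% between-subject spread).  This coupling is what
  makes *cross-participant* prediction possible: a held-out participant's
  metabolic scale is observable through their ventilation, while HR alone
  carries only relative intensity — which is also why an HR-only model
  degrades sharply.
* **Measurement.** Breaths are sampled at the instantaneous breathing
  frequency; each carries multiplicative noise (~4% VO2, ~5% VE) and, with
  probability 0.02, becomes a spurious outlier (x2-3 or x0.2-0.5) for the
  median filter to remove.  The measured VO2 channel is rebuilt through
  the same filter-and-interpolate chain as real data; HR gets additive
  1 bpm noise at 1 Hz.
* **Population.** Mass ~ N(70, 11) kg, VO2peak ~ N(42, 6) ml/min/kg,
  baseline VO2 ~ N(600, 50) ml/min, gain ~ N(10, 0.7) ml/min/W, resting
  HR ~ N(62, 6), maximal HR ~ N(190, 8).  The spreads put the unexplained
  between-participant variation at roughly 5-8% of VO2, consistent with
  the test-set error scale reported for this model family on human
  cohorts (SD ~120-140 ml/min).

What the simulator does **not** emulate: the VO2 slow component above the
ventilatory threshold, respiratory compensation (VE rising
disproportionately near peak), cadence effects, drift from heat stress or
fatigue, and motion artifacts in garment signals.  Tests passing on this
generator therefore demonstrate that the architecture, training, and
statistics behave as specified — not that the trained weights transfer to
human data.

## Ramp analytics

`vo2peak_20s()` is the highest 20 s moving average.  The mean response
time comes from the double-linear construction: the mean VO2 of the final
2 min of baseline cycling, intersected with the OLS line through the
linear ramp segment (a 60 s guard after onset skips the curvilinear lag
region; on noise-free first-order responses the estimate recovers the time
constant to within ~2 s).  The ventilatory threshold of a synthetic
participant is ground truth by construction (default 0.65 x VO2peak),
replacing the visual gas-exchange determination used with human data.
Protocol work rates are read off the MRT-left-shifted ramp at 90% VT, VT,
and the VT-to-peak midpoint (delta-50%).

## Evaluation statistics

Second-by-second agreement uses Bland-Altman limits of agreement
(bias +/- 1.96 SD).  With repeated measures per participant, the SD
combines within- and between-subject variance components from a one-way
random-effects ANOVA of the differences grouped by subject; unbalanced
designs use the average-cluster-size correction
`n0 = (N - sum(ni^2)/N) / (K - 1)`.  When every subject contributes one
point the method reduces to the standard SD, and exact small-sample CIs
for the limits are not computed (point limits only).  Proportional bias is
the OLS slope of difference on pair mean with its 95% CI.  VO2peak
agreement applies the standard Bland-Altman to the per-participant 20 s
moving-average peaks of the predicted and measured ramp signals.

Activity classification converts VO2 to METs ((VO2/mass)/3.5, mass in kg)
and classifies each second as light (< 3.0), moderate ([3.0, 6.0)), or
vigorous (>= 6.0).  The half-open moderate interval is the only convention
under which "3.0-5.9" class labels and a ">= 6.0" vigorous rule are
jointly consistent.  The report is a 3x3 confusion matrix in seconds with
overall (trace/total) and per-class (diagonal/row-sum) accuracies.

## Numerical choices and degenerate inputs

* First-order integration uses the exact exponential step
  `v + (1 - exp(-1/tau)) (target - v)`, so step responses match the
  closed form sample-for-sample and equal on/off constants give an exactly
  linear (superposable) system.
* Layer-norm epsilon 1e-5; Adam (0.9, 0.999, 1e-8).
* The LFSR rejects the all-zero seed (a fixed point) and non-maximal tap
  sets (reporting the period actually found).
* Cross-correlation alignment refuses constant series; calibration refuses
  a constant predictor; `hr_max <= hr_rest` is an error.
* Sessions shorter than the receptive field yield an empty window set /
  empty prediction with a warning rather than an error.
* Training aborts with a diagnostic if the loss becomes non-finite.

## Desk-scale problem sizes

The bundled test suite exercises the full pipeline on a 6-participant
cohort (one ramp plus three single-repetition PRBS sessions each, ~45 min
of 1 Hz data per participant; ~2,400 windows per training participant at a
94 s receptive field), split 3/1/2 across train/validation/test.  The
desk-scale architecture is f = 12, k = 4, N = 5 (receptive field 94 s,
2,809 parameters) against the k = 1 no-history baseline, trained for 12
epochs.  The repeated-measures Bland-Altman implementation is verified
against a hand-computed balanced ANOVA to 1e-10, and the preprocessing
operators against brute-force oracles on randomized inputs.

## Known limitations

* Training at full scale (200-configuration grid, 100 epochs, 22
  participants) is supported but slow on one CPU; the grid is subsettable
  and the procedure is deterministic given seeds.
* Exact reproduction of human-cohort error tables is out of
  scope: that data is unavailable, and the simulator is a stand-in whose
  difficulty is calibrated only approximately to it.
* The repeated-measures limits of agreement omit small-sample confidence
  intervals.
* Model selection uses a single validation partition; with very small
  cohorts the selected epoch is noticeably seed-dependent.
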