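---
title: "Estimating muscle force from HD-sEMG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating muscle force from HD-sEMG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(emgforce)
```

## The problem

High-density surface electromyography (HD-sEMG) samples muscle activity
with a 2-D grid of closely spaced electrodes (64 or 128 channels here),
giving a spatial map of activation alongside its time course. Because
the amplitude of the sEMG envelope grows with contraction intensity, a
regressor can be trained to read exerted force off the envelope. Beyond
prosthetics and human-machine interfaces, such a regressor has a
clinical use: if it is trained on *healthy* EMG-force data, then the
error it makes on a new person measures how far that person's EMG-force
relationship deviates from the healthy pattern. In cerebral palsy (CP),
where hand dysfunction is otherwise graded by subjective clinical
scales, this deviation is a candidate quantitative marker.

`emgforce` implements that whole chain: a synthetic HD-sEMG/force
simulator (so everything is testable without clinical recordings), the
preprocessing cascade that turns a 64-channel recording into paired
(envelope window, force target) samples, a stacked-LSTM force
regressor, layer-freezing transfer-learning calibration, and a
deviation-score assessment layer with rank-based group statistics.

## Preprocessing cascade

Each recording passes through four stages.

**Channel screening.** Grid recordings routinely contain defective
channels. A channel is flagged when its variance falls below `1e-12`
(flatline), when more than 10% of its samples sit within 0.1% of its
absolute maximum (amplifier railing), or when its log-RMS is more than
5 MADs from the median log-RMS of its grid (gross noise or a dead
contact). The MAD is floored at 0.05 log10 units so a grid of
near-identical quiet channels does not flag hairline differences.
Flagged channels are replaced by the mean of their valid 4-neighbours
on the grid. If more than half the channels fail, the recording is
rejected outright. The thresholds are engineering choices; the
screening criteria themselves are not prescribed by any protocol we
follow.

**Filtering.** Mixed-rate datasets are first brought to a common rate
by per-channel linear interpolation in time (only upsampling is
offered; for a one-dimensional time axis, bilinear interpolation
degenerates to linear). The sEMG band is isolated with a 100th-order
Hanning-window FIR band-pass, 20-500 Hz. Two numerical choices matter
here:

* All FIR filters are applied forward-backward, so the net phase is
  zero. Phase alignment between envelope and force is essential - the
  force target of a window is computed from the *same* samples as the
  envelope input, and a linear-phase one-way filter would shift the
  envelope by 50 samples relative to the force.
* When the sampling rate cannot support the nominal 500 Hz edge
  (fs <= 1 kHz), the upper edge is clipped to `0.45 * fs` so the design
  stays valid before upsampling.

**PCA spatial filtering.** Principal components are computed across
channels (time samples as observations) and the signal is reconstructed
without the component of highest explained variance (redundant
common-mode information: line interference, crosstalk shared by all
electrodes) and the component of lowest explained variance (measurement
noise). Keeping every component reproduces the input to numerical
precision, which is how the test suite anchors the implementation to an
independent SVD-based oracle.

**Envelope, channel optimization, segmentation.** Full-wave
rectification followed by a 100th-order FIR low-pass at 5 Hz yields the
amplitude envelope of each channel; each channel is then min-max
normalized onto [0, 1], storing the bounds. Channel optimization uses
non-negative matrix factorization: the envelope matrix is factorized
into spatial *activation modes* (weights over channels) and their
time-varying coefficients, fitted by Lee-Seung multiplicative updates
(seeded uniform initialization, relative-change tolerance `1e-5`, at
most 500 iterations; the Frobenius objective is non-increasing at every
step by construction, and the test suite asserts it). The mode whose
coefficient row sums largest - the *primary activation mode*, the one
contributing most to force - selects the top quarter of channels by
weight (ties toward the lower channel index, deterministically). The
selected channels' envelopes are averaged with the renormalized mode
weights and min-max normalized to give the one-dimensional envelope.

One design decision deserves emphasis: **NMF operates on the amplitude
envelope, not the per-channel normalized one.** Per-channel min-max
normalization maps every channel - active or idle - onto the same
[0, 1] range, which provably erases the between-channel amplitude
differences that the mode weights are supposed to encode; on simulated
grids the primary-by-intensity mode then locks onto the flat noise
pedestal of the many off-muscle channels and the selection inverts. The
normalized matrix is still produced (it is the documented envelope
product, and its bounds are reported); the factorization and the
weighted average simply read the amplitude version, and the collapsed
1-D envelope is normalized at the end, exactly once.

The NMF rank defaults to 2 (one dominant mode plus one residual mode);
it is configurable and nothing in the chain assumes a particular value.

The force trace is smoothed with a 0.05 s zero-phase moving average (to
remove measurement burrs; the window is an engineering default), min-max
normalized per repetition, and both streams are cut into windows of 500
samples with a hop of 500 (non-overlapping). Each window's regression
target is the mean normalized force over the window - the protocol we
follow leaves the target's temporal resolution open, and a scalar per
window matches a single-output dense head. Normalization bounds are per
repetition; cross-repetition MVC normalization is not attempted because
maximal-contraction values are not modelled.

## The force regressor

The estimator is a stack of one to three LSTM layers (default units
256-128-64), each followed by batch normalization and dropout (default
0.4), with a single-output dense layer reading the last time step.
Training minimizes the RMSE loss

RMSE = sqrt( (1/N) * sum_i (y_i - yhat_i)^2 ) x 100%

on normalized force, with Adam at learning rate 0.001, batch size 100,
and early stopping on validation loss (patience 20; the
best-validation-loss parameters are restored). Goodness of fit is
reported as

R^2 = ( sum_i (x_i - xbar)(y_i - ybar) )^2 /
      ( sum_i (x_i - xbar)^2 * sum_i (y_i - ybar)^2 ),

the squared Pearson correlation between estimated and measured force,
which lies in [0, 1].

Implementation notes:

* The recurrent forward pass and backpropagation-through-time are
  written in C++ (RcppArmadillo); batch normalization, dropout, Adam
  and the training loop are R. Gradients are verified against central
  finite differences in the development workflow.
* Batch normalization is per feature over (batch x time); running
  statistics use momentum 0.9 and are the ones used at inference, so
  repeated inference on the same input is bit-reproducible.
* All stochasticity (initialization, shuffling, dropout masks) flows
  from explicit seeds; identical seeds give identical estimators.
* `input_stride` optionally decimates the envelope window before the
  recurrent stack. The envelope is band-limited to 5 Hz, so a
  500-sample window at 1-2 kHz is oversampled roughly two orders of
  magnitude; a stride of 10 shortens the sequence tenfold with no
  information content lost and a proportional training speedup. The
  default is 1 (feed the raw window); the desk-scale experiments in the
  test suite use 10.
* The 8:1:1 train/validation/test split is performed at the window
  level by default, mirroring the source-network protocol. A
  subject-level split is available (`split_samples(by_subject = TRUE)`)
  because window-level splitting leaks subject identity across
  partitions; between-subject claims in this package are always made
  with held-out *subjects*.

## Transfer-learning calibration

A trained source network is calibrated into a target network under one
of three layer-freezing strategies: TL1 transfers all parameters with
everything trainable; TL2 freezes the first LSTM layer; TL3 freezes the
first two. `non_TL` trains the same architecture from fresh parameters,
and `source_only` applies the source network unchanged - both serve as
baselines. Freezing is strict: frozen layers' weights, batch-norm
parameters *and batch-norm running statistics* are excluded from
updates (a frozen layer that kept accumulating running statistics would
leak target data into the "frozen" computation), and the test suite
asserts bit-identity of frozen parameters across calibration.
Calibration runs 50 epochs by default with early stopping off, matching
experiments that define no validation set; when a validation set is
supplied (as in the leave-one-subject-out harness, which splits the
remaining subjects 9:1) early stopping is active.

The two experiment harnesses are `loso_evaluate()` (one fold per
subject, test subject completely held out, fold-level RMSE/R-squared
aggregated as mean and SD) and `ratio_experiment()` (subject-level
training:test ratios such as 15:1 down to 1:15, each cell resampled 16
times by default, no validation set). Gesture-specific target networks
are obtained by calibrating once per gesture label; strategy selection
between TL1-TL3 is left to the user since the harnesses report all of
them.

## Deviation-score assessment

For one subject and gesture, every repetition is preprocessed with the
full cascade, the gesture's target network predicts its windows, and
the repetition's RMSE is recorded; the subject's *deviation score* is
the mean over repetitions (invariant to repetition order by
construction). Group analyses use rank-based tests throughout,
two-sided, with mid-ranks and tie-corrected variances:

* healthy vs CP: Mann-Whitney U per gesture. The U statistic for group
  `a` is `R1 - n1(n1+1)/2`, the number of (a, b) pairs with `a > b`
  counting ties one half. For combined samples up to 12 the p-value is
  computed by exhaustive enumeration of group assignments, which stays
  exact under ties (classical exact tables do not); larger samples use
  the tie-corrected normal approximation without continuity correction,
  which makes the two-group case agree with Kruskal-Wallis.
* graded comparisons (e.g. four severity grades): Kruskal-Wallis
  (tie-corrected H; for pooled samples up to 10 the p-value comes from
  exhaustive enumeration of group assignments, otherwise from the
  chi-square approximation) followed by Dunn's pairwise z-tests on mean
  ranks at the Bonferroni-adjusted level `0.05 / choose(k, 2)` - 0.0167
  for three comparisons, 0.0083 for four groups.
* repeated measures across conditions: the Friedman test, with the
  p-value by exhaustive within-subject column permutation whenever the
  permutation space is small enough to enumerate (up to 20000
  combinations) and by chi-square otherwise. A fully tied matrix is a
  0/0 in the tie-corrected formula; since the rank sums are exactly
  equal there, the statistic is defined as 0 (no effect).

At small sample sizes the chi-square and normal approximations can
disagree with exact permutation p-values by 0.1 or more, which is why
the small-sample branches enumerate instead of approximating; the test
suite pins both the statistics and the exact p-values to independent
brute-force oracles.

## The synthetic data generator

The simulator exists so that every stage above has ground truth. Per
channel, the signal is

gain_c x w_c x force(t)^alpha x carrier_c(t) + noise,

where `w_c` is a Gaussian spatial bump over the electrode grid (the
active muscle), `alpha in [0.8, 1.5]` covers linear to mildly nonlinear
envelope-force laws, the carrier is white Gaussian noise band-passed to
20-500 Hz (the simplest process whose rectified envelope tracks its
modulation), and the additive noise is white. Force profiles follow
four modes: increasing-plateau (linear ramp then hold), half-rectified
sine, constant, and a smooth random trajectory band-limited to about
1 Hz (spline through uniform control points 0.5 s apart). Channel
faults (flatline, saturation, gross noise) can be injected to exercise
screening.

Calibration choices made once and kept:

* The activation spread sigma is drawn from U(1.2, 1.8) electrode
  pitches, so the active muscle spans much of its 4 x 4 patch - on real
  montages the target muscle underlies most of its dedicated grid,
  and a "top-quarter" channel selection is only spatially meaningful
  under that geometry.
* The noise level is set per subject from a target SNR (default 10 dB)
  relative to the mean amplitude of the *bump* channels. Off-muscle
  channels, whose signal share is the 0.1 floor weight, are then
  noise-dominated, as they are on real grids; this is what makes the
  NMF weights spatially discriminative.
* Pathology models are deliberate caricatures with a single
  `pathology_strength` dial in [0, 1], built to reproduce qualitative
  clinical observations, not waveform realism: **tremor** multiplies
  the exerted force with a 5 Hz oscillation of depth `0.4 x strength`
  while the EMG drive carries only a half-depth, phase-lagged
  (electromechanical delay) ripple - the envelope then no longer
  predicts the measured force; **shifted activation** moves the bump to
  a different grid and blunts the coupling exponent
  (`alpha x (1 - 0.5 x strength)`), emulating compensatory activation
  misaligned with the measured force; **coactivation** adds a second,
  force-independent bump (tonic co-contraction). All three raise the
  deviation score monotonically in strength, which the test suite
  checks.

What the simulator does **not** model: motor-unit action potentials,
recruitment and firing statistics, volume conduction, electrode-skin
impedance drift, electrode shift, or fatigue. Passing tests on this
generator therefore demonstrate that the pipeline recovers the
constructs it assumes (monotone envelope-force coupling, spatially
localized activation, specific pathology signatures) - they do not
demonstrate performance on clinical recordings, which differ in all the
ways just listed.

A measurement artifact worth knowing: on an increasing-plateau effort,
half the force samples share one value, and rank correlation against
*anything* is capped near 0.935 by those ties alone. Envelope-recovery
properties are therefore evaluated on the random (smooth, tie-free)
force mode.

## Problem sizes and defaults used in the test suite

The packaged experiments run on desk-scale cohorts chosen once: 64
channels (four 4 x 4 grids), 1 kHz sampling, 6 s efforts, cohorts of
2-4 subjects with 2-4 repetitions, estimators of 32-16 units with input
stride 10 and at most 50 training epochs (the assessment model trains
up to 150 epochs because its smaller window count yields few gradient
steps per epoch). The full-scale defaults (2 kHz, 256-128-64 units,
batch 100, dropout 0.4) remain the package defaults for real use.

## Known limitations

* No EDF reader/writer: the native interchange format is CSV + JSON
  sidecar. EDF support would need a biosignal-format dependency not
  currently available to the package.
* The LSTM backend is single-threaded CPU code; it is sized for
  calibration-scale datasets (thousands of windows), not for training
  on very large corpora.
* Deviation scores are association measures. No claim is made that a
  score threshold grades clinical severity; the statistics layer
  reports group differences, nothing more.
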