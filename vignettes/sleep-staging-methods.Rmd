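---
title: "Methods: synthetic nights, circadian features and memory models for sleep staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic nights, circadian features and memory models for sleep staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SleepStaging)
```

# The problem and the pipeline

Consumer wearables score sleep in fixed epochs (15, 30 or 60 s) and expose
two kinds of data: per-epoch sensor streams (heart rate, steps, sometimes
raw acceleration, temperature, SpO2) and *summarized* stage records — a
start time, a duration, a stage name and a granularity tag (short/long
cycle). Predicting the stage of the next epoch from these streams is a
sequence-labeling problem with strong class imbalance (roughly half of all
sleep is light sleep) and strong temporal structure (stages come in ~90 min
cycles with characteristic dwell times).

The package implements the full path from raw records to evaluated models:

1. `record_store` preprocessing: expand summarized records onto the epoch
   grid, resolve short/long duplicates, floor-align off-grid timestamps,
   join streams, drop incomplete rows, select named instance schemas.
2. feature engineering: clock, circadian oscillator, activity counts,
   smoothing, heart-rate variation, scaling transforms.
3. sliding-window construction (`ns` history rows + the current row).
4. models: five memoryless classifiers and an LSTM written from its gate
   equations; a sweep over `ns`.
5. weighted multiclass evaluation.

Because the real collections this design targets are private or
access-restricted, a synthetic-night generator stands at the front of the
pipeline; it is first-class, tested code, and its defaults define the study
conditions used throughout the test suite.

# The synthetic-night generator

## Hypnogram model

The generator uses a dwell-time-constrained semi-Markov cycle model. A
night is `nCycles ~ Uniform{4..6}` concatenated cycles; each cycle
traverses wake → N1 → N2 → (N3) → REM. Bout durations are drawn uniformly
from intervals that sit inside hard dwell ranges (defaults N1 1–5, N2
10–60, N3 20–40, REM 10–60 min) and whose *means* are derived in closed
form from the target long-run proportions (defaults wake 0.122, light
0.501, deep 0.181, REM 0.196) times the nominal cycle length (90 min):

* per-cycle budgets: `c_wake = p_wake L`, `c_N1 = mean(N1 range)`,
  `c_N2 = p_light L − c_N1`, `c_deep = p_deep L`, `c_REM = p_REM L`;
* deep sleep is special: its per-cycle budget (~16 min) is below its dwell
  floor (20 min), so a deep bout cannot appear in every cycle. Deep is
  placed in the first `kDeep` cycles (deep sleep concentrates early in real
  nights), with `kDeep` stochastically rounded so the *expected* total deep
  time equals the target exactly;
* cycles without a deep bout redistribute its budget over the other stages
  (a common rescaling factor), so every cycle stays near the nominal length
  and the pooled proportions remain exactly calibrated;
* the first cycle's budgets are scaled by 0.8, making it the shortest in
  expectation — with the wide dwell ranges a later deep-free cycle can
  occasionally be shorter, which matches the "usually the shortest"
  physiology rather than a hard guarantee.

Uniform draw intervals have half-width `min(0.3·target, distance to the
range bounds)`, so each draw's mean is exactly its target and every bout
respects its range. Durations are then discretized to whole epochs, with
deep/REM/N1/N2 bout lengths clamped inside their ranges after rounding.

The `historyDependence = FALSE` variant replaces all of this with a
first-order chain: each epoch resamples the stage from the target
proportions with a fixed hazard (geometric dwell, mean 20 min). Its
stationary distribution is the target by construction, and — because the
hazard does not depend on elapsed dwell — past context carries no
information beyond the current stage. It is the negative control for the
memory-effect studies.

## Emission model

No public spec exists for the sensor distributions, so they are the
package's own choices, fixed once: per-epoch heart rate is Gaussian with
stage-conditional parameters (wake 72±8, REM 66±6, light 62±5, deep
56±4 bpm) — overlapping distributions in the realistic nocturnal ordering
wake > REM > light > deep; steps are zero in all sleep stages and sparse
Poisson bursts in 30 % of wake epochs; acceleration is stage-modulated
Gaussian noise around gravity at a configurable rate (default 10 Hz).

## Duplicate records

`emitSleepRecords()` run-length encodes the hypnogram into `Long` records,
then overlays `Short` records (30 s, or 60 s where the stage is locally
constant) on a configurable fraction of epochs. The short record carries
the *true* stage while the long coverage underneath is corrupted to a
different stage; long records always partition the night exactly. This is
the convention that makes the preprocessing testable: expanding and merging
with the short-wins rule must recover the hypnogram identically at every
duplicate rate, and the test suite asserts that it does.

## What the generator does and does not emulate

It reproduces: the cycle architecture and dwell-time ranges, the stage
imbalance, stage-conditional heart rate and activity, epoch gridding, and
the short/long duplicate mess. It does not attempt: waveform-level PPG/ECG
realism, inter-subject variability in emission parameters, arousals or
stage fragmentation within bouts, daytime activity, or device artifacts
such as missing spans (nulls are injected separately where tests need
them). Passing tests on synthetic nights therefore demonstrate pipeline
correctness and the *learnability mechanics* of history, not real-data
accuracy; the headline accuracies reported for private/restricted
collections are out of reach by construction.

# Preprocessing decisions

* **Expansion before merging.** A 60 s short record can overlap two 30 s
  slots; only expansion to the finest interval first, then slot-wise
  short-wins, resolves mixed-granularity overlaps deterministically.
* **Floor alignment** maps each timestamp to its grid floor (06:00:30 →
  06:00:00 on a 60 s grid); collisions within a cell keep the earliest
  record, on the assumption that a stage does not change within one cell.
* **Epochs are half-open** `[t, t + interval)`; timestamps are treated as
  timezone-naive clock instants (stored as UTC).
* **Non-multiple durations** are truncated to the last full epoch, with a
  message.
* The seven shipped instance schemas (`I1_act` … `I5_spo2`, `AW`, `MESA`)
  fix column inventories of 14/16/19/20/21/7/7 including the patient id,
  time and stage columns, each nesting its predecessor. The HRV block is
  carried as three columns (rmssd, f_high, f_low) so the inventory matches
  the published instance table's count; the `MESA` interval defaults to
  15 s (configurable, as sources disagree between 15 and 30 s).

# Features

* **Cosine clock**: `cos(2πt/24)` with `t` in hours since sleep onset. The
  24 h period is a convention fixed here (the raw `cos(t)` form is
  dimensionally ambiguous); it makes the clock fall and rise once
  overnight.
* **Circadian oscillator**: the cubic van der Pol pacemaker with light
  drive `B`, integrated with classical fixed-step RK4 (`deSolve`,
  `method = "rk4"`, default `dt = 60 s`). The light-transduction stage is
  the Kronauer-family Process L — `α(I) = α₀ (I/I₀)^p`,
  `dn/dt = 60[α(1−n) − βn]`, `B = G α (1−n)(1−0.4x)(1−0.4x_c)` with
  defaults α₀ = 0.05 min⁻¹, β = 0.0075 min⁻¹, I₀ = 9500 lux, p = 0.5,
  G = 33.75 — the closest published completion of the pacemaker model,
  with every constant exposed in `circadianParams()` so alternatives can
  be swapped. Two structural facts anchor the tests: with `B ≡ 0` the
  origin is an *exact* fixed point (every RK4 stage derivative vanishes),
  and the free-running period is `0.99669 τ_x` to first order, which the
  suite verifies by zero-crossing measurement over 10 simulated days for
  τ_x ∈ {23.5, 24.2, 24.6} within 5 %.
* **Light from activity**: epochs with counts above a threshold (default
  0) map to 1000 lux, the rest to 0 — an empirical proxy for the
  illuminance wearables do not record.
* **Activity counts**: one-pole high-pass (default 0.25 Hz) per axis to
  remove gravity, vector magnitude, per-epoch maximum, integer scaling.
  The published coefficient sets for specific devices are not reprinted
  anywhere usable, so the cutoff and scale are configuration with sane
  defaults.
* **Smoothing**: Gaussian kernels are unit-sum (constants invariant), the
  difference-of-Gaussians kernel is the difference of two unit-sum
  Gaussians and hence zero-sum (constants map to 0, change periods are
  highlighted; defaults σ = 120 s vs 600 s for heart rate). Kernels
  truncate at 4σ; edges use reflect padding. The activity-smoothing width
  σ = 50 is interpreted in *samples* on the count grid — the width
  carries no unit in its source, so the unit is declared, not inferred.
* **Heart rate** is linearly interpolated to a 1 s grid and smoothed
  (default σ = 120 s, reused from the change-highlighting filter because
  no separate width is published); heart-rate variation is
  `|Δhr| / mean(hr over the sleep period)`.
* **Transforms**: `log2(y + 1 − min(y))` (order-preserving, minimum
  exactly 0) and train-fitted min-max scaling without clipping.

All feature operations are deterministic; the only randomness in the
package lives in the generator, the splits and the model initializations,
each behind an explicit seed.

# Windowing

A window is `ns` history rows plus the current row (`ns + 1` rows), labeled
by the current row's stage; `ns = 0` degenerates to the memoryless table.
Windows never span a timestamp gap or a patient boundary — the table is
split into contiguous single-patient segments first; mixing subjects inside
one window would leak context across subjects. Stride is 1 (sliding);
flattening to `(ns+1)·F` columns with `_lag<k>` suffixes serves the
memoryless engines, and flatten/unflatten is an exact round trip.

# Models

* **Split**: `stratified_random` (default, 0.75/0.25, per-class sampling
  preserving proportions within one sample per class) and
  `subject_held_out` (whole subjects per side) are both provided — the two
  readings of "subject-independent stratified" are contradictory for
  overlapping windows, so both exist and the stratified variant is the
  default while the held-out variant supports leakage studies.
* **Memoryless engines** are delegated: multinomial logistic regression and
  the MLP to `nnet`, the random forest to `randomForest`, kNN to `class`
  (default k = 3), the SVM to `e1071` (radial kernel). Hyper-parameters
  are selected by k-fold cross-validated weighted F1 over small grids
  (tens to hundreds of fitted models, configurable); a single-point grid
  skips CV.
* **LSTM**: standard gates with logistic activations; the candidate gate
  uses the hyperbolic tangent (`candidateActivation = "tanh"`). A sigmoid
  candidate variant is kept as a switch because the source prints that
  form, but tanh is the standard reading consistent with its own "tanh
  operation" narrative and with the modulation-gate identity `g ≡ c̄`.
  Training is full BPTT with Adam at canonical rates (0.9/0.999, lr
  0.001 default), batch size 128, 50 epochs by default; hidden size
  (default 16) and batch size are declared defaults, not published values.
  Correctness rests on a finite-difference gradient check (relative error
  < 1e-4 on a 3-hidden-unit, 2-feature, 3-step network) and on exact
  zero-propagation (zero weights give zero states and uniform
  probabilities). Divergence (loss > 10× initial) aborts with diagnostics.
* **Sweep**: `memorySweep()` windows, splits, trains and scores per `ns`,
  and `sweepSummary()` reports the first `ns` attaining the maximum
  accuracy (ties at the smallest `ns`, logged) plus the top-3 set.

# Evaluation conventions

All metrics are computed from the predicted-by-true confusion matrix.
Precision/recall/F1 are support-weighted; the support-weighted recall is
algebraically the accuracy (the suite asserts this on a thousand random
fixtures), which explains why accuracy and recall columns coincide in
weighted reporting. Kappa uses chance agreement from the marginals; the
Matthews coefficient uses the multiclass covariance form. All scores are
reported on the [0, 1] scale uniformly. RMSE, where probabilities are
available, is measured against one-hot truth.

# Problem sizes and numerical tolerances used by the suite

The test suite runs everything at desk scale, as the package's own choice
of study size: generator calibration pools 50 nights; the learnability
study uses 60 s epochs with no acceleration channel, five seeds × four
nights for the LSTM memory comparison (`ns ∈ {0, 4, 8}`, hidden size 8, 10
epochs, lr 0.01) and eight nights for the random-forest-vs-baseline check;
circadian trajectories run 10 simulated days at `dt = 60 s`, with a
halved-step agreement check under smooth forcing (< 1e-6 over a day).
Floating-point identities (recall ≡ accuracy, scaler inversion, zero-sum
kernels) are asserted at 1e-9–1e-12.

# Known limitations

* Synthetic emission parameters are fixed population values; no
  inter-subject variation, so subject-held-out and stratified splits look
  more alike than they would on real data.
* The memoryless negative control still has persistent stages (geometric
  dwell), so neighboring epochs correlate and small apparent gains from
  history can appear by noise-averaging; the suite therefore tests for
  *overlapping* accuracy bands rather than exact equality.
* HRV/temperature/SpO2 columns are consumed as inputs where present, never
  computed.
* No GPU or compiled code: the LSTM is pure R, vectorized over the batch;
  it is sized for method studies, not production training.
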