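---
title: "Classifying early-labour cardiotocograms: models and methods"
author: "ctgnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying early-labour cardiotocograms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cardiotocography (CTG) records the fetal heart rate (FHR) and uterine
activity during labour. Visual interpretation of the FHR trace —
baseline level, variability, accelerations and decelerations — is
subjective, and severe compromise at birth (stillbirth, neonatal death,
encephalopathy, seizures, prolonged intensive-care resuscitation) is
rare, on the order of one birth in a hundred in high-risk cohorts.
`ctgnet` implements an end-to-end pipeline that takes the first 20
minutes of a 4 Hz FHR recording and produces a probability of severe
compromise: signal cleaning, quality-controlled segment extraction, gap
imputation, optional time-frequency imaging, class rebalancing, five
neural-network architectures, and an evaluation suite centred on the
partial area under the ROC curve at clinically tolerable false-positive
rates.

Because real labour-ward recordings are not redistributable, the package
ships a synthetic CTG simulator that reproduces the statistical features
the pipeline depends on. Every stage is exercised and tested against
that simulator.

## The synthetic cohort generator

`simulateRecord()` builds a 4 Hz trace from components that mirror what
a clinician reads off a CTG:

* **Baseline**: a bounded, slowly drifting AR(1) random walk per
  3.75-second epoch (default mean 140 bpm, stationary spread 5 bpm), in
  the normal 110–160 bpm range.
* **Short-term variability (STV)**: clinically quantified as the mean
  absolute change of epoch-averaged beat intervals in milliseconds. The
  generator perturbs the per-epoch beat interval with Gaussian jitter
  whose scale is calibrated in closed form against the
  mean-absolute-successive-difference statistic, subtracting the
  baseline walk's own epoch-to-epoch interval drift. The package's own
  estimator (`stv()`) recovers the target within 10% on clean 20-minute
  traces (a property the test suite asserts over 50 seeds). Default
  target 6 ms; severe-compromise records draw reduced STV (factor 0.42
  by default), emulating the clinical association between low STV
  (≤ 3 ms) and compromise.
* **Accelerations and decelerations**: Poisson-counted smooth (Hann)
  bumps of +15 bpm and −20 bpm, 1–3 minutes long; positive outcome
  raises the deceleration rate.
* **Sensor dropout**: a two-state Markov chain, simulated as alternating
  geometric run lengths. The stationary loss fraction is
  `enter/(enter + exit)`; the defaults give 27%, matching the raw
  signal-loss level the cleaning stage is designed around.
* **Artifacts**: short spikes above 230 bpm, drops below 50 bpm, and
  contiguous maternal-heart-rate capture episodes at about half the
  fetal rate. Spikes and drops are what the cleaning thresholds remove;
  MHR capture survives cleaning by construction, because no published
  rule identifies it from the FHR channel alone — a known limitation we
  inherit deliberately.

What the generator does **not** model: uterine activity, fetal
behavioural states, gestational-age effects, drug effects, or monitor
autocorrelation structure. Passing tests on this cohort demonstrate that
the pipeline machinery learns the features it is pointed at; they do not
demonstrate clinical performance on real traces.

## Cleaning and segment extraction

Cleaning marks samples above 230 bpm or below 50 bpm invalid (exactly
230 and 50 are kept). The start time is then adjusted with a 5-minute
sliding window on a 1-minute grid: the first window with signal loss
strictly below 50% defines the record's usable start, and the 20-minute
segment cut there is admitted only if its own loss is strictly below
50%. Records with no qualifying start are excluded. Gaps live in a
validity mask, never as sentinel values, so raw values stay
inspectable.

Downsampling is block averaging over valid samples only; an all-invalid
block propagates as a missing output sample. The 1D networks consume
20-minute segments at 0.25 Hz (300 time steps); the time-frequency
images are computed from the same segment at 1 Hz.

## Gap imputation

Three strategies share one contract: observed samples pass through
unchanged, output is fully valid and finite, and the fill is
deterministic.

* **Linear**: interior gaps interpolate between flanking valid samples;
  leading/trailing gaps take the nearest valid value.
* **Autoregressive (the pipeline default)**: an AR model is fitted to
  the longest observed run by Yule–Walker equations with AIC order
  selection up to order 10. Gaps are filled with the fitted model's
  conditional mean, computed by solving the normal equations of the AR
  process's banded precision matrix over the missing positions. For an
  AR(1) this reduces to the classic two-sided bridge, and it is exactly
  the model-implied distance weighting of forward and backward
  forecasts; a forward-only mode is available. We chose the conditional
  mean over an ad-hoc linear blend of forward/backward forecasts after
  measuring both on AR(1) gap-recovery: the conditional mean is the
  optimal predictor under the fitted model and measured strictly better.
  It is worth recording honestly that on a stationary AR(1) with
  phi = 0.9 and a 20-sample interior gap, linear interpolation is a
  near-tie per replicate: the two predictors are strongly correlated and
  parameter-estimation noise decides many comparisons. The aggregate
  error favours the AR fill; per-replicate win rates hover near one
  half.
* **Gaussian process**: squared-exponential posterior mean, provided
  for parity; useful when the expected signal is smooth at a known
  length scale.

## Time-frequency images

The spectrogram frames the 1 Hz signal with a Hann window (lengths 32,
64, 128, 256; 50% overlap; 64 is the default, the best-performing
configuration), takes the magnitude-squared DFT over non-negative
frequencies, adds `1e-10` before the log, resizes to 128 × 128 by
bilinear interpolation and min–max scales each image to [0, 1]. An
all-constant segment maps to an all-zero image rather than amplified
interpolation ripple. The scalogram takes absolute continuous wavelet
coefficients over 128 logarithmically spaced scales spanning
pseudo-periods of 2–256 s — covering baseline drift through
beat-to-beat variability — for four mother wavelets (Mexican hat as the
default, Morlet, Shannon 1.5–1.0, 8th-order Gaussian derivative), with
the same resize and scaling. Min–max scaling is per image; the per-image
choice makes each sample self-contained and independent of the cohort.
Images are replicated to three channels at the network input.

One numerical subtlety the tests encode: with the L2-normalised kernel
`psi(t/a)/sqrt(a)`, the scale of maximum response to a sinusoid carries
an extra `sqrt(a)` factor, so the centre-frequency relation
`f = fc / a` is verified on the response divided by `sqrt(a)`; for the
band-limited Shannon wavelet the argmax inside the flat passband is
arbitrary, and the verified property is that the passband contains the
centre-frequency scale.

## Class rebalancing

Severe compromise is roughly 0.9% of births, so training uses three
mechanisms. Positive records contribute up to four 20-minute windows
cut from the first hour at 50% overlap (a 60-minute trace admits five
candidate starts; the first four are kept, matching the intended
four-fold expansion), each window subject to the same <50% loss filter.
Qualifying windows are then duplicated once (oversampling factor 2), for
at most eight positive training samples per record. Finally the binary
cross-entropy loss weights positive-class errors by the inverse class
frequency of the training set — with the published cohort counts this
rounds to 14. Augmentation applies to the training split only; the test
set always holds one segment per record, and all windows of a record
share a cross-validation fold.

## Architectures

Five architectures share Table-style tuned defaults: five 1D
convolutional layers with filters (16, 32, 64, 64, 16) and kernel 3,
each followed by ReLU, max-pool 2 and dropout; LSTM components of two
layers with 16 units; two fully connected layers (width 64, then 1); a
sigmoid output probability.

1. `cnn1d` — the convolutional encoder plus the FC head.
2. `cnn_lstm_seq` — the encoder followed by the two-layer LSTM, then
   the head.
3. `cnn_lstm_par` — the encoder and the two-layer LSTM read the raw
   (300, 1) signal in parallel; their flattened outputs are concatenated
   before the head. Concatenation is the standard reading of the
   parallel topology.
4. `cnn2d_residual` — for 128 × 128 × 3 time-frequency images: a
   stride-2 stem convolution, then five residual blocks (convolution →
   batch normalisation → ReLU → dropout → max-pool, with a pooled 1 × 1
   projection on the skip path), global average pooling, and the head.
   The stride-2 stem halves the spatial grid before the residual stack;
   with five pooling stages behind it the block arithmetic stays exact
   and the computation tractable on a CPU.
5. `multimodal` — the parallel 1D branches and the residual 2D trunk
   run simultaneously on the signal and its image; all features are
   concatenated into the head.

The layers are authored in the package: vectorised im2col convolutions
and dense algebra on BLAS in R, with the LSTM recurrence, 1D pooling and
column gather/scatter in C (the package pins the BLAS thread pool to one
thread on load, because the many small dense products here lose more to
synchronisation than they gain from threads). Every layer's backward
pass is verified against central finite differences in the test suite.
Weight initialisation is He-style for convolutions and dense layers and
uniform with forget-gate bias 1 for LSTMs; all builds are deterministic
given a seed.

## Training protocol and evaluation

The full-scale defaults follow the published protocol: stratified 85/15
record-level split, ten grouped cross-validation folds on the training
set, weighted binary cross-entropy, Adam at 0.001 halved every 50
epochs, batch 128, dropout 0.3, at most 400 epochs with early stopping
on validation partial AUC over a 50-epoch window (the best-epoch weights
are restored, so the returned model never underperforms an intermediate
epoch on validation PAUC). Batch 512 — the tuned optimum — is available
through `trainConfig`.

Evaluation reports the standardized partial AUC over the 0–10%
false-positive band (trapezoidal, linearly interpolated at the band
boundary, divided by the band width: perfect = 1, chance = 0.05),
sensitivity at 95% specificity (maximum TPR at FPR ≤ 5%), full AUC, and
precision/recall/F1 at a fixed 0.5 threshold. The standardization is by
band width rather than the McClish transform because the latter would
place chance at 0.5, inconsistent with reported partial-AUC magnitudes
for this problem class. Metric implementations are tested against
brute-force threshold-sweep oracles and against `pROC`.

### Standardization scope

Inputs are z-scored with mean and standard deviation **fitted on the
training split and applied everywhere**. A per-segment z-score was
considered and rejected: it divides out the absolute bpm variability
scale, which is precisely the clinical signal (STV is measured in
milliseconds), and on the synthetic separable cohort it reduced a simple
variability feature's AUC from 0.99 to 0.80. Fitting on the training
split only introduces no leakage.

### Desk-scale protocol

The package validates end-to-end learning on a separable synthetic
cohort (`separableCohortConfig()`): 600 records, 10% prevalence,
20-minute traces, class STV 2.5 ms versus 6 ms, default dropout and
artifact processes, the parallel CNN-LSTM model. At this size the
full-scale protocol is mis-sized: dropout 0.3 in every layer prevents a
~500-sample training set from being fitted at all, and hundreds of
epochs are unnecessary. The desk-scale protocol therefore uses no
dropout, learning rate 0.003, batch 64, at most 14 epochs with a 6-epoch
early-stopping window, and 10 grouped folds — chosen once while sizing
the validation study. On this cohort the mean test PAUC across folds and
three seeds is well above the 0.6 bar the validation asserts (chance is
0.05), and the post-hoc analysis reproduces the expected low-STV
enrichment among high predictions.

## Post-hoc analyses

`stv()` uses the Dawes–Redman-style estimator (3.75-s epoch-averaged
beat intervals, mean absolute successive difference); at 0.25 Hz one
sample approximates one epoch. `fhrBaseline()` is a 10%-trimmed mean,
which a single 1–3-minute acceleration cannot move by more than about a
bpm; the clinical grouping cut is 150 bpm. Predictions are grouped at
their own 25th/75th percentiles (low/medium/high; ties collapse to
medium and are flagged), and the analyses report (a) Spearman rank
correlations between predictions and the four pre-imputation gap
statistics — loss fraction, number of gaps, longest gap, longest-gap
location — per outcome class, and (b) the proportion of clinically low
STV (≤ 3 ms) and high baseline (≥ 150 bpm) segments per prediction
group.

## Degenerate inputs and numerical choices

Fully invalid records are unusable and excluded; segments at exactly 50%
loss are rejected (strict inequality); a constant segment has STV 0 and
z-scores to all-zeros rather than NaN; AR falls back to linear (with a
warning) when the longest observed run cannot support the order;
zero-variance inputs to Spearman are flagged NA; tied quartile
boundaries collapse to the medium group with a flag; the spectrogram's
`log_eps` is 1e-10; bilinear resizing uses `EBImage`; all Monte-Carlo
behaviour is seeded, and cohort/fold/initialisation seeds fan out
deterministically from one master seed.

## Known limitations

Maternal-heart-rate capture is simulated but not removed — no rule for
it exists from the FHR channel alone, so cleaned traces retain those
episodes and estimators see them as noise. The 2D networks are
computationally heavy in this implementation and are exercised at small
batch sizes. The synthetic cohort's class separation is by construction
(STV and deceleration rate); real-data effect sizes are far smaller, as
the clinical partial-AUC literature for first-20-minute traces makes
clear. Nothing here is a clinical device; the package is a research
instrument for method development.
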