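---
title: "Decoding imagined speech from EEG with multi-condition training: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding imagined speech from EEG with multi-condition training: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

People who lose speech to motor-neuron disease retain, for a while, the
ability to speak — and, longer, the ability to *imagine* speaking.
Imagined (covert) speech decoded from scalp EEG is therefore an attractive
brain-computer-interface channel, but it is starved for training data:
covert-speech trials are slow to collect, fatiguing, and offer the subject
no feedback.  This package implements, end to end, an analysis that asks
whether EEG recorded during *overt* (pronounced) speech — cheap to collect
while speech is intact — can be mixed into the training data of an
imagined-speech classifier, and with what effect.

The protocol it models: subjects see one of five Spanish words ("si",
"no", "agua", "comida", "dormir") on a screen and either pronounce or
imagine pronouncing it; eight blocks of 50 trials (four blocks per
condition) give 200 trials per condition, 40 per word.  EEG is recorded
from 32 electrodes (10/10 placement) at 1200 Hz; the analysis window is
−1.5..1.5 s around the visual cue.

# Pipeline and models

## Synthetic cohorts

Because no public recordings accompany the protocol, the package carries a
first-class synthetic generator (`sim_config()`, `generate_cohort()`)
whose defaults *are* the protocol: 24 subjects, 2 × 4 × 50 trials, 32
channels, 1200 Hz, −1.5..1.5 s.  Each epoch is the sum of:

* **1/f^α background noise** (default α = 1, sd 10 µV), synthesized by
  spectral shaping of white noise.  The amplitude scale is a calibration
  choice — the protocol literature reports component latencies and
  polarities, not printable amplitudes — and is config-exposed
  (`noise_sd`, `component_amp`).
* **Stimulus-locked components** at the canonical visual/linguistic
  latencies — P100 (100 ms, posterior), N200 (200 ms, frontocentral),
  P300 (275 ms, centroparietal), N400 (370 ms), P450 (450 ms, frontal) —
  as Gaussian-tapered half-cosine bumps of ~100 ms width and 3–4 µV
  amplitude, with posterior channels leading frontal ones by ~50 ms
  (the posterior-to-anterior cascade of visual word recognition).
* **Overt-only late activity** at 600–800 ms, modelling
  production-related dynamics present only when the word is pronounced.
* **A word-specific signature**: a rank-2 spatiotemporal pattern per word
  drawn once per cohort, scaled by `word_effect_size`.  A fraction
  `shared_fraction` of the signature is identical across conditions; the
  imagined-condition signature is further scaled by `imagined_scale` to
  model its lower signal-to-noise ratio.  These two knobs define the
  transfer structure that the training scenarios probe.
* **Optional artifacts**: frontal low-frequency blinks, temporal-channel
  EMG bursts, and periodic cardiac spikes, injected per-trial with
  configurable rates and returned with ground-truth indices.

All randomness fans out from one master seed through named substreams
(schedule, per-trial noise, artifacts, signatures, subject profiles), so
any stage can be regenerated in isolation.

What the generator does *not* emulate: volume conduction from dipolar
sources, inter-channel noise correlation, non-stationarity across blocks,
or realistic artifact morphology beyond the three stereotypes.  Passing
tests on synthetic cohorts therefore demonstrate that the pipeline's
statistics and learning machinery behave correctly under the assumed
signal model — not that any particular accuracy level will be attained on
real recordings.

## Preprocessing

`preprocess_subject()` applies, in a fixed and logged order: trim to
−1.5..1.5 s and polyphase resampling 1200 → 256 Hz (a windowed-sinc
operator; both window endpoints are sample-inclusive, so the epoch is
exactly 769 samples); zero-phase 8th-order Butterworth band-pass 1–30 Hz
(forward–backward `signal::filtfilt`, so ERP peak latencies are not
shifted; epochs are demeaned and reflection-padded first because on 3-s
epochs the filter's edge transients would otherwise dominate); robust
noisy-channel rejection; optional ICA artifact removal; and statistical
trial rejection.

Two steps the protocol leaves under-specified are made explicit and
automatic here:

* **Channel rejection**: channels whose log-variance robust z-score
  (median/MAD) exceeds 4 are flagged, at most 4 per subject — the
  observed range in practice.  Detection is performed jointly over the
  two conditions so a subject keeps one montage.
* **ICA component selection**: a manual mode reproduces a human's
  component list exactly; the automatic mode scores each of the 32
  components for blink (frontal topography × low-frequency dominance),
  muscle (spectral power fraction above 20 Hz > 0.6) and cardiac
  (autocorrelation at 0.6–1.3 s lags) character, removing at most 6.
  The decomposition is a seeded symmetric FastICA with tanh contrast,
  written in-package.

Trial rejection is a conjunction: a trial is discarded only if some
single channel exceeds **both** 150 µV peak-to-peak **and** 20 µV
standard deviation over the epoch.  The conjunction makes the rule
monotone in both thresholds.  Whether trial rejection ran before or after
ICA in the original procedure is not stated; this pipeline fixes the
order (ICA first) and records it in every report.

## ERP analysis

`subject_erp()` band-passes 4–20 Hz, baseline-corrects on −400..−100 ms
and averages within subject; `grand_average()` then averages *subjects*,
not pooled trials, so every participant contributes equally.
`kde_peak_significance()` implements the peak test: per channel, a
Gaussian-kernel KDE (Silverman bandwidth, floored at 1e-3 µV for
degenerate baselines) is fitted to the 52 pre-stimulus amplitudes
(−0.2..0 s), its CDF inverted numerically, and each post-stimulus sample
marked `+`/`−` if it exceeds the 1 − α/2 / falls below the α/2 quantile
(α = 0.01, split equally per tail — the equal split is a declared choice,
as is the quantile reading of "tails"; a density-threshold reading exists
but is not used).  No multiple-testing correction is applied, mirroring
the per-sample character of the original test; a Bonferroni option is
available behind a flag.

Because the KDE convolves the 52-sample baseline with its bandwidth, the
test errs slightly on the conservative side (measured type-I ≈ 0.005 at
α = 0.01 on white noise); the calibration test pools the marked fraction
over channels, since all samples of a channel share one quantile estimate
and per-channel counts are therefore overdispersed relative to a
binomial.

## The classifier

The network (built and trained in compiled code with analytic gradients;
`model_config()`, `train_model()`) is a compact three-block CNN for
(channels × 129 samples) inputs — the 0–0.5 s window where overt and
imagined dynamics are most similar:

1. temporal convolution, `F1 = 8` kernels of size (1, 128) (half the
   sampling rate), same-padded; then a depthwise spatial convolution
   (C, 1) with depth `D = 2` (`F2 = F1·D = 16`), batch-norm, ELU,
   dropout 0.65, average-pool (1, 4);
2. separable convolution — depthwise (1, 16) plus pointwise `F2` —
   batch-norm, ELU, dropout 0.65, average-pool (1, 8);
3. flatten and dense softmax.

The convolutions are evaluated as banded-Toeplitz GEMMs; gradients are
verified against numerical differentiation in the test suite, and the
trainable-parameter count has a closed form checked against the built
model.  The per-scenario `F1`/`D` and optimizer settings used originally
are not published; the defaults here (Adam, learning rate 1e-3, batch 16,
≤500 epochs, early stopping on a stratified validation split with
patience 50) follow the compact-CNN literature's standard regime and are
config-exposed.  Channel counts below 32 (after channel rejection) are
handled by per-subject model instantiation rather than zero-filled
channels, since intra-subject training dominates the design.

## Training scenarios and evaluation

Four training-data compositions are compared on the target subject's
imagined trials (`scenario_spec()`, `run_scenario()`):
imagined-only (80/20 five-fold CV), mixed (adds 100% of the target's
overt trials to each fold's training set), overt-only (train on all overt,
test on all imagined — a single evaluation), and multi-subject augmented
(adds all *other* subjects' overt trials).  Two further multi-subject
variants are runnable behind `experimental = TRUE` but carry no
calibration claims — they were reported as failing to train stably.
Folds are stratified by class (the original says only "five groups";
stratification is declared for balance).  Tasks: the ten word pairs,
short-vs-long ({si, no} vs {agua, dormir}; "comida" excluded), and
five-class.

z-score normalization follows a strict train-fit contract: per-channel
mean/sd are estimated on the imagined training portion of each fold and
reused for the test set; the overt portion is standardized once with its
own parameters.  Normalization is applied in *all* scenarios by default
(the original describes it for the multi-subject scenario; the same
voltage-range argument applies to mixing overt and imagined data), with
`zscore = FALSE` available to reverse the choice.  Train/test
disjointness is asserted at runtime on trial identifiers in every fold.

## Significance statistics

Small test sets make guessing accuracy exceed 1/c; the analytic chance
threshold (`analytic_chance_threshold()`) is the smallest success count
whose binomial CDF (success probability 1/c) reaches 1 − α, as a
percentage of n — computed by explicit log-space summation so the
"smallest integer" convention is unambiguous, and cross-checked against
the quantile function in the tests.  For n = 80, c = 2 it is 58.75%; for
n = 200, c = 5 it is 24.50%.  The permutation alternative
(`permutation_chance_threshold()`) shuffles *training* labels only (test
labels intact), retrains, and takes the 95th percentile of the null
accuracies; both conventions exist in the literature, so this one is
stated prominently.  `wilcoxon_signed_rank()` wraps the standard
signed-rank test (exact null for ≤ 25 untied non-zero differences,
tie-corrected normal approximation otherwise); the α it is reported at is
a report parameter (0.05 by default), since the original states both 0.01
and 0.05 in different places.

# Numerical choices

* Resampling: windowed-sinc (Hann window, 30-tap half-width, cutoff
  0.45 × min(fs)), rows normalized to unit DC gain; in-band tones are
  reproduced to ~4e-4.  The rational-ratio polyphase route through the
  `signal` package was measured to be both inaccurate (0.34 amplitude
  error at 10 Hz) and one sample short, so the operator is in-package.
* Filtering: `signal::butter` designs; an order-n band-pass uses an
  order-n/2 prototype.  Stability at the 1 Hz edge was verified (largest
  pole modulus 0.991 at 256 Hz).
* KDE: 2048 grid points, 4-bandwidth tails, CDF inversion by linear
  interpolation with duplicate-mass removal.
* ICA: eigendecomposition whitening with eigenvalue floor 1e-12,
  symmetric fixed-point tanh iteration, tolerance 1e-6, 200 iterations,
  seeded random orthonormal start.
* Tie-breaks: predicted class is the softmax argmax with ties resolved
  to the lowest class index; zero-variance channels in z-scoring are
  floored at sd 1e-9 with a warning; an all-rejected trial set is an
  error, not an empty result.
* Serialization: raw little-endian float32 + JSON sidecar is the
  lossless interchange format; EDF export (16-bit, one record per epoch)
  is provided for interoperability and round-trips within quantization.

# Problem sizes used by the checks

The packaged calibration checks run the full pipeline at a reduced,
fixed scale chosen once: the null-calibration cohort uses 10 subjects ×
25 trials per condition (5 per word) with `word_effect_size = 0`,
50-epoch training, ICA off (no artifacts are injected there); the
transfer check uses 10 single-subject cohorts × 50 trials per condition
with `word_effect_size = 2`, `shared_fraction = 0.9`,
`imagined_scale = 0.5`.  These sizes exercise every scenario including
the multi-subject augmentation (whose training sets reach ~200 trials)
while keeping the whole suite desk-scale.  The directional transfer
property — mixed training not worse than imagined-only on average, given
strongly shared signatures and weaker imagined SNR — is asserted without
any claim about its magnitude.

# Known limitations

* The generator's linear-superposition signal model cannot validate
  claims about real-EEG accuracy levels; only calibration, contracts and
  ordering properties are asserted.
* FastICA separation on finite samples is approximate (≈2% residual on a
  noiseless 2×2 toy at 4000 samples); the automatic component scores are
  tuned to the generator's artifact stereotypes and should be reviewed
  (or replaced by `manual` mode) on real recordings.
* The KDE peak test is mildly conservative for 52-sample baselines, as
  discussed above.
* `intra_overt` has no cross-validation by construction; its dispersion
  should be read across seeds or subjects, not folds.
* EDF support covers the subset of the format the package writes
  (equal-rate channels, fixed-length records); it is not a general EDF
  reader.
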