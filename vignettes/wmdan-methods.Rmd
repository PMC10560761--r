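---
title: "Methods: simulated working-memory EEG cohorts and the dense attention network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated working-memory EEG cohorts and the dense attention network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wmdan)
```

## Overview

`wmdan` re-implements, as a tested pipeline on synthetic data, an EEG
analysis of visual working memory (WM) in a small patient/control
cohort performing a lateralized change-detection task. The pipeline
has seven analysis stages:

1. **Cohort simulation** (`cohort_config()`, `generate_subject()`):
   epoched multichannel EEG plus behavioral trial logs with planted
   group, condition and task-phase effects.
2. **Behavior** (`summarize_behavior()`): Pashler memory capacity
   `K = N (HR - FAR) / (1 - FAR)` and the reaction-time coefficient of
   variation.
3. **ERP** (`compute_cda()`): the contralateral delay activity (CDA),
   the contra-minus-ipsilateral parieto-occipital ERP difference, with
   mean amplitude in 500–900 ms.
4. **Time-frequency** (`morlet_power()`, `db_baseline()`,
   `tfr_roi_table()`): Morlet-wavelet total power, decibel change from
   a −850…−650 ms baseline, and phase-by-band ROI means.
5. **Statistics** (`mixed_anova()`, `welch_t()`, `cohens_d()`):
   mixed-design ANOVAs with Greenhouse–Geisser correction, classical
   η², and Welch/paired post-hocs with Bonferroni correction.
6. **Classification** (`incremental_stepwise_average()`, `dan_fit()`,
   `loocv_evaluate()`): reduction of each subject's epoch tensor to a
   2750-sample time course and classification with a dense attention
   network (DAN) under 10×-repeated leave-one-out cross-validation,
   against a bank of reference classifiers.
7. **Interpretation** (`extract_attention()`, `phase_overlap()`,
   `threshold_map()`): the attention distribution projected on the
   task timeline and compared with the significant ROI phases.

`run_pipeline()` chains all stages on one configuration.

## The task and epoch conventions

A trial shows an arrow cue (200 ms), fixation (400 ms), a memory array
(300 ms), a 1400 ms delay and a 4 s test array; conditions are 2, 2+2
(two targets plus two distractors) and 4 items, crossed with cue side,
200 trials per condition. Epochs are aligned to memory-array onset and
span the half-open window [−1000, 4500) ms at 500 Hz — exactly 2750
samples, the feature count after the reduction. Task phases are
preparation (−400…0 ms), encoding (0…300), maintenance (300…1700) and
retrieval (1700…3060 ms, the slower group's mean RT + 1 SD after test
onset); frequency bands are theta 4–7, alpha 8–12, beta 13–29 and
gamma 30–60 Hz, inclusive edges on the integer grid.

## The synthetic cohort generator

Each subject × channel × trial time series is a sum of

* **1/f background noise** (PSD ∝ 1/f, broadband RMS 3.69 in nominal
  µV), independent across channels and trials;
* a **posterior alpha oscillator** (8–12 Hz, baseline RMS 10) on the
  parieto-occipital channels, shared across those channels within a
  trial;
* **task-locked slow evoked deflections** at cue, memory-array and
  test onsets, identical for every subject;
* a **sustained lateralized potential** (the CDA) added to
  parieto-occipital channels contralateral to the cue over
  300–1700 ms (−0.5/−0.7/−1.0 µV for conditions 2/2+2/4).

Group effects enter only through the alpha amplitude envelope: per
subject, per phase, the dB change from baseline is drawn from the
group presets (patients −1.09/−0.83/−1.11/−1.13 dB for
preparation/encoding/maintenance/retrieval, SD 0.81/1.00/0.98/1.13;
controls −2.36/−2.17/−2.29/−2.50 dB, SD 1.81/1.93/1.95/2.16). The
preparation, encoding and retrieval values are the published group
summaries; the maintenance means are set so the four-phase average
equals the published overall means (−1.04 and −2.33 dB). A shared
subject intercept with cross-phase correlation 0.8 (derived from the
ratio of the published overall to per-phase SDs) plus independent
per-phase deviations generates the subject draws. The envelope ramps
between phase levels over 100 ms and returns to baseline after
3060 ms; the baseline window itself is never modulated, so baseline
statistics are group-independent by construction.

**Phase reset.** The alpha oscillator is partially phase-locked to the
stimulus events: at cue, memory-array and test onsets the inter-trial
phase clustering jumps to 0.65 and decays with τ = 800 ms, implemented
by mixing a trial-independent locked waveform with per-trial
narrowband noise at amplitude ratio λ(t) / √(1−λ(t)²). Partial phase
reset of ongoing oscillations by salient stimuli is a standard feature
of event-related EEG. It matters here for a structural reason: a
purely phase-random oscillator leaves the trial-averaged time course
with only a variance signature of the suppression effect, whose
precision is limited to about 2·(bandwidth)·(task duration) ≈ 28
effective samples (≈1.2 dB of measurement noise per subject) — enough
for the wavelet pipeline, which averages power over hundreds of
trials, but far too little for any classifier of the 1-d reduced time
course. With partial reset the suppression level also scales a
deterministic component that survives averaging, so the reduced time
course carries the group signal the classification stage is designed
to detect, while total power (and therefore every ROI statistic) is
unchanged and the contra−ipsi CDA subtraction still cancels the
non-lateralized alpha exactly, preserving the null ERP result.

Remaining amplitude parameters (in-band alpha SNR of 20 dB over the
1/f floor, subject-level amplitude CV 0.05, trial-level amplitude CV
0.2) are not published quantities; they were calibrated once so that
the reference classifier bank's leave-one-out profile on synthetic
default cohorts approximates the published model table, and then
frozen.

Behavioral logs are drawn per trial: hit and false-alarm rates
(0.915/0.894/0.696 and 0.10/0.12/0.15 for conditions 2/2+2/4, equal
across groups, consistent with the published per-condition K means and
the null group effect) and lognormal RTs (patients 1000 ± 360 ms,
controls 900 ± 300 ms, truncated at the 4 s response window; positive
skew is the standard RT phenomenology). In the 2+2 condition the set
size is 2 — distractors are not to-be-remembered items.

Seeding: one master seed draws a locked-waveform seed plus one stream
seed per subject, so a subject's data are invariant to cohort-size
changes and cohorts are bit-reproducible.

### What the generator does not emulate

No volume conduction or realistic topography, no eye/muscle artifacts,
no bad channels (preprocessing is out of scope; data are born clean
and epoched), no condition-dependent alpha effects (the published
maintenance-phase condition×group interaction is small and is not
planted), and no latent patient heterogeneity beyond the planted
Gaussian effects. Passing tests therefore demonstrate the pipeline's
correctness and calibration on data of known structure — not clinical
validity on real recordings.

## Time-frequency details

Complex Morlet wavelets at 1–60 Hz (1 Hz steps) with log-spaced width
`n_cycles(f) = 4·(10/4)^(log f / log 60)` (4 cycles at 1 Hz to 10 at
60 Hz). Convolution is FFT-based with zero padding sized to the
longest wavelet; the wavelet has unit gain at its center frequency, so
a unit-amplitude tone measures unit power. Near the epoch edges part
of the wavelet's Gaussian energy envelope falls outside the data;
power is divided by the analytically known in-support energy fraction
(unbiased for stationary signals), and samples with less than half the
energy in support are marked invalid. Total power is the per-trial
squared magnitude averaged over trials (evoked plus induced), then
over the parieto-occipital subset (configurable to all channels). dB
normalization divides by the mean baseline power per frequency; ROI
means are unweighted over the band (inclusive edges) × phase window
(half-open) rectangle.

The baseline window (−850…−650 ms) ends only 50 ms before the cue;
the generator's suppression envelope therefore starts its ramp at
−500 ms so that wavelet smearing (σt ≈ 107 ms at 10 Hz) cannot reach
back into the baseline.

## Statistics

`mixed_anova()` handles one between-subject factor and one or two
within-subject factors on balanced tables. The multivariate fit,
Mauchly tests and Greenhouse–Geisser ε come from `car::Anova`;
corrected df and p-values are reported for within effects whose
Mauchly p < 0.05. Effect sizes are classical η² = SS_effect/SS_total
computed from the equivalent univariate `aov` decomposition (partial
variants were considered; the classical form is reported because it is
what the printed label "η²" most plausibly denotes, and the choice is
documented rather than asserted). Cohen's d uses the unweighted
root-mean of the two variances, `(m1−m2)/√((s1²+s2²)/2)` — the only
standardizer that reproduces all four published d values from the
published means and SDs. Welch tests use the Satterthwaite df;
Bonferroni families are the comparisons within one ANOVA follow-up.

## The dense attention network

The reduction averages the epoch tensor over cells (3 conditions × 2
cue sides), channels and trials, leaving one 2750-sample time course
per subject (`incremental_stepwise_average()`); 30 subjects give the
30 × 2750 feature matrix.

Architecture: a per-feature gate vector (one trainable logit per time
point) is softmax-normalized into the **attention distribution**
(non-negative, sums to one, one-to-one with the input), multiplied
elementwise with the input (rescaled by the input dimension), and fed
to two dense ReLU hidden layers of size H and H/2 with dropout, then a
2-class softmax. Training: minibatch Adam (batch 4) on cross-entropy
with label smoothing 0.1, decoupled weight decay 3 on the dense
weights, and Gaussian train-time input jitter (SD 0.3 of the
standardized features); each fit averages an ensemble of 3 random
initializations. Features are z-scored per column with training-fold
statistics only.

Design notes on the open architecture choices:

* **Two hidden layers.** The planted group structure has unequal
  group variances, so the optimal decision rule on the latent
  suppression level is an interval (patients intermediate, controls at
  both extremes). One hidden layer over amplitude-like ReLU features
  gives only a single-threshold readout; a second layer can carve
  intervals. Depth is configurable.
* **Regularization.** With 29 training subjects and 2750 features the
  network memorizes in a few epochs; weight decay and label smoothing
  keep the fit on consistent features, and input jitter restores the
  noisy-replica structure that makes amplitude-sensitive units
  learnable when trial averaging has made the informative columns
  nearly deterministic. Dropout rate, hidden size, epochs and learning
  rate remain the searched grid of 160 configurations (4 × 4 × 5 × 2).
* **Headline configuration.** The default (`dan_config()`: dropout
  0.2, hidden 32, 32 epochs, lr 0.001) was selected by grid mean
  accuracy on synthetic preset cohorts, with near-ties (within one
  pooled prediction) resolved toward the smaller model. The selection
  is not nested inside cross-validation, so accuracies reported for
  the selected configuration carry optimistic selection bias — the
  same caveat applies to any best-of-grid headline number.
* **Attention aggregation.** `extract_attention()` averages the
  attention distribution over all LOOCV folds and repeats and
  renormalizes; fold-averaging is stabler than a single full-data
  refit on 30 subjects.

Evaluation: leave-one-out cross-validation repeated 10 times;
accuracy, precision, recall (positive class: patient) and
F1 = 2PR/(P+R) are computed from the pooled predictions of each
repeat, then summarized as mean ± SD over repeats, so deterministic
models show SD 0. The reference bank pairs the DAN with ridge
logistic regression, linear/polynomial/RBF SVMs, 3-NN, a random
forest, a plain feed-forward network, and a temporally average-pooled
network standing in as the minimal convolutional reference.

## Interpretation stage

`threshold_map()` masks group-difference values below 30 % of the map
maximum (display convention). `locate_peaks()` reports the top-k local
maxima of the attention trace with a 200 ms minimum separation so the
two reported peaks are distinct task events. `phase_overlap()` maps
peaks to phase windows, computes per-phase attention mass, and flags
descriptively whether peaks fall in phases with significant group ROI
effects; no inferential test of overlap is performed.

## Problem sizes and numerical choices

Full-size cohorts (200 trials/condition, 32 channels) occupy ~0.8 GB
per subject; `subject_map()` streams subjects one at a time so peak
memory stays at one subject. The package's standard analysis runs use
scaled problem sizes chosen for routine reproducibility: the reference
classification cohort uses 60 trials per condition (the reduced time
course's discriminability is dominated by the phase-locked component
and the between-subject draws, not the trial count), and parameter
-recovery runs use alpha-band-only wavelet configurations when only
alpha ROIs are consumed. Degenerate inputs are defined behavior:
all-equal ANOVA tables report F = 0; a flat attention trace has no
peaks; F1 at zero precision and recall is 0 with a warning; K is
returned (flagged) when FAR > HR and is an error at FAR = 1.

## Known limitations

Synthetic cohorts inherit every simplification listed above; in
particular the classifier's operating point on synthetic data tracks
the planted effect sizes and the generator's calibration, and
cohort-to-cohort variation at n = 15+15 is substantial, so accuracies
from single cohort draws carry sampling error of several points. The
published real-data F statistics cannot be reproduced without the
original recordings and are not targets of this package.
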