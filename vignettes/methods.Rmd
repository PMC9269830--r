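---
title: "Time-window EEG emotion recognition: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-window EEG emotion recognition: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Scalp EEG carries emotion-related structure in the power of its canonical
frequency bands, but two nuisances dominate any attempt to classify it:
the choice of the temporal scale at which features are computed, and
session-level baseline and gain differences (electrode impedance, cap
placement, the subject's state on a given day) that swamp the
class-related signal when data from several recording sessions are pooled.
`eegtw` implements a complete, testable version of a standard
analysis design for this setting: band-wise feature extraction from 1-s
epochs, aggregation over time windows (TW) of eleven lengths, a min-max
session normalization called experiment-level batch normalization (ELBN),
a six-classifier offline comparison over ten fixed trial splits, a
sliding-window online classifier, and a Kruskal-Wallis map of which
channel-band cells discriminate the emotions.

The study structure mirrors the SEED recording protocol: 15 subjects,
3 sessions each, 15 film-clip trials per session with the fixed label
sequence `1, 0, -1, -1, 0, 1, -1, 0, 1, 1, 0, -1, 0, 1, -1`
(positive/neutral/negative, 5 trials each), 62 recorded channels at
200 Hz of which 58 are retained (PO5, PO6, CB1, CB2 excluded), and
trials of at least 180 s. That dataset is registration-gated, so the
package ships a synthetic generator that emulates exactly this structure
with known ground truth; every claim the test suite makes is a claim
about the pipeline's behaviour on data with known structure, not about
real EEG.

## The synthetic generator

`generate_trial()` synthesizes each channel as a sum of five band-limited
Gaussian processes, one per band (delta 1-3, theta 4-7, alpha 8-13,
beta 14-30, gamma 31-50 Hz), produced by zero-phase 4th-order Butterworth
filtering of white noise and rescaled so the band variance equals a
target power

P(channel, band, label) = noise_floor x exp(effect[label, band])
  x channel_gain x session_gain + session_offset,

floored at a small positive value. The pieces are:

* **Class effects** (`class_band_effects`): log-power offsets per
  emotion and band. No published effect sizes exist for the emulated
  dataset, so these are free parameters; the default
  (`default_class_effects()`) gives each class a distinct signature --
  negative raises theta and beta by 0.5 log units, positive raises alpha
  and gamma by 0.5 -- which yields strong but imperfect separability at
  the scales used in the analysis scripts. A scale argument moves all
  offsets together (0 = pure chance data, 3 = clearly separable).
* **Session drift**: a multiplicative log-normal gain
  (`drift_gain_sd`, default 0.4) and an additive power offset
  (`drift_offset_sd`, default 0.5) per (channel, band) cell, drawn once
  per (subject, session) and shared by all 15 trials of the session.
  Per-channel variation is the physically sensible shape: impedance and
  cap placement change electrode by electrode between sessions. This is
  the batch structure ELBN is designed to remove. Gain drift multiplies
  every feature of a session's cell by one constant, which ELBN removes
  *exactly* (see below); offset drift enters the target power before
  the epoch noise draw, so its removal is only approximate.
* **Channel heterogeneity**: a per-subject log-normal channel gain
  profile (`channel_gain_sd` = 0.1), making the channel dimension
  non-degenerate without inventing scalp topography.

All randomness flows through one seed via per-entity substreams (a
counter-based hash of subject, session, and trial indices), so
generation order is irrelevant and a trial can be regenerated
bit-identically in isolation.

Two entry points produce the same study conditions at different cost.
`generate_dataset()` synthesizes raw 62 x 36000 signals (the physical
model; about 5 s per trial). `simulate_feature_dataset()` draws the
per-epoch band powers directly from the distribution the signal path
induces on the periodogram estimator: band power of a Gaussian band
process of power P is approximately P x chi-square(2m)/(2m) with m the
number of 1-Hz bins in the band. The epoch-noise substream depends only
on (seed, subject, session, trial), never on drift or effect values, so
two configurations differing only in gain drift produce feature sets
related by an exact per-session multiplicative map -- this is what lets
the test suite assert ELBN's drift invariance *exactly* rather than
statistically. Agreement of the two paths is itself a test. The feature
path is used for large runs: 675 trials of raw signal would occupy
~12 GB, versus ~280 MB of feature tensors.

What the generator deliberately does **not** model: eye-blink and muscle
artifacts, the 0-75 Hz acquisition filter, realistic topography,
non-stationarity within a trial, volume-conduction correlation between
channels. Tests passing on this generator therefore demonstrate the
pipeline's correctness and the normalization's mechanism, not expected
accuracy on real recordings.

## Features

Each retained-channel trial is cut into 180 non-overlapping 1-s epochs
(epoch k covers samples ((k-1)fs, k fs]; surplus beyond 180 s is
dropped; shorter trials are an error). Per epoch and band:

* **PSD feature**: the one-sided Hann-window periodogram integrated over
  the band, summing bins whose centre frequency lies in [low, high]
  inclusive. At 200 Hz and 1-s epochs the bins sit at exact integer
  frequencies, so the integer band edges map cleanly onto bins; the
  normalization makes the full-spectrum sum equal the window-weighted
  signal power, giving the Parseval check its 1% tolerance. No estimator
  was mandated by the design; the single-epoch Hann periodogram is the
  simplest choice consistent with the 1-s epoch grid, and it is
  cross-checked in tests against closed forms (a unit sinusoid's band
  power is A^2/2) and an independent `spec.pgram` route.
* **DE feature**: the differential entropy of a Gaussian whose variance
  equals the band power, DE = 0.5 ln(2 pi e P), in nats. Computing DE
  from the band power rather than from a separately filtered time series
  keeps the two feature types exactly linked (DE is a monotone transform
  of PSD), which the tests assert entrywise. Non-positive powers are
  clipped to machine epsilon with a warning.
* **LDS smoothing** (optional, off by default in the generator output,
  selectable everywhere): a fixed-interval Kalman/RTS smoother for the
  random-walk-plus-noise model x_t = x_{t-1} + w_t, y_t = x_t + v_t,
  applied independently per channel-band series. Only the ratio q/r
  matters; the default 0.01 smooths strongly while leaving constants
  untouched. The upstream design names the smoother but not its
  parameters or whether it applies to PSD, DE, or both; both are
  supported and the choice is a config flag.

## Time windows and ELBN

The 180 epoch values are averaged within non-overlapping windows of
length L seconds for the eleven L in {180, 90, 60, 30, 20, 10, 5, 4, 3,
2, 1}, giving N = 180/L values per channel-band cell and a per-trial
feature format 58 x 5 x N. Only these lengths are accepted: they are the
ones whose arithmetic is exact, and arbitrary lengths would silently
truncate. Aggregation conserves the trial mean and nests (aggregating
the 1-s output at L equals aggregating the raw tensor at L); both are
asserted to floating tolerance.

ELBN rescales each channel-band cell to [0, 1] within one session:
F_norm = (F - F_min) / (F_max - F_min), with the extrema taken over the
session's 15 trials. The narrative description of the procedure pins
down only the N = 1 case (one value per trial); for N > 1 the package
pools all 15 x N window values by default (`pooling = "all_windows"`),
which reduces to the stated rule at N = 1, and offers per-window-index
extrema behind a flag. A degenerate cell (F_max = F_min) maps to 0,
keeping outputs in [0, 1]. Normalizing with another session's statistics
is an error: the construction is strictly within-session, which is also
why it removes per-session affine distortion exactly -- the property the
tests assert and the mechanism by which the synthetic drift disappears.

One methodological caveat is preserved deliberately: the published
protocol fits the extrema on all 15 trials, *including the test trials
of every split*. This leaks test-trial information. The package
reproduces that behaviour as `elbn = "paper"` (the default, for
fidelity) and provides `elbn = "causal"`, which fits extrema on the 12
training trials only; causal test-trial values can then fall outside
[0, 1]. The two modes are compared in the test suite.

## Offline evaluation

One sample per trial: the TW tensor flattened in (channel, band, window)
order -- vector length 58 x 5 x N, i.e. 26100 at the 2-s TW. The
window-level sample counts of the online stage (540 training and 135
testing samples per split set at full scale, from 12 + 3 trials in each
of 45 sessions) force this trial-level reading, and the five bands are
concatenated into one vector (the design's prose is ambiguous between
concatenated and per-band evaluation; per-band is available via the
`bands` argument).

The ten train/test splits are fixed: 12 training and 3 testing trial
indices, identical in every session, each test triple containing one
trial per emotion. Set 3 lists trial 12 on both sides; the overlap is
reproduced verbatim (it is part of the published design) and flagged
with a message. K-fold is not used, matching the design's rationale that
the fixed label order cannot guarantee class-balanced folds.

Classifiers and their settings follow the published table: KNN (k = 5,
Euclidean), logistic regression (liblinear-style L2, C = 1), SVM (RBF,
C = 1), Gaussian naive Bayes, an MLP with hidden layers (100, 3), L2
penalty 1e-5 and L-BFGS, and bagging of 500 LR base learners. Backends:

* KNN via `class::knn`, SVM via `e1071::svm` with `scale = FALSE` and
  `gamma = 1/(p Var(X))` (the reference implementation's `'scale'`
  default; `e1071`'s internal per-column scaling has no counterpart
  there), LR via `glmnet` ridge multinomial with
  `lambda = 1/(n C)` and `standardize = FALSE`.
* Gaussian naive Bayes is implemented in-package with vectorised matrix
  algebra (moment estimators, variance smoothing 1e-9 x max variance):
  looping reference backends take minutes per prediction call at
  p ~ 5 x 10^4. It is cross-checked against `e1071::naiveBayes` in the
  tests.
* The MLP is implemented in-package (ReLU, softmax, mean cross-entropy
  plus alpha/(2n) weight penalty, `optim` L-BFGS-B): no installed
  backend supports two hidden layers, and the single-hidden-layer
  alternative allocates O(n_weights^2) optimizer memory, which is
  infeasible at these input dimensions.
* Bagging is a bootstrap-and-average-probabilities loop over the LR base
  learner (soft voting); resamples that lose a class are redrawn.

**Row-space reduction.** At trial level n is at most 675 while p reaches
52200, so before fitting, the sample matrix is replaced by Z with
Z Z' = X X' (eigendecomposition of the Gram matrix). All pairwise inner
products and distances are preserved exactly, and the optima of the
L2-penalised models lie in the data row space, so KNN, SVM, LR, the MLP
and bagging give identical predictions on Z -- asserted against
unreduced fits in the tests. GNB depends on per-coordinate variances and
is not rotation-invariant, so it always sees the original features. The
reduction is what makes the full 11 x 6 x 10 grid tractable in R at
these dimensions; it changes no result.

Accuracy is the overall fraction correct (folds are class-balanced), and
the grid reports mean and standard deviation over the ten sets, plus
per-class accuracies and confusion matrices. The ELBN contrast table is
the elementwise difference of two summaries with an argmax report.

## Online recognition

A 2-s window sliding in 1-s steps gives 179 windows per 180-s trial
(floor((180-2)/1) + 1, checked against brute-force enumeration). A
trial-level model of dimension 26100 cannot score one 2-s window of
dimension 290, so the online classifier trains on window-level samples:
each training trial contributes its 179 windows, labelled with the
trial's emotion. This is the only dimensionally consistent reading of
the published sample counts and is documented as such. LR is the online
classifier; its per-window class probabilities form a W x 3 trace per
test trial, summarized as median/25th/75th percentile trajectories per
true class -- the numeric content of the usual online-recognition
figures. ELBN in online mode uses extrema over all sliding windows of
the session's 15 trials (the same leaky protocol; a causal mode exists).

## Kruskal-Wallis sensitivity maps

Per channel-band cell, the per-trial mean feature (equal to the epoch
mean whenever no window-dependent transform intervenes, by conservation)
is compared across the three emotions with the tie-corrected
Kruskal-Wallis H (chi-square, 2 df), pooling trials across sessions --
at 5 trials per class per session, pooling is the only way the reported
near-zero p-values are reachable. No multiplicity correction is applied,
matching the analysis being reproduced. The statistic route
(`stats::kruskal.test`) is verified against an independent
midrank/tie-correction oracle on exhaustive small instances. Within a
single session ELBN is a monotone map per cell, so a rank test cannot
move -- asserted exactly; pooled across sessions, ELBN aligns the
sessions' scales, which is precisely how it increases the count of
significant cells under drift. The default TW for this analysis is 2 s
(the length the offline comparison selects); without ELBN the choice is
irrelevant by conservation.

## Problem sizes and numerical choices

The analysis scripts and the acceptance script run the structural checks
at the full 45-session/675-trial scale (feature-level simulation,
seconds of CPU) and the classifier and online stages at 5 subjects x
1 session with all ten splits, with bagging reduced to 50 estimators --
sizes chosen so a complete run takes minutes on one core while leaving
every mechanism visible. Because the generator's band-wide class effects
give every channel signal, classification saturates easily; the
drift-contrast runs therefore use moderate effects (scale 0.3) under
heavy gain drift (sd 2.0), the regime where the batch effect visibly
suppresses unnormalized accuracy and ELBN restores it. Chance-level bands in the tests use 3 binomial
standard errors at the number of *distinct* test trials, since
predictions recur across overlapping splits.

Numerical conventions collected in one place: epoch indexing is 0-based
half-open in samples; flattening is column-major (channel fastest);
ELBN's degenerate cells map to 0; DE's power floor is machine epsilon;
LDS initializes at the first observation with the sequence variance;
ties in classifier argmax resolve to the first (most negative) class;
all stochastic backends take fixed seeds from their specs.

## Known limitations

The generator's independence across channels and epochs makes the
classification task easier than real EEG at matched effect sizes;
accuracies here say nothing quantitative about gated-dataset accuracies.
Offset drift is only approximately removed by ELBN (gain drift exactly).
The paper-faithful ELBN mode leaks test-trial extrema, and the package
defaults to it for fidelity rather than hygiene -- use
`elbn = "causal"` for honest generalization estimates. KNN and SVM
backends emit hard labels only, so they do not participate in
probability-based summaries.
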