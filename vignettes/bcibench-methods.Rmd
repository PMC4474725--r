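---
title: "Methods: models, parameters and design choices in bcibench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in bcibench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bcibench)
```

This vignette documents the scientific content of `bcibench`: the models
each stage implements, the assumptions behind them, the tunable parameters
with their defaults and rationale, the numerical conventions, and what the
synthetic-data generator does and does not emulate.

## The processing model

A sensory-motor BCI decodes imagined movement from band-limited EEG power
changes. `bcibench` realizes the standard three-stage architecture —
filtering, feature extraction, classification — as a single trainable
pipeline whose supervised components are always fit on training data only.

### Frequency filtering

Every band-pass block is a Butterworth filter of order 5 (maximally flat
pass band). The design is computed analytically in zero-pole-gain form:
Butterworth low-pass prototype poles, low-pass→band-pass transform,
bilinear transform with pre-warped edges. The result is stored as cascaded
second-order sections rather than as one order-10 polynomial; on
narrow-band designs the polynomial form loses ~6 digits to coefficient
sensitivity while the section cascade stays at machine precision (the test
suite verifies agreement with the `signal` package's transfer function and
linearity to 1e-8 relative).

Filtering is applied forward and backward. This makes the operation
zero-phase — no group delay, so band-power features from different bands
stay time-aligned — at the price of squaring the magnitude response, which
only sharpens the band edges. Offline operation makes the non-causality
irrelevant. Edges are handled by odd-symmetric extension of length
`3 * (2 * order + 1)` samples (truncated for short epochs) with
steady-state initial conditions per section. Edge transients of a resonant
band-pass decay over a few hundred samples; tests that assert stop-band
attenuation therefore measure over signals long enough (20 s) for the
steady-state response to dominate.

The band-power pathway uses the filter bank {8–12, 16–24} Hz — the alpha
and beta rhythms where ERD expresses. The Morlet pathway applies a single
broad 4–30 Hz pre-filter before wavelet decomposition; whether a pre-filter
should precede the wavelets at all is genuinely open, and we chose the
broad filter because it removes drift and line noise without touching any
frequency the wavelets analyse.

### Common Spatial Patterns

CSP finds spatial filters `w` maximizing the ratio of one class's variance
to total variance, `w Σ⁺ wᵀ / (w (Σ⁺+Σ⁻) wᵀ)`, where Σ are class-mean
trial covariances, each trial's covariance normalized to unit trace so
every trial contributes equally regardless of amplitude. Epochs are
standardized beforehand by per-trial per-channel mean removal only — no
variance scaling — so that post-filtering variance *is* band power, which
is the quantity ERD modulates.

Numerically we whiten the composite covariance (eigendecomposition of
Σ⁺+Σ⁻) and eigendecompose the whitened Σ⁺; this is the standard
realization of simultaneous diagonalization and fixes the normalization
`w (Σ⁺+Σ⁻) wᵀ = 1`, so eigenvalues lie in [0, 1] and label swap maps
λ → 1−λ. Conventions chosen for determinism across linear-algebra
backends: a ridge of `1e-10 · trace` on the composite (rank deficiency
after zero-phase filtering of short epochs), each filter's
largest-magnitude coefficient made positive, and ties kept in original
eigen-order.

Filter selection keeps the `n_pairs` largest- and smallest-eigenvalue
components (symmetric top/bottom pairs). Symmetric selection is our
convention; ranking heuristics exist but add a degree of freedom the
benchmark does not need. Binary problems use plain CSP; multiclass uses
one-against-others with the per-class filter sets concatenated, matching
the features the classifiers consume.

### Features

Band power is the time-averaged (not summed) square of the filtered
signal. Averaging makes features invariant to epoch length, so candidate
time segments of different lengths remain comparable during model
selection; since the two differ by a monotone factor, no classifier
decision changes. Both the power and its natural log enter the feature
vector (the log compresses the heavy right tail of power distributions);
the log is clamped at `log(1e-12)` for degenerate all-zero segments.

Morlet features convolve each channel with unit-energy complex Morlet
wavelets and time-average the squared magnitude. Defaults: 26 center
frequencies at 4.5, 5.5, …, 29.5 Hz — the unique uniform 1-Hz tiling of
4–30 Hz producing 26 bands — and a width of 7 cycles at every frequency, a
common compromise between time and frequency resolution. These constants
are package choices where the underlying configuration is not otherwise
determined. Morlet features are raw power by default; a switch adds logs.

### Classifiers

Seven learners sit behind one train/predict-probability contract; all
produce class probabilities (rows summing to 1, columns in sorted label
order), so synchronous accuracy and self-paced AUC evaluation both apply
uniformly. Standard solvers are consumed, not re-derived: LDA/QDA from
MASS, elastic-net multinomial logistic regression from glmnet (the "L1 and
L2 jointly" regularization is realized as elastic net with the mixing
ratio on the grid), RBF SVM from e1071 (one-against-one multiclass, Platt
probabilities), random forest from randomForest. Two learners are
implemented in-package because no installed engine provides the required
form: AdaBoost as SAMME over rpart weak learners (depth-limited trees,
per-tree feature subsampling, learning-rate-scaled votes), and the MLP as
a single-hidden-layer tanh/softmax network minimizing negative
log-likelihood with both L1 and L2 penalties, trained by full-batch
gradient descent with early stopping on a seeded 10 % validation split.

Feature standardization (train-set mean/variance, frozen into the model)
is applied inside train/predict for the scale-sensitive learners (SVM, LR,
MLP) and skipped for trees. QDA falls back to Gaussian fits with a
`1e-6 · I` covariance ridge when the per-class covariance is singular, as
happens with high-dimensional Morlet features at small n. All stochastic
learners are seeded; training twice with the same spec, seed and data is
bit-reproducible.

Hyperparameter grids follow each learner's tuned-parameter schema (none
for LDA/QDA; C and kernel width for the SVM; regularization type and
coefficient for LR; tree count, feature-subset size, depth, leaf size for
the forest; tree count, feature-subset size, depth, learning rate for
boosting; hidden width, L1, L2, learning rate for the MLP). The candidate
*values* are configuration defaults of this package — e.g.
C ∈ {0.1, 1, 10, 100}, γ ∈ {0.1, 1, 10}/d — and are fully overridable;
they are deliberately small so that joint search spaces stay tractable.

## Evaluation

Synchronous trials are scored by accuracy (argmax of probabilities, ties to
the earliest sorted label). Self-paced streams are cut into half-open
sliding windows with configurable length and overlap; a window is labeled
*control* when at least 50 % of its samples lie inside a control interval,
else *No-Control*. The majority rule is symmetric and threshold-free; how
boundary-straddling windows "should" be labeled is not well defined, and
50 % is the unique choice that treats the two states identically. Scores
against these labels are summarized by the ROC curve and its trapezoidal
area, which equals the Mann–Whitney U statistic with half credit for ties
(verified exactly against the O(n²) pairwise count in the tests) — the
probability that a random control window outranks a random NC window.

## Model selection

BCI parameters (time segment, CSP pair count; window length and overlap
for self-paced data) and classifier hyperparameters are searched jointly
on an exhaustive grid, scored by 5× repeated stratified 5-fold
cross-validation. CSP and feature scaling are refit inside every training
fold: both are supervised, and fitting them once on the full training set
would leak validation labels into the features. Fold assignments derive
from `seed + repeat`, so searches are bit-reproducible. Ties in mean CV
score resolve to the earliest configuration in a deterministic enumeration
order (earlier time segment, fewer CSP pairs, smaller hyperparameters) —
a simplicity-first rule. Default candidate lattices (0.5 s time-segment
steps, 1–3 CSP pairs, 1–2 s windows at 50–75 % overlap) are package
configuration. The winning configuration is refit on all training data and
scored once on held-out data; shared trial identifiers between the two
sets are refused as leakage.

## Rank-based statistics

Classifier comparison across subjects uses per-subject mean-tie ranks
(rank 1 = best), the classic Friedman chi-square

χ² = 12N/(k(k+1)) · (Σ R_j² − k(k+1)²/4),  df = k−1,

and, when the null is rejected, Holm's step-down procedure against the
best-ranked control: z = (R_j − R_ctrl)/√(k(k+1)/6N), raw two-sided normal
p-values sorted ascending and compared to α/(k−i). The recommended set is
the control plus every classifier not shown worse. No tie correction is
applied to the Friedman statistic (ties are already mean-ranked; the
statistic matches `stats::friedman.test` exactly on tie-free tables), and
reporting layers *truncate* — not round — average ranks to 2 and p-values
to 4 decimals, matching the conventions of the published tables the
package ships as fixtures. The analysis API always returns full precision.
One known quirk of those fixtures: recomputing the self-paced band-power
ranks yields average ranks 5.50 for boosting and 5.81 for the SVM, while
the published summary prints the mirror image for those two cells; the
Holm p-values, which depend on the same ranks, agree with the published
ones, so the rank recomputation is taken as authoritative and those two
cells are not used for validation.

## The synthetic generator

Synthetic EEG is built from band-limited oscillatory sources — white
Gaussian noise band-pass filtered to the source band — mixed linearly into
channels with additive white sensor noise. Band-limited noise rather than
pure sinusoids matters: a sinusoidal source has a rank-1 covariance and
makes CSP trivially perfect, while broadband-in-band sources give the
spatial filters realistic estimation error. Class dependence enters by
multiplying each source's amplitude by √factor per class (ERD/ERS are
defined on power). Defaults emulate a 10-channel sensorimotor montage at
250 Hz with two lateralized alpha sources (contralateral ERD factor 0.3),
one midline beta source, 10 µV source amplitude, 5 µV sensor noise — an
in-band SNR above 1 — and 4 s trials with 1 s unmodulated gaps. Self-paced
streams alternate No-Control and control stretches with lengths uniform on
1.5–8 s, the interval statistics reported for published self-paced
recordings; modulation applies only inside control intervals. The final
stretch is truncated to the configured total length, and a truncated
control stretch shorter than the minimum is emitted as NC so every
reported control interval respects the range.

Determinism: one global seed; each trial's signal stream uses the derived
seed `(seed + 1000003·i) mod (2³¹−1)`, so increasing the trial count never
reshuffles earlier trials. Randomized class order is drawn once from the
global seed.

What the generator does *not* emulate: volume conduction from a head
model, 1/f background spectra, non-stationarity across a session, and
ocular/muscular artifacts. Tests passing on this data therefore show that
the pipeline recovers class-dependent band-power structure through linear
mixing and noise — the mechanism BCI feature extraction targets — not that
any particular accuracy transfers to recorded EEG, where artifacts and
non-stationarity dominate the difficulty.

## Problem sizes used in validation

The packaged validation runs at desk scale, chosen to exercise every code
path with comfortable statistical margins: pipeline-recovery checks use
100 training and 50 test trials per class (strong ERD, factor 0.3) and
expect hold-out accuracy ≥ 0.85 for LDA and LR with band-power features,
with modulation-free controls expected inside [0.4, 0.6] for both accuracy
and self-paced AUC; the CSP oracle check compares extreme eigenvalues
against a derivative-free random Rayleigh-quotient search with a 1e5
evaluation budget on up to 5-channel covariance pairs (uniform sampling
alone stalls near 2e-3 in 5 dimensions, so half the budget refines around
the incumbent); AUC is checked exactly against the O(n²) pairwise count on
sets up to n = 2000; and Friedman calibration uses 2000 simulated null
rank tables at N = 10, k = 5, where the empirical type-I rate at α = 0.05
lands at 0.043–0.05 depending on seed.

## Known limitations

The statistics layer reports the Holm step regardless of the Friedman
outcome (the caller enforces the classic gate). The self-paced pipeline
trains on windows cut with the same windowing as evaluation; event-level
(debounced) self-paced metrics are out of scope, as are causal/online
filtering, artifact rejection, readers for vendor EEG formats, and
regularized CSP variants.
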