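---
title: "Sliding-window multivariate decoding of ERPs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sliding-window multivariate decoding of ERPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis model

`erpdecode` asks, per analysis time window, whether multichannel EEG
amplitude patterns carry information about experimental categories (or a
continuous trial variable). The unit of analysis is the *exemplar*: a single
epoch (trial), or a run-averaged epoch when block averaging is enabled.
Within a window of `width` samples starting at sample `t`, an exemplar is
turned into a feature vector in one of three ways:

* **spatial** — the within-window time average per channel (`n_channels`
  features). Averaging acts as a low-pass filter matched to the window.
* **temporal** — the raw window samples of a single channel (`width`
  features), trading spatial for temporal pattern information.
* **spatiotemporal** — all samples of all channels (`n_channels x width`
  features), laid out channel-major: all window timepoints of channel 1,
  then channel 2, and so on. The ordering is fixed and documented because
  feature weights are later averaged within channels.

A linear soft-margin support vector machine (C-SVM, default `C = 1`)
separates two classes; problems with more classes are decomposed one-vs-one
with majority voting, ties resolved toward the lowest class index. For
continuous labels, linear epsilon-SVR (default `C = 0.1`, tube 0.1) is used
and performance is the Fisher-Z (atanh) transformed Pearson correlation
between predicted and true labels. Classification performance is the
percentage of correctly labelled test exemplars.

Because no SVM library is available as an R dependency in the supported
environment, the solvers are implemented in the package itself
(`src/linsvm.cpp`) as dual coordinate descent in the standard
C-parameterised formulation, the approach popularised by liblinear. The
intercept is carried by an augmented constant feature and is therefore
weakly regularised; on EEG-scale problems this is indistinguishable from an
unregularised intercept, and the unit tests verify agreement with an
independent quadratic-programming oracle and with scikit-learn's linear SVM.

## Cross-validation and the chance distribution

Exemplar counts are first equalised across conditions by uniform
subsampling to the smallest condition (conservative balancing: theoretical
chance is then exactly `100/n_classes` percent). Exemplars are divided into
`k` sets of exactly `floor(n/k)`; left-over exemplars are excluded for that
cycle so no set outnumbers another. Training uses `k - 1` sets, testing the
held-out set, rotating through all `k`. The whole cycle is repeated `m`
times with independently drawn sets — and, deliberately, an independently
re-drawn balancing subsample per repetition, so exclusion noise averages
out. With the defaults `k = m = 10` each window's performance is the mean
of 100 analyses.

The empirical chance distribution repeats the identical procedure — same
data, same cross-validation assignment — with condition labels re-shuffled
across exemplars, independently for every repetition. Reusing the
assignment (rather than redrawing it) makes the permuted analyses differ
from the real ones only in the labels. One subtlety matters for
calibration: the shuffle preserves class balance within every
cross-validation set, which is equivalent in distribution to re-sorting
the relabelled exemplars into balanced per-class sets, i.e. to running the
full pipeline on shuffled labels. A naive unstratified shuffle leaves the
permuted folds class-imbalanced while the real folds are balanced by
construction; the majority-class bias then pushes permuted accuracy
systematically below chance and makes real-vs-permuted comparisons
anticonservative. The package's calibration suite (200 simulated null
group studies) verifies that every test-and-correction combination holds
its nominal familywise level under the balanced construction.

Cross-context generalisation trains on the balanced exemplars of one
condition tuple and tests on a disjoint tuple; training and test data are
already independent, so there is no fold structure, and the analysis is
repeated `m` times over re-drawn balancing subsamples.

## Feature weights

Linear decoder weights are extraction filters; a channel can earn a large
weight purely for cancelling noise shared with informative channels. The
package therefore stores, per analysis, the activation pattern
`a = Sigma_X w / var(w'X)` computed from the training data of that fold
(the single-component Haufe transformation). The fold-wise corrected
patterns are averaged over all `m x k` analyses *before* rectification —
averaging signed patterns suppresses noise that rectified averaging would
keep — then averaged over each channel's timepoint features, taken in
absolute value, and z-standardised across channels within the window. A
window whose channel means are all equal yields all-zero z-scores plus a
warning rather than NaN. Signed per-feature weights remain available in
`coef(fit, "raw")` / `coef(fit, "corrected")`. Whether the correction
should use the fold's training set or the whole dataset is not prescribed
anywhere authoritative; the package uses the fold training set, matching
how the weights themselves arise.

## Group inference

Group analyses operate on the subjects-by-windows matrix of mean
performance. Each window is compared against either the theoretical chance
level or, preferably, the subject's own mean permuted-label performance,
with a paired Student t-test or Yuen's 20%-trimmed paired test (robust to
the skewed, bounded distribution of accuracy scores). Differences with zero
(winsorised) variance yield `t = 0`, `p = 1` and a warning. Accuracy tests
are one-sided above chance by default; feature-weight tests one-sided above
zero; both configurable.

Multiple-comparison control across windows offers:

* **Holm** step-down and **Benjamini-Hochberg** step-up FDR (via
  `p.adjust`), plus the **two-stage adaptive (sharpened) FDR** variant;
* **maximum-statistic** and **cluster-based** permutation tests using
  random within-subject sign flips of the difference scores. Clusters are
  runs of adjacent windows with same-signed t exceeding the two-sided
  cluster-forming threshold (uncorrected `p < alpha`, configurable); the
  cluster statistic is the mass (sum of t), compared to the permutation
  distribution of the maximal absolute mass;
* **generalised FWER control** allowing `u` false positives (default
  `u = 1`), implemented as the single-step procedure on the permutation
  distribution of the (u+1)-th largest statistic — a valid gFWER(u)
  controller; the full step-down refinement was judged not worth its
  complexity here.

Prevalence inference follows the minimum-statistic construction: the
observed value of each subject joins its first-level permutation values as
the neutral permutation; second-level resampling draws one first-level
value per subject and takes the across-subject minimum. The global-null
p-value is the rank of the observed minimum; because draws are independent
across subjects it also has the closed form `prod_i(#{P_i >= min_obs}/P1)`,
which the package exposes as `method = "exact"` and the tests use as an
oracle. The prevalence lower bound is the largest majority fraction
`gamma0` whose null is rejected:
`gamma0* = (alpha^(1/N) - p^(1/N)) / (1 - p^(1/N))`, the closed-form
solution of the step-down over `gamma0` (the criterion is monotone in
`gamma0`, so the scan and the closed form coincide). In this package the
first-level permutation values are the per-repetition permuted-label means,
i.e. single-shuffle analyses, while the observed value averages all `m`
repetitions; the observed statistic is therefore less variable than its
permutations, which makes the global-null test somewhat liberal. This is a
property of the stored permutation layout, stated here openly; retaining
full per-analysis permutation results (as the package does) is what makes
the construction possible at all without re-decoding.

A practical caveat on power: the global-null p-value is a product of
per-subject tail fractions evaluated at the *minimum* observed statistic,
so a single information-free subject drags the threshold down and pushes
every fraction toward 1. When only part of the population carries signal
(say half the subjects), the global null is typically *not* rejected —
simulation with perfectly exchangeable permutations puts the rejection
probability near 0.2 at the 5% level, irrespective of the number of
subjects or permutations. Prevalence bounds are therefore most useful in
samples where every subject is expected to carry at least weak
information; this is an inherent property of minimum-statistic inference,
not of this implementation.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `window_width_ms`, `step_ms` | 10, 10 | analysis grid; must be whole samples at the sampling rate — non-integral conversions are an error, never silently rounded, because rounding would change the grid |
| `k` | 10 | cross-validation sets; `n >= k` exemplars per condition required |
| `m` | 10 | independent repetitions; 100 analyses per window at the defaults |
| `cost` | 1 / 0.1 | SVM / SVR soft-margin C |
| `average_by_block` | off | run averages as exemplars (higher SNR, fewer exemplars) |
| `zscore_features` | off | per-feature z-scoring with training statistics; off by default since nothing in the validated pipeline requires scaling of same-unit amplitude features |
| `alpha` | 0.05 | significance level throughout |
| `n_permutations` | 1000 | sign-flip resamples for permutation corrections |
| `n_second_level` | 10000 | second-level draws for prevalence inference |

Seeding: one master seed; every stochastic step (balancing, set assignment,
label shuffling, sign flips, second-level draws) derives a child seed from
`(window, repetition, purpose)`, so real and permuted analyses are
reproducible and mutually independent, and identical configurations
reproduce identical results bit for bit.

## What the synthetic generator does and does not emulate

The generator draws every timepoint, channel and epoch independently from a
Gaussian (mean 0, SD 1) and adds a constant signal to a stated channel and
timepoint block — by default channels 1–10 over the second half of the
epoch, the layout used throughout the validation suite. This gives exact
ground truth: any window before the signal onset is exchangeable between
conditions, so decoding there must be at chance, and the signal block fixes
which channels must dominate the corrected weight maps. It does *not*
emulate real EEG: no temporal or spatial autocorrelation, no 1/f spectrum,
no trial-to-trial amplitude variability, no volume conduction. An `ar1`
option adds within-epoch temporal correlation for stress tests but defaults
off to keep the validation world exactly as stated. A green test therefore
establishes the correctness of the pipeline's bookkeeping and statistics
under known ground truth — not performance claims about real recordings.

Group studies derive per-subject seeds from the study seed; a
`heterogeneity` fraction of subjects receives no signal, which is the
ground truth needed to exercise prevalence inference. For half-carrier
designs the test suite uses `m = 10` repetitions (the field default): `m`
doubles as the number of stored first-level permutation values, and the
second-level minimum statistic needs roughly that many per subject before
it can resolve a 12-subject global null at the 5% level. The regression
generator draws trial labels uniformly on [0, 1] and writes
`slope x label` into the signal block.

## Numerical choices and degenerate inputs

* Fisher-Z at `|r| = 1`: r is clamped to `1 - 1e-12` before `atanh`,
  avoiding infinities while preserving order; undefined correlations
  (constant predictions or labels) are recorded as 0 with a warning flag.
* Dual coordinate descent stops when the projected-gradient violation falls
  below `1e-3` (SVC) / step tolerance `1e-4` (SVR), or after 2000 epochs.
* Balanced sets with `n < k` exemplars are refused with advice to lower `k`.
* MAT v7.3 files (HDF5 containers) are refused with advice to resave as
  v7; no R HDF5 binding is available in the supported environment, and the
  v5/v7 reader covers what the interchange layout needs.
* Windows that would overrun the epoch are dropped, never truncated, so
  feature dimensionality is constant across the grid.

## Scope and limitations

Per-subject decoding expects preprocessed, epoched data; no filtering,
artefact handling or epoching is performed. Temporal-generalisation
(train-time x test-time) matrices, nonlinear kernels in the validated path,
frequency-domain inputs and scalp-topography interpolation are out of
scope; the channel map degrades to an ordered strip without electrode
coordinates. Feature-weight group statistics are defined for spatial and
spatiotemporal analyses only, since temporal analyses use a single channel.
For multi-class problems the stored weight map averages the pairwise
classifiers' patterns, whose signs are only pairwise-consistent;
interpretation is safest for two-class analyses.
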