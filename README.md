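# erpdecode

Sliding-window multivariate pattern analysis (MVPA) for epoched,
preprocessed EEG. Instead of testing a single electrode or component,
`erpdecode` trains a linear classifier on the full amplitude pattern inside
an analysis time window and steps that window through the epoch, mapping
*when* information about experimental conditions is present in the signal —
including effects far too subtle for univariate ERP analyses. It is aimed at
cognitive neuroscientists running ERP decoding studies and at
methodologists who need a scriptable, fully seeded pipeline with honest
chance distributions.

## What it computes

For each analysis window (width *w*, step *s*, given in ms) and each
subject:

* feature vectors per trial — **spatial** (window-averaged value per
  channel), **temporal** (single channel's samples) or **spatiotemporal**
  (all channels x samples);
* linear **C-SVM** decoding (default C = 1; one-vs-one majority voting for
  more than two classes) or linear **epsilon-SVR** for continuous trial
  labels (default C = 0.1), after conservative trial balancing;
* **m x k cross-validated performance** (default 10 x 10 = 100 analyses per
  window): percent correct, or Fisher-Z transformed correlation
  `z = atanh(cor(predicted, true))` for regression;
* the **empirical chance distribution**: the identical analysis with labels
  re-shuffled independently per repetition;
* **Haufe-corrected feature weights** `a = Σ_X w / var(wᵀX)`, reduced to one
  absolute, z-standardised value per channel per window.

At the group level, each window's accuracies are tested against theoretical
or empirical chance (paired Student or Yuen trimmed t), corrected across
windows by Holm, Benjamini-Hochberg or two-stage adaptive FDR,
maximum-statistic or cluster-mass sign-flip permutation, or generalised
FWER control, and optionally summarised by minimum-statistic prevalence
inference: a lower bound on the population fraction with decodable
information,
`γ₀* = (α^(1/N) − p^(1/N)) / (1 − p^(1/N))`.

The linear SVM/SVR back-end is built into the package (dual coordinate
descent, `src/linsvm.cpp`) and is verified in the test suite against an
independent QP oracle and scikit-learn.

## Worked example

```r
library(erpdecode)

# A synthetic subject: 30 timepoints x 8 channels, 40 epochs per condition;
# condition 2 carries a constant 1.0 uV signal on channels 1-4 over the
# second half of the epoch.
noise  <- simulate_noise_dataset(synthetic_spec(n_timepoints = 30, n_channels = 8,
                                                n_epochs = 40, rng_seed = 1))
signal <- simulate_signal_dataset(synthetic_spec(n_timepoints = 30, n_channels = 8,
                                                 n_epochs = 40, signal_value = 1,
                                                 signal_channels = 1:4,
                                                 signal_timepoints = 16:30, rng_seed = 2))
d <- combine_conditions(noise, signal)

fit <- decode_erp(d, mode = "spatial", window_width_ms = 10, step_ms = 10,
                  k = 4, m = 2, permute_labels = TRUE, seed = 7)
fit
#> Sliding-window classification decoding (spatial mode)
#>   3 window(s); 8 analyses per window; chance 50.0%
#>   performance range 46.88 .. 98.75
#>   permuted-label mean 47.71
round(fit$accuracy, 1)
#> [1] 46.9 91.9 98.8
```

The three windows cover timepoints 1–10, 11–20 and 21–30: decoding sits at
chance (46.9%) before the signal, rises once the window touches the signal
block and saturates inside it, while the permuted-label analyses stay near
50% throughout. `coef(fit)` returns the per-channel corrected weight map;
in the signal windows the z-scores of channels 1–4 exceed those of
channels 5–8:

```r
round(coef(fit)[3, ], 2)
#> [1]  1.23  0.62  0.85  0.98 -0.97 -0.80 -0.90 -1.01
```

Per-subject fits from a study are aggregated with
`group_decode(list_of_fits, chance = "empirical", correction = "cluster_perm",
prevalence = TRUE)`, summarised with `summary()` / `write_group_csv()` and
plotted with `plot()`. A thin command-line front end
(`inst/cli/erpdecode`, subcommands `simulate`, `decode`, `group`, `plot`)
drives the same functions from JSON configuration files. Data enter either
as MATLAB MAT files holding the conventional `eeg_sorted_cond{run, cond}`
cell array (`read_mat_dataset()`), or in a transparent native layout of a
JSON manifest plus raw float64 arrays (`read_native()`/`write_native()`).

## Acceptance script

`scripts/acceptance.R` regenerates the package's calibration quantities
from scratch — chance-level performance of balanced two-class and
three-class decoding of pure-noise datasets under the standard simulation
design (100 timepoints, 64 channels, spatial mode, 10-sample windows,
k = m = 10) — and writes them to JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
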