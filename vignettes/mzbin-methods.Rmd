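---
title: "Window construction, chi-square screening and the mzbin model zoo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window construction, chi-square screening and the mzbin model zoo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mzbin)
```

## The model

`mzbin` treats a case/control LC-MS study as a collection of per-sample
peak lists — tables of (m/z, retention time, peak height, peak area) rows
of *different lengths*, because each acquisition detects a different set of
peaks. The working assumption is that class-discriminative signal lives at
reproducible m/z positions, while retention time is unreliable enough
across runs that it is carried through the I/O but never used for
alignment. Alignment is therefore purely mass-based: a fixed grid of m/z
windows, with each sample summarized by the mean peak height (or area) per
window.

This is intentionally coarser than RT-aware peak matching. What it buys is
robustness and a trivially invertible feature space: any selected feature
index maps back to a mass interval by
`Original_mass = F_index * W_step + W_start`, so a classifier's chosen
features are directly interpretable as candidate biomarker mass regions.
What it gives up: co-eluting isomers at the same mass are merged, and a
discriminative species whose m/z falls near a window boundary can be
diluted by its neighbours.

## Grid convention

`build_grid(min, max, step)` uses `n = floor((max - min)/step)` windows,
window `i` covering `[start + i*step, start + (i+1)*step)` with the last
window right-closed so the maximum-m/z peak is never orphaned. The floor
convention is the one consistent with a 54–1223 Da range yielding 1169,
779 and 584 windows at steps 1.0, 1.5 and 2.0; a degenerate range or a
step wider than the range yields a single window. Window assignment is a
partition: `i = min(floor((mz - start)/step), n - 1)`, and the assignment
carries a `1e-9` relative tolerance so exactly divisible ranges are not
truncated by floating-point representation.

The step size is the pipeline's key tunable. Small steps preserve mass
resolution but leave most windows empty (at step 0.1 a serum cohort is
>90% missing per sample); large steps fill windows but average away
between-class contrast. The per-class `missing_stats()` summary makes this
trade-off visible, and `run_pipeline(steps = c(...))` sweeps several steps
side by side.

## Missingness and imputation

A window with no peak for a sample is recorded in a logical mask and then
filled with 0. We read an empty window as "no signal detected", which on
an intensity scale *is* zero; it also makes the presence/absence
chi-square form (`presence = non-missing = non-zero`) exactly consistent
with the filled matrix. No normalization or log transform is applied by
default: the method is deliberately evaluated on raw aggregated
intensities, and any transform would change both chi-square forms.

## Chi-square scoring: two forms

The 2×2 form scores presence/absence against class membership,
`(AD - CB)^2 / ((A+C)(B+D)(A+B)(C+D))`. As written this omits the
sample-size factor N of the classical Pearson statistic; since N is the
same for every window the *ranking* is unchanged, so we implement the
normalized form verbatim and expose `classical = TRUE` for
interoperability (the identity `normalized * N == Pearson` is enforced by
an oracle test against `chisq.test(correct = FALSE)`). Degenerate margins
(a constant feature, or a single-class cohort slice) return 0 with a
`degenerate` attribute rather than NaN.

The default `"frequency"` form is the intensity-weighted variant familiar
from scikit-learn's `chi2` scorer: per-class observed intensity sums
against expectations proportional to class sizes. It uses the magnitude of
the signal, not just its presence, which is what you want when a marker is
present in both classes but elevated in one. Its ranking is invariant to
any global positive rescaling of the matrix. Ties in either form are
broken by the lower feature index, making the ranking fully deterministic.

## The subset search and split discipline

`minimal_subset_search()` sweeps `k = 1..k_max` over the top-k prefix of
the ranking, fitting every model of the zoo on the training partition and
scoring accuracy on a validation partition carved (stratified) from the
training side; the test partition is touched exactly once, by the winning
(smallest-k, earliest-model) configuration refit on train + validation.
The ranking itself is computed on the training side only, so the test
partition never influences feature selection. `k_max` defaults to 20,
comfortably above the subset sizes the method typically settles on (2–10);
the default validation fraction is 0.25 of the training side. On small
cohorts a tiny validation fold can saturate at accuracy 1 early — if k
looks implausibly small, raise `val_frac`.

Three split protocols cover the usual study designs: stratified
train:test ratios (2:1 and 7:3 being common), exact per-class counts (for
matching a comparison paper's split), and batch holdout, where an entire
acquisition batch forms the test set — the honest way to measure
generalization across batch effects.

## The model zoo

Ten fixed learners in a fixed order (the order doubles as the
deterministic tie-break): RF (10 trees), DT, SVM (radial kernel, 200 MB
kernel cache), KNN (5 neighbours), LR, GBM (gradient-boosted trees, 100
rounds, xgboost backend), Gaussian NB, Bagging (100 bootstrapped trees),
AdaBoost (50 stumps, discrete SAMME), MLP (one hidden layer of 32 units).
Hyperparameters follow the published table where the named parameter
exists for the model; entries with no analogue (a "penalty" for a decision
tree; a multinomial smoothing alpha for a *Gaussian* NB) fall back to
library defaults. Bagging and AdaBoost are implemented in-package on
rpart trees — bagged class-probability averaging and the standard
weighted-stump committee respectively — because no suitable ensemble
backend is among the package's dependencies; both are exact textbook
algorithms, seeded and reproducible.

Numerical choices worth knowing about:

* **Scaling.** The pipeline default is *no* feature scaling. The three
  scale-sensitive learners (SVM, KNN, MLP) standardize internally using
  training-side statistics — raw LC-MS intensities span orders of
  magnitude, which degenerates a radial kernel and saturates a sigmoid
  layer; trees, NB and LR are scale-equivariant and see raw values.
* **NB posteriors** are computed in log space with a small variance floor
  (`1e-9` of the largest feature variance): a window absent from every
  training sample of one class otherwise has zero variance, and raw
  density products underflow on intensity-scale features.
* **Scores.** Models with a native probability emit it; SVM emits its
  decision value. The rank-based AUC only needs an ordering, so both are
  valid inputs. Mid-ranks handle score ties, making the statistic exactly
  the Mann-Whitney U estimator (enforced by an exhaustive pair-counting
  oracle test).
* **Degenerate metrics.** Any 0/0 metric cell returns 0 with a flag
  rather than raising, so sweep loops survive tiny validation folds.

## The synthetic cohort generator

`synth_config()` defaults describe the kind of study the pipeline
targets: 59 disease / 43 healthy serum samples in two acquisition batches
of 41 and 61, peaks over 54–1223 Da, ~1000 background peaks per sample
(Poisson, so lengths differ), log-normal heights (meanlog 11, sdlog 1 —
heights around 6 × 10^4 spanning roughly two decades), areas = height ×
a chromatographic width factor, and one planted marker at 113.02 Da,
present in every disease sample with a +3 sdlog intensity effect and in
20% of controls at baseline. Batch effects are a +0.05 Da shift and a
×1.4 intensity factor on the second batch — enough to split a rounded
mass and to separate batches in a two-feature scatter, without modeling
instrument drift over time.

What the generator deliberately does **not** emulate: isotope envelopes,
adducts, correlated co-eluting features, RT drift, and heteroscedastic
detector noise. Passing tests on synthetic cohorts therefore demonstrate
that the machinery recovers planted mass signal under realistic sparsity,
batch structure and intensity noise — not that the pipeline's accuracy on
any real cohort will match.

Marker insertion jitters the mass by a Gaussian of SD 2 × 10^-4 Da, below
the three-decimal rounding the common-mass traversal uses, so a planted
mass remains recognizable after rounding. The traversal's `min_support`
defaults to 1 ("common to all samples"), but batch m/z shifts legitimately
split a mass into two rounded values, so batched analyses should lower it
(the worked example uses 0.25).

## Problem sizes used in the test suite

The suite generates all fixtures in code at fixed seeds. Recovery
properties run on cohorts of 20 samples per class with ~300 background
peaks per sample at step 1.0 (1169 windows): the planted marker window
must top the chi-square ranking in at least 95 of 100 replicate seeds, the
subset search must settle on exactly that window with every zoo model at
or above 0.95 held-out accuracy, and a designed jointly-discriminative
pair (each mass high in all cases but in only half the controls) must be
selected at k = 2. Grid arithmetic, back-mapping, metric and oracle
identities run on closed-form or enumerable inputs.

## Known limitations

* The mean aggregate is sensitive to a single huge outlier peak inside a
  window; no robust alternative (median, trimmed mean) is offered because
  the method is defined by the mean.
* Windows are fixed-width; species density varies along m/z, so one step
  size is never optimal everywhere. The sweep is the mitigation, not a
  solution.
* The subset search is a prefix search over one ranking, not a wrapper
  search: a pair of windows that is informative only jointly is found only
  if both rank above the noise individually.
* With two chi-square forms and ten models, the selected subset is not
  unique across configurations; determinism is guaranteed per
  configuration and seed, not across them.
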