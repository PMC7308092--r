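---
title: "Opportunistic multimodal stacking for brain-age prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Opportunistic multimodal stacking for brain-age prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`oppstack` predicts a person's age from several high-dimensional blocks of
brain-derived features — for example MEG spectral and connectivity
summaries, fMRI functional connectivity, and anatomical MRI morphometry —
and treats the prediction error (the *brain-age delta*,
$\Delta = \widehat{\mathrm{age}} - \mathrm{age}$) as a surrogate biomarker
of brain health. The model is a two-layer stack:

$$y = f\bigl([X_1\hat\beta_1, \ldots, X_m\hat\beta_m]\bigr)$$

**Layer 1.** Each block $X_j$ gets its own ridge regression
$\hat\beta_j = (X_j^\top X_j + \lambda I)^{-1} X_j^\top y$, equivalent to a
zero-centered Gaussian prior on the coefficients. The penalty is selected
per fit by generalized cross-validation over 100 log-spaced candidates in
$[10^{-3}, 10^5]$; the whole path is computed from one SVD, with the GCV
criterion $n\,\mathrm{RSS}/(n - \mathrm{df})^2$ and
$\mathrm{df} = 1 + \sum_k d_k^2/(d_k^2 + \lambda)$ (intercept plus shrunk
directions). Predictors are standardized internally with means and SDs
learned on the training rows only; the target stays in years.

**Layer 2.** The per-block out-of-fold age predictions form a small
subjects × blocks matrix that a random-forest regressor combines
non-linearly (1000 trees by default, MSE splits; depth tuned over
$\{4, 6, 8, \infty\}$ and per-split features over
$\{\sqrt p, \log_2 p, p\}$ by inner 5-fold grid search scored by MAE, with
ties resolved toward the simpler model). Because no random-forest package
ships with the supported R installation, the forest is implemented in this
package (compiled code), following the classical bagged-CART algorithm and
exposing MDI importance.

**Opportunism.** Before the forest sees them, the stacked predictions are
*double-coded*: every column is duplicated, and missing cells receive a
low sentinel (−1000 years) in one copy and a high sentinel (+1000 years)
in the other. A subject missing block $j$ can then be routed by a split at
either sentinel, so *missingness itself becomes a feature* and any subject
with at least one observed modality is usable in training and prediction.
Sentinel values only need to be separable from real predictions; results
are invariant to rescaling them (a tested invariant).

**Shared cross-validation.** One explicit `cv_scheme` object (10 folds ×
10 repeats with reshuffling, by default) is consumed bit-exactly by layer
1, layer 2 and the chance baseline. Every observed (subject, block) cell
receives exactly one out-of-fold prediction per repeat from a model that
never saw that subject in that repeat, and layer-2 train/test splits
coincide with layer-1's. This is what makes fold-wise paired comparisons
(`paired_compare`) meaningful: for each of the 100 splits we compare two
models on identical data, and summarize the paired differences by mean,
SD, 2.5/97.5 percentiles and the fraction of splits won.

# Design choices where the design was open

* **Layer-2 refitting granularity.** Whether the combiner should be refit
  per repeat or pooled across repeats is genuinely open. We fit it per
  repeat on that repeat's out-of-fold matrix and report per-subject
  predictions as the mean over repeats. Hyper-parameter tuning runs once
  per repeat on the training rows of the first fold split by default
  (`tune = "per_repeat"`); fully nested per-fold tuning is available
  (`tune = "per_fold"`) at roughly 10× the cost. The per-repeat default
  selects hyper-parameters on rows that exclude fold 1 but are partially
  reused as training rows for other folds — this can only affect which
  grid point is chosen, never leaks test targets into fitting, and in
  practice selects the same grid point as the nested variant.
* **Forest feature-sampling grid.** The conventional reading
  $\{\sqrt p, \log_2 p, p\}$ is used (a literal "p, log(p), p" grid would
  name p twice); configurable in `forest_spec()`.
* **Per-block training rows.** Each block's ridge is trained only on the
  subjects observed for that block — forced by missing rows, though
  rarely stated.
* **Restricted vs opportunistic.** The "restricted" (complete-case) model
  is defined as the opportunistic pipeline applied to the complete-case
  subset. On fully observed data the coded matrix degenerates to an exact
  column duplication, so the two paths are bit-identical at a fixed seed
  — the restriction identity is exact by construction, and tested.
* **Tie-breaking** in the tuning grid prefers the smallest depth, then the
  smallest feature count; in rank tables ties get average ranks; the
  split-win fraction `pr_better` counts strict wins only.

# Feature mathematics

The M/EEG feature operations mirror standard practice:

* `welch_psd`: Hann-tapered averaged periodogram, 2-s windows, 50%
  overlap, one-sided density scaling (total power ≈ variance).
* `alpha_peak`: a degree-15 polynomial in (linear) frequency is fit to
  log10 power over the whole estimated range and subtracted; the per-bin
  maximum of the residual across channels is searched in 6–15 Hz. Whether
  the detrend polynomial should live on a log or linear frequency axis is
  unstated in the tradition this follows; we use the linear axis, which
  removes the smooth 1/f trend while leaving narrow bumps. A flat
  residual yields an explicit "no peak" flag (propagated downstream as a
  missing feature, consistent with the opportunistic design), governed by
  a `min_prominence` threshold of 0.05 log10-units above the median
  residual.
* `one_over_f_slope`: OLS of log power on log frequency, per channel;
  default fit range 0.1–40 Hz, configurable.
* `hilbert_envelope`: magnitude of the FFT-based analytic signal.
* `oas_shrunk_covariance`: $(1-\alpha)\hat\Sigma + \alpha
  \frac{\mathrm{tr}(\hat\Sigma)}{p} I$ with the closed-form OAS $\alpha$
  (1/n-normalized empirical covariance), clipped to $[0,1]$.
* `tangent_space`: $S_i = \log\!\bigl(R^{-1/2} C_i R^{-1/2}\bigr)$ at the
  affine-invariant geometric mean (fixed-point iteration, tolerance
  1e-8, max 50 iterations, log-Euclidean fallback with a warning). The
  strict lower triangle is scaled by $\sqrt2$ — the isometric convention,
  which makes Euclidean distances between tangent vectors match the
  manifold metric at the reference; diagonals serve as log-power,
  off-diagonals as connectivity ($p(p-1)/2$ values: 100,128 at $p=448$,
  32,640 at $p=256$).
* `envelope_correlation(orthogonalize = TRUE)`: for each ordered pair the
  zero-lag component of one raw signal is regressed out of the other
  before the envelope is taken, and the two directions are averaged. This
  is one member of the orthogonalization family (Hilbert- and
  wavelet-domain variants exist); equivalence with any published variant
  is not claimed. Orthogonalized correlations are Fisher z-transformed
  rather than tangent-projected because orthogonalization destroys
  positive-definiteness.
* `minimum_norm_operator`: $W = G^\top (G G^\top + \lambda I)^{-1}$, a toy
  linear inverse operator for synthetic leadfields — no depth weighting,
  orientation constraints or noise whitening.

# The synthetic world

`simulate_multimodal` generates the stated world every test runs in: ages
uniform on 18–88 years (the life-span cohort range; the empirical age
density of real cohorts is not modeled), a standard-normal latent health
factor, and per block a 3-factor loading model
(age signal, health, block-private latent) plus Gaussian noise. The age
signal can be linear, quadratic or saturating, and is re-standardized so
loading weights keep their meaning. Missingness is none, MCAR, or
age-dependent (logistic in age, intercept calibrated so the marginal rate
is exact). The latent health factor is the deliberate device linking brain
features to behavioral scores: it gives the delta–score association a
known ground truth. One master seed with fixed per-component offsets makes
a config bit-reproducible.

`simulate_oscillatory` builds multichannel signals by spectral shaping of
white noise (exact $f^{-\beta}$ target in expectation), optional
band-limited components with prescribed variances, and an alpha-band
carrier amplitude-modulated by partially shared slow modulators so that
two designated channels attain a target envelope correlation. Envelope
coupling checks run at high alpha SNR (alpha variance well above the 1/f
background), since the envelope of a mixed signal is attenuated by
background noise — real pipelines band-pass first.

What a green test does *not* establish: the generator has no sensor
physics, head geometry, hemodynamics, realistic covariance structure
across features, or non-stationarity; block SNRs are chosen for clear
qualitative regimes (complementary blocks, single-informative block,
informative vs. uninformative missingness), not to reproduce any real
cohort's error magnitudes. Headline real-data numbers (e.g. ~4.7-year
stacked MAE on a real multimodal cohort) are out of desk-scale reach by
design and are not asserted anywhere.

# Delta associations

`delta_association` implements three deconfounding specifications with all
continuous inputs standardized: *two-step* (residualize the score on a
cubic age polynomial, then regress on the delta; the coefficient equals
the residual–delta Pearson correlation), *joint* (delta and age terms in
one model — the two-step shortcut can produce spurious associations when
the delta itself carries age), and *extended* (adding gender, binarized
handedness and log Frobenius-norm motion variability). The per-subject
delta uses the consensus convention: mean over repeats of out-of-fold
predictions, minus age. No multiple-testing correction is applied; the
Manhattan-style `autoplot` draws the conventional 5%/1%/0.1% reference
lines. PC1 aggregation of sub-scores fixes the sign so the
largest-magnitude loading is positive.

# Numerical choices and degenerate inputs

* Ridge: zero-variance predictors are dropped (coefficient 0); constant
  targets and all-constant designs are errors.
* Forest: nodes stop at depth limits, fewer than 2 samples, or SSE below
  1e-12; equal-valued feature ranges are unsplittable. R's RNG drives
  bootstrap and feature sampling, so `set.seed()` gives bit-reproducible
  forests.
* Tangent projection: non-PD inputs raise an error naming the offending
  matrix (index), since shrinkage should have been applied upstream.
* `double_code` refuses observed values equal to a sentinel (ambiguity).
* Permutation importance uses a dedicated stream seeded per (feature,
  permutation index) — `permutation_stream()` is exported so importances
  can be recomputed independently.
* The missingness diagnostic (observed cells zeroed, missingness coding
  kept) refuses fully observed data, where it is undefined.

# Scaling in the shipped tests

The acceptance suite runs the full 10×10 scheme at n = 600 with 3 blocks
but uses 300-tree forests (and the pipeline script 500) instead of the
1000-tree default, purely for runtime; tree count is a plateaued
hyper-parameter well past a few hundred trees at these dimensionalities.

# Known limitations

No classification variant, no gradient boosting or deep combiners, no
real-data ingestion beyond delimited feature tables, no mediation
modeling. The orthogonalization recipe is one member of its family, not a
reimplementation of any specific published variant. In-sample permutation
importance can flatter correlated features; the out-of-sample and MDI
estimators are provided for cross-checking.
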