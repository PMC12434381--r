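---
title: "Methods: connectome-harmonic features and family-aware behavior prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectome-harmonic features and family-aware behavior prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, the parameters that matter, and the design
choices that were genuinely open. Everything quantitative stated here is
computed by the test suite or by `scripts/acceptance.R`; nothing is quoted
from external results.

## 1. The pipeline

Per subject we observe multi-session parcellated BOLD (R regions × T frames
per session, sampling interval `tr_seconds`) and a weighted structural
connectome (SC). The pipeline is:

1. **Denoising** (`preprocess_*`): discard the first `n_discard` frames of
   each session, regress out an intercept, a linear trend, six motion
   regressors and their first-order backward differences, then apply a
   zero-phase high-pass filter. Order is fixed: discard → regression →
   filter.
2. **Consensus connectome** (`consensus_sc`): per *training set*, average
   the subject SCs and Hadamard-multiply with a binary mask that keeps the
   most frequently occurring edges up to a target density.
3. **Harmonic basis** (`harmonic_basis`): eigendecomposition of the
   symmetric normalized Laplacian of the consensus SC.
4. **Features** (`build_feature_matrix`): nine subtypes per subject from the
   concatenated preprocessed sessions.
5. **Prediction** (`run_prediction`): family-respecting outer splits, inner
   3-fold hyperparameter selection, standard scaling fitted on training
   rows, R²/accuracy on the test set, and a permutation null.
6. **Scaling** (`run_scaling`): the same evaluation over a grid of training
   fractions × scan-time amounts.

## 2. Preprocessing: parameters and rationale

* `n_discard = 6` frames — removes scanner-drift frames at session start.
* Confound design: intercept + linear trend + 6 motion regressors + their
  backward differences (first element 0, preserving length). Detrending is
  folded into the same least-squares design rather than run separately; the
  residuals are therefore orthogonal to *all* columns simultaneously, which
  is the property the tests assert.
* High-pass at `highpass_hz = 0.01` Hz: an order-2 Butterworth run forward
  and backward (`signal::filtfilt`), i.e. an order-4-equivalent magnitude
  response with zero phase. Zero phase matters because MSSD is a
  successive-difference statistic and phase distortion would corrupt it.
  Only the cutoff is externally specified; the filter family and order are
  this package's choice.

## 3. Consensus connectome and harmonics

The binary mask ranks edges by across-subject occurrence frequency, with
ties broken by mean weight and then by edge index (full determinism). The
target density defaults to the mean subject density. A distance-binned
selection strategy (which would preserve the fiber-length distribution)
requires fiber-length data this artifact does not model; occurrence-ranked
selection is exposed through the same interface so a binned variant can be
added without touching callers.

The *symmetric* normalized Laplacian L = I − D^(−1/2) A D^(−1/2) is used
(not the random-walk variant) because its eigenvectors are orthonormal,
which the Parseval identity — and with it the energy interpretation of the
graph PSD and the SDI — requires. Eigenvalues lie in [0, 2]; eigenvector
signs are fixed by making each eigenvector's largest-magnitude entry
positive, so graph Fourier coefficients are reproducible across runs and
platforms.

The consensus (and hence the basis) is rebuilt for every training set. The
test suite verifies by mutation that test-subject SCs cannot influence it.

## 4. Features: numerical choices

* **FC**: Pearson correlations, strict upper triangle, row-major. A region
  whose variance is numerically zero relative to the matrix scale raises an
  error rather than yielding silent NaNs.
* **MSSD**: mean of squared successive differences with denominator N − 1.
* **fALFF**: ratio of the *amplitude* spectrum summed over 0.01–0.08 Hz
  (endpoints inclusive) to the sum over all positive frequencies, DC
  excluded, from a plain untapered periodogram. Amplitude (not power) and
  the inclusive endpoints are conventions chosen once for determinate edge
  behavior; tests pin them against an explicit FFT oracle.
* **Graph PSD**: per harmonic, the ℓ2 norm over frames of its coefficient
  series. The alternative reading (norm of squared coefficients) was
  rejected because it breaks the identity Σₖ PSDₖ² = total energy, which
  the tests use as an invariant.
* **Cutoff**: ⌊R/2⌋ harmonics in the low band. For odd R the floor rule is
  this package's choice.
* **SDI**: ratio of high- to low-band temporal norms per region, no log
  transform.
* **Sessions are concatenated** (not averaged) before feature computation,
  consistent with treating scan time as cumulative frames in the scaling
  experiments.

## 5. Prediction framework

Splits are grown family by family in seeded random order until the test set
reaches the target fraction (default 15%), so test sizes vary slightly with
family granularity but families are never separated. Inner folds (3) are
plain random subject folds — stratified by class for binary targets so each
fold's training part sees both classes; the family constraint applies to
the outer partition, where performance is estimated.

Hyperparameter grids are small, standard, and configurable: elastic-net
mixing ∈ {0.1, 0.5, 0.9} with penalty strength log-spaced 10⁻³..10³ (7
points), KRR ridge log-spaced 10⁻³..10³, SVM cost log-spaced 10⁻²..10².
Linear kernels throughout. KRR is solved in closed dual form,
α = (K + λI)⁻¹(y − ȳ), which is exact and fast at cohort scale. Degenerate
inner folds (singleton or constant validation target, or a single-class
training part) score NA and are dropped from the grid mean; if every fold
degenerates the first grid point is used.

R² is 1 − SS_res/SS_tot and may be negative; accuracy is the binary score.
A correlation-based metric is deliberately not offered (it overstates
performance by ignoring calibration).

**Permutation test.** Targets are reshuffled freely over the whole cohort,
`n_permutations` times per outer split (default 100 × 10 = 1000 null
scores), with the entire training procedure repeated per reshuffle. The
p-value uses +1 smoothing: (1 + #{null ≥ mean real}) / (1 + #null). The
significance flag is the strict rule "mean real score > 95th percentile of
the null". Whether permutations should respect family structure is an open
question; free permutation is used.

## 6. The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, with
parameters fixed once at field-realistic values:

* **Base SC**: stochastic-block-model-like weighted graph; within-community
  edge probability 0.6 (lognormal weights around 1.0, sd 0.35), between
  0.15 (around 0.4); a light ring backbone guarantees connectedness.
  Subject SCs apply lognormal jitter (sd 0.25) and 2% random edge
  addition/deletion, so consensus construction is nontrivial.
* **BOLD**: x(t) = U·diag(e^(−decay·λ))·w(t) + ε(t) in the subject's own
  harmonic coordinates, decay 2.5, with w, ε white. Graph-spectral energy
  therefore decays with λ; with decay ≥ 2 over 90% of the energy sits in
  the lower half of the spectrum (a tested property).
* **Subject noise level**: ε's standard deviation is lognormal across
  subjects (sd 0.4 around `noise_sd = 0.5`). Scanner and physiological
  noise genuinely differ across individuals, and this global coupling level
  is the dominant stable trait axis in the generated FC.
* **Targets**: each continuous target is √e·z + √(1−e)·η, where z is the
  z-scored projection of the subject's *expected* feature under the
  generative model (trait FC / regional SD / low-harmonic spectrum derived
  from C = U·g(λ)²·Uᵀ + σ²I) onto a fixed random weight vector, e the
  configured effect size, η standard normal. Targets load on traits — what
  a measured feature *estimates* — not on the sampling noise of one
  realized scan, mirroring how behavior relates to stable brain phenotypes.
  Age is mapped to the narrow 22–37 range; sex is Bernoulli with a logistic
  link on a latent carrying the regional-SD trait.
* **Families**: sizes 1–5 with probabilities (0.45, 0.25, 0.15, 0.10,
  0.05) — configurable, and not a claim about any real cohort's pedigree
  structure.
* **Confounds**: six smoothed random walks per session.

What the generator does **not** emulate: hemodynamic response shape,
spatial autocorrelation within parcels, scanner drift beyond the discarded
frames, non-Gaussian motion artifacts, heritability of the targets within
families. Passing tests therefore demonstrate the pipeline's mechanics and
statistical calibration on data satisfying its assumptions, not performance
on real cohorts.

## 7. Scaling experiments

Training subsets are family-respecting and *nested* across fractions (the
subjects used at fraction 0.2 are reused at 0.4, and so on) — nesting is
this package's choice, made to reduce Monte-Carlo noise in scaling curves.
The test set of each split is untouched across fractions. Scan-time
truncation always starts at the beginning of session one and extends
forward, applied to *preprocessed* (post-discard) frames; every frame used
at a smaller amount is used at every larger one. The time axis is
minutes = session_amount × 4 × 3.6. Curves report the per-point SD across
splits as the error band.

## 8. Problem sizes used in the checks

All automated checks run on synthetic cohorts sized for tight feedback
loops while staying in their statistically meaningful regimes, a deliberate
package choice: dimensional contracts at the full R = 274 on a single
short-scan subject; permutation-count machinery at 40 subjects / 16
regions; signal recovery at n = 300, R = 20, effect size 0.5 on FC edges;
the type-I calibration of the significance rule at n = 120 with 30-subject
test sets, 3 splits × 20 permutations × 100 independent runs. The
calibration size matters: with very small test sets, single-split R² noise
is large and nearly independent across splits, so the mean-over-splits
statistic almost never exceeds the 95th percentile of single-split nulls
and the rule becomes structurally conservative. At 30-subject test sets the
score noise is small relative to the null spread — the regime a full-scale
cohort operates in — and the empirical firing rate under the null is ≈5%.

## 9. Known limitations

* Consensus masking cannot reach a target density above the density of the
  union of subject edges; the mask then simply keeps every observed edge.
* The elastic-net path is interpolated at requested penalties by `glmnet`;
  with very small training sets the inner-fold selection can be noisy.
* The SDI errors out when a region's low-band norm is exactly zero rather
  than returning infinity; callers with pathological signals must filter
  first.
* `graph_psd_low` ground truth uses the lower half of the subject's own
  spectrum; with strong SC jitter the harmonic ordering can differ between
  subjects, which slightly blurs that trait.
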