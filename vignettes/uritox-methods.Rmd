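---
title: "Methods: urinary toxic-metal panels, ASD classification, and severity regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: urinary toxic-metal panels, ASD classification, and severity regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uritox)
```

## The problem

Case-control biomonitoring studies of autism spectrum disorder (ASD) measure
panels of urinary toxic metals (UTM) — creatinine-normalized concentrations in
mcg/g-creatinine of Al, As, Cd, Cs, Hg, Ni, Pb, Sb, Sn, Tl, W in first-morning
urine — alongside batteries of behavioural severity instruments. Three
questions recur:

1. Do the two groups differ, metal by metal and jointly?
2. Can group membership be predicted from the panel alone, and with what
   Type I (neurotypical called ASD) / Type II (ASD called neurotypical)
   error tradeoff?
3. How strongly does the panel predict symptom severity, and does a
   nonlinear model predict better than a linear one once the evaluation is
   honest (statistically independent of fitting)?

`uritox` implements this pipeline end to end: left-censored preprocessing,
univariate summaries and Hotelling's T², linear and kernel Fisher
discriminant classification with kernel-density score models, linear and
kernel partial least squares (PLS) with exhaustive metal-subset search under
leave-one-out (LOO) cross-validated R², and PCA of the severity instruments.
A calibrated synthetic-cohort generator makes every stage testable without
any external data file.

## Data model and preprocessing

A cohort is a tibble with `participant_id`, `group` (`"ASD"`/`"NT"`), one
concentration column per metal and one `<metal>_censored` flag column;
per-metal detection limits (LOD) ride along as an attribute. Values reported
below the LOD are replaced by `2/3 * LOD` (`substitute_below_detection()`),
the conventional single-value substitution for left-censored biomonitoring
panels; the operation is idempotent and every censored cell equals exactly
2/3 of its limit afterwards.

All eleven metals are summarized univariately, but the multivariate panel
(`utm_metals_modeling`) excludes antimony: with roughly half of each group
below its detection limit, Sb carries mostly imputed values and is retained
for univariate description only.

Standardization (`standardize_panel()`) centres and scales each metal to
mean 0, variance 1 using the sample (n−1) standard deviation. The statistics
are estimated on a caller-chosen fitting set and applied as a fixed affine
map to any other rows. Inside every cross-validation fold the statistics are
re-estimated on the training fold only, so no information about the held-out
sample leaks into the scaling. For the one-shot classification analysis the
combined set of all participants is standardized together, matching common
practice for descriptive discriminant analysis.

## Univariate statistics

`group_summary()` reports per-metal group means, quartiles (type-7 linear
interpolation between order statistics — the convention is fixed so quartile
comparisons are reproducible), percent of cells below the LOD, the percent
difference of means `100 * (mean_ASD − mean_NT) / mean_NT` computed from
unrounded means (rounding happens only at report time), and a two-sided
pooled-variance Student's t-test p-value (Welch available via
`var_equal = FALSE`). No multiple-testing correction is applied across
metals. `hotelling_t2()` is the two-sample Hotelling T² with pooled
covariance and the exact F transformation
`F = (n₁+n₂−p−1) / ((n₁+n₂−2) p) · T²` on `(p, n₁+n₂−p−1)` degrees of
freedom; it requires `n₁+n₂−2 > p`.

## Kernel density estimation of discriminant scores

Score distributions are modelled with the classical estimator
`f̂(x) = (1/nh) Σᵢ K((x−xᵢ)/h)` for Gaussian, triangular, Epanechnikov, or
uniform `K` (Gaussian is the default: discriminant scores are smooth,
unbounded quantities). The bandwidth minimizes the least-squares
cross-validation estimate of the integrated squared error,

`LSCV(h) = ∫ f̂² − (2/n) Σᵢ f̂₋ᵢ(xᵢ)`,

whose minimizer tracks the MISE-optimal bandwidth. The squared-density
integral uses the closed-form kernel convolution for the Gaussian and
uniform kernels and a fine fixed-grid trapezoid rule for the bounded kernels
with kinks (adaptive quadrature is unreliable across a uniform kernel's
discontinuities). The search is a deterministic grid of 41 log-spaced
bandwidths on `[h_S/10, 10·h_S]` around the Silverman pilot
`h_S = 0.9 · min(sd, IQR/1.34) · n^(−1/5)` — a bounded search that needs no
starting value and is reproducible bit for bit.

## Discriminant classification

**Linear FDA.** The direction is the classical `w ∝ S_w⁻¹ (μ_ASD − μ_NT)`
with `S_w` the pooled within-class scatter of the standardized panel
(optional relative ridge for ill-conditioned scatters), unit-normalized,
sign fixed so ASD scores exceed NT scores on average.

**Kernel FDA.** With the Gaussian kernel
`k(x,x′) = exp(−‖x−x′‖²/2σ²)` on the z-score scale, the dual coefficients
solve the ridge-regularized kernel Fisher problem
`α = (N + λ·mean(diag N)·I)⁻¹ (M_ASD − M_NT)` where `M_g` are per-class mean
kernel columns and `N` the within-class kernel scatter; `score(x) = Σᵢ αᵢ
k(x, zᵢ)`. The ridge is expressed relative to the mean diagonal of `N` so
`λ` is comparable across problem sizes.

Scores from any fit are affinely normalized so the training class means sit
at +1 (ASD) and −1 (NT); held-out scores from different cross-validation
folds are therefore on a common scale before pooling.

**Error tradeoffs.** `error_tradeoff_loo()` removes each participant in
turn, refits standardization and discriminant on the rest, and scores the
held-out sample. Thresholds sweep the pooled held-out scores; for each
allowed Type I error on the fixed grid {0.40 … 0.10} the threshold is the
smallest value whose empirical held-out NT exceedance rate does not exceed
the allowance — empirical quantiles make the grid exact on finite samples,
unlike inverting a fitted density. Ties classify as NT (conservative on
Type I). The per-group KDEs retained for plotting are fitted to the pooled
held-out scores; fold-wise density refits would play no role in the
quantile thresholding.

**Hyperparameters.** No kernel width or ridge is canonical for this problem,
so `tune_kfda()` makes the choice explicit: a grid of widths (multiples
0.25–4 of the median pairwise z-score distance) crossed with ridges
{1e-3, 1e-2, 1e-1}, scored by the LOO total error (achieved Type I + Type
II) at a target operating point (default allowed Type I 0.15), with the full
grid returned for inspection.

## PLS and kernel PLS severity regression

**Linear PLS (NIPALS, single response).** Sequential covariance-maximizing
weight vectors with deflation; predictors centred/scaled and the response
centred on the training rows. At full latent count on a well-conditioned
design the coefficients equal ordinary least squares — one of the package's
frozen identity tests.

**Kernel PLS.** The kernel-matrix formulation with a centred Gaussian (or
linear) kernel and iterative deflation; predictions use the dual form
`U (TᵀKU)⁻¹ Tᵀy` with the test kernel centred against the training kernel.
With the linear kernel the predictions reproduce linear PLS to 1e-6 for
every latent count (second identity test).

**Cross-validated R².** For each LOO fold the model is refitted from
scratch; the criterion is `R² = 1 − SS_e/SS_y` where `SS_e` sums squared
held-out residuals and `SS_y` sums squared fold-centred responses (centring
from the training fold — the reading under which values near zero or
negative signal a model no better than predicting the mean). No
degrees-of-freedom adjustment is applied. The number of latent variables
(1 … subset size) is chosen to maximize this cross-validated R², i.e.
selection happens inside the same LOO loop that reports the statistic. This
mildly optimistic but standard protocol is retained as the primary mode
because it is the one the headline numbers use; the brute-force refit oracle
in the test suite pins its exact semantics.

The Gaussian width for kernel PLS, when not supplied, is selected from 15
log-spaced multiples (0.25–10) of the median pairwise predictor distance,
maximizing the same LOO R²; the winning width is reported in the result row.

**Subset search.** `subset_search()` enumerates every metal combination of
each requested size — all `2¹⁰ − 1 = 1023` subsets for the ten-metal panel —
and keeps the per-size maximum of the LOO R², breaking ties toward the
lexicographically first combination. No stepwise or penalized shortcut is
offered: the procedure is exhaustive by design. `fit_r2()` reports the
companion no-cross-validation fit R² (the OLS R² at full rank), whose
monotone growth with subset size against the rise-then-fall of the LOO curve
is the overfitting signature the pipeline is built to expose.

**Sensitivity profiles.** `sensitivity_profile()` holds all predictors at
their training means and sweeps one metal at a time across its training
range — a direct readout of each metal's marginal response shape (exactly
straight for linear fits; curved for kernel fits on saturating data).

## PCA of severity instruments

The eleven instruments have incommensurate scales, so `fit_pca()` analyses
the correlation structure (standardized columns). Loading signs follow a
deterministic convention (largest-magnitude loading positive).
`cluster_measures()` groups instruments by the angular proximity of their
leading two-component loading vectors: complete-linkage agglomeration on
cosine distance, tree cut at height 0.3 (≈ 45°); groups of ≥ 2 instruments
are clusters, singletons are flagged as outliers. The rule and cut height
are configurable — any eyeball grouping of a loading plot is a judgment
call, and this one is simply made explicit and reproducible.

## The synthetic-cohort generator

`reference_config()` freezes a cohort of 67 ASD / 50 NT participants whose
marginal structure approximates the reported univariate summaries for this
study design:

* **Marginals.** Log-concentrations are multivariate Gaussian (so
  concentrations are lognormal — group means far above medians in such
  panels indicate strong right skew). NT medians sit at the geometric
  midpoint of the reported NT quartiles; log-scale sigmas come from the
  quartile ratio, except for the heavily censored metals (Al, Hg, Sb) whose
  printed quartiles are substitution-distorted — their sigmas instead
  reconcile the two reported censoring fractions with the mean shift, clamped
  to [0.4, 1.8].
* **Group contrast.** The ASD log-location is shifted by `log(shift)` with
  the reported mean ratios (Pb 1.72, Sn 2.77, Tl 1.50, Sb 1.49, …), so the
  expected percent mean differences match the reported values exactly while
  the realized ones fluctuate with lognormal sampling noise.
* **Censoring.** Fixed per-metal limits are placed at the NT censoring
  quantile; cells below a limit are flagged and substituted with 2/3 of it.
  Censoring rates are therefore emergent, not forced, and thallium (0%/0%)
  is never censored.
* **Correlation.** Exchangeable correlation 0.3 on the log scale — a
  deliberately simple stand-in for common-exposure correlation.
* **Severity links.** Each instrument responds to a standardized
  combined-burden index `t` over its active metal subset (subsets follow the
  strongest reported per-measure combinations) through a saturating link
  with a U-shaped component, `amp·(tanh(gain·t) + u·(t²−1)/√2)`: saturation
  because doubling excretion need not double severity, and the U because
  both unusually low excretion (impaired detoxification) and unusually high
  excretion (high body burden) can accompany worse symptoms. This is the
  structure a kernel method can exploit and a linear projection cannot —
  the qualitative contrast the pipeline exists to measure. Two latent
  factors plant the observed instrument clusters (parent questionnaires vs
  professional evaluations); the sensory measure (SSP) is reverse-scored
  (negative amplitude) and mostly noise-driven, which places it away from
  both clusters. Amplitudes and noise levels were chosen once so that the
  linear LOO R² peaks around 0.5 at an intermediate subset size, kernel PLS
  exceeds it, and the first two principal components carry the majority of
  the instrument variance.
* **Seeding.** One master seed feeds a splitter (panel draw, latent
  factors, severity noise); equal seeds give byte-identical CSV output, and
  the caller's RNG stream is untouched.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: no age or gender structure, no assay measurement
error distinct from biological variability, no discreteness beyond rounding
scores to 0.1, no diagnosis subtypes, and an exchangeable rather than
empirical metal correlation matrix. Quantities that depend on those features
(e.g. exact reported R² values) are not reproduced, only the qualitative
regime.

## Numerical choices and degenerate inputs

* Sample statistics use the n−1 denominator throughout.
* Zero-variance columns, constant responses, empty classes in a fold,
  censored cells without a known LOD, and rank-deficient scatters raise
  classed errors naming the offending column where applicable.
* NIPALS stops when the residual weight norm falls below 1e-12; requesting
  more components than extractable is a rank error.
* Identical groups leave discriminant scores unscaled (the ±1 normalization
  is skipped below a 1e-12 separation).
* Subset-search ties break lexicographically; classification ties go to NT.

## Problem sizes

The test suite runs cohorts of 67/50 (the study design) for the end-to-end
checks and 10–80 rows for identity and property tests; replicate counts
(10–30) were chosen so Monte-Carlo error is comfortably inside the asserted
tolerances while the whole suite completes in about a minute. The
acceptance script performs the full 1023-subset linear search at 67-fold
LOO and evaluates kernel PLS on the strongest subsets; exhaustive kernel
enumeration (1023 subsets × 67 folds × 15 widths) is omitted as its cost
buys no additional information about the implementation.

## Known limitations

* The LOO-internal latent-count (and kernel-width) selection is optimistic;
  a nested protocol would give lower, more honest numbers. The package
  reports the standard protocol because it is the one the headline numbers
  of this literature use.
* Single-value 2/3-LOD substitution understates below-limit uncertainty;
  censored-likelihood methods are out of scope.
* The KFDA ridge form (on the within-class kernel scatter) is the standard
  reading of the kernel Fisher problem; other regularizations exist and give
  slightly different operating points.
* On cohorts whose group contrast is a pure location shift, tuned KFDA
  approaches but need not beat linear FDA; its advantage appears when class
  boundaries curve (the concentric-ring fixture in the tests isolates
  this).
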