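---
title: "Quantifying breast tissue organisation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying breast tissue organisation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammospat)
```

## The question and the pipeline

Mammographic percentage density (PD) — the fraction of the breast area
occupied by radiodense fibroglandular tissue — is a strong breast cancer
risk factor, but it ignores *where* in the breast the dense and fatty
tissue sit.  `mammospat` quantifies that spatial organisation and tests
whether it carries risk information beyond PD and the standard
epidemiological covariates.

The pipeline has five stages:

1. **Preprocessing.** The mammogram is rescaled to `[0, 1]`, denoised by a
   pixelwise adaptive (Wiener-type) minimum-MSE filter, and
   contrast-enhanced by `log(1 + c x)/log(1 + c)`.  A three-class Otsu
   multi-threshold separates background from tissue; the two brightest
   classes are kept, the largest 8-connected component is extracted and
   smoothed morphologically, and a simplified straight-line estimate of the
   pectoral muscle is removed from the mask.
2. **Tissue partition.** Breast pixels are clustered into four intensity
   classes by fuzzy C-means (FCM); hardened labels 1–4 correspond to
   fatty, semi-fatty, semi-dense and dense tissue, ordered by intensity.
3. **Forces histograms (FH).** For each ordered pair of classes and each of
   180 sweep directions (2° steps over 0–360°), parallel digital lines
   cover the image; on each line the pairwise force `1/d²` is summed over
   pixel pairs with the first class ahead of the second, and per-line
   weights are summed into one histogram bin.  Six histograms (one per
   unordered pair) describe an image.
4. **Functional PCA.** Across images, each histogram family is a sample of
   curves over angle.  Discretised functional PCA (eigendecomposition of
   the sample covariance on the angular grid) compresses each family into
   the scores of the leading eigenfunctions, retained up to 85% cumulative
   variance and standardised to zero mean, unit variance.
5. **Association.** The standardised scores enter an adjusted logistic
   regression of case–control status (adjustments: age, BMI, the square
   root of PD, a five-level parity/age-at-first-birth factor, HRT use).
   A global likelihood-ratio test on all score columns tests the spatial
   signal; a weighted score summarises it; Harrell-style bootstrap
   optimism correction yields "honest" per-SD odds ratios and AUCs; DeLong's
   test compares correlated AUCs; stepwise AIC selection names the most
   informative components, which linear determinant models then relate to
   the covariates.

## Conventions that define the forces histogram

The FH is the one primitive built entirely in this package (with a C++
line sweep and a pure-R brute-force oracle used in tests), so its
conventions matter:

* Pixels are indexed row-major with origin at the top-left; `x = col`,
  `y = -row`, angles counter-clockwise from the +x axis.
* For `|tan θ| ≤ 1` the digital lines are indexed by row-intercept with
  nearest-pixel sampling along columns (`round(x) = floor(x + 0.5)`), and
  by column-intercept with the roles swapped otherwise.  Every pixel lies
  on exactly one line of the family — the property that makes the
  brute-force oracle well defined.
* A pixel's position along its line is its scalar projection onto the
  direction vector; "ahead" means a strictly larger projection.  Bin θ of
  FH_ij accumulates `1/d²` over pairs with the class-i pixel ahead of the
  class-j pixel, giving the exact directional symmetry
  `FH_ij(θ) = FH_ji(θ + 180°)`.
* Distances are in pixel units of the 0.25 mm analysis grid; histograms are
  not normalised by default (breast size is handled downstream as a
  covariate; a sum-to-one flag exists).

Two numerical consequences are worth knowing.  First, translation
invariance is exact only when the shift does not change the nearest-pixel
digitisation (axis/diagonal directions, or shifts along the line-index
axis); at general angles the re-digitised lines perturb bins by a few
percent.  Second, two isolated pixels on the same row produce small
non-zero bins at neighbouring angles (±2–6°), because nearby directions'
digital lines still contain both pixels; the closed form `1/d²` holds
exactly at the aligned angle.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| Wiener window | 5 px | neighbourhood of the adaptive denoiser; 1 = identity |
| log-contrast gain `c` | 9 | mid-grey brightening of the enhancement map |
| morphology radius | 1% of width | disc radius for mask closing/opening |
| FCM fuzzifier `m` | 2 | conventional softness; `m → 1` approaches k-means |
| FCM tolerance / cap | 1e-6 / 300 | centroid-shift stop rule |
| analysis grid | 0.25 mm/px | label maps are nearest-neighbour downscaled to it |
| angles `a` | 180 | 2° angular resolution of each histogram |
| variance threshold | 0.85 | cumulative-variance retention rule for components |
| bootstrap `B` | 1000 | optimism-correction resamples (tests use 100–200) |

The denoiser window, contrast constant and morphology radius are
conventional values, exposed as arguments rather than claimed to be
canonical.  FCM is initialised deterministically with centroids spaced
evenly over the observed intensity range: starting from intensity
percentiles can place two centroids inside one dominant stratum (a very
fatty breast) and converge to a local optimum that merges the dense
classes, while range-spaced starts put one centroid near each stratum
regardless of class balance.  Percentile and seeded-random initialisation
remain available.

Clustering operates on the denoised, pre-enhancement intensities: the
logarithmic map is needed to pull the faint skin line above the background
for mask extraction, but it compresses exactly the bright (dense) end of
the scale that the four-class partition must resolve.

## What the synthetic generator does and does not emulate

`phantom_spec()`/`generate_phantom()` render an idealised MLO view: a
breast half-ellipse flush with the chest-wall edge, a bright right-triangle
pectoral region in the adjacent corner, a skin-line intensity fall-off over
the outer 3% of the radius, and four Gaussian intensity classes.  Dense
and semi-dense tissue form Gaussian blobs at controllable polar positions;
the remaining pixels split between fatty and semi-fatty with the fatty
probability tilted towards the skin line and (via a single weight) towards
the lower quadrants.  The weight makes "fatty tissue concentrated in the
lower quadrants" a recoverable ground-truth parameter.

`cohort_spec()`/`generate_cohort()` draw covariates calibrated to a
post-menopausal Swedish screening population (age ≈ 63 ± 6.5 y,
BMI ≈ 25 ± 3.7, PD ≈ 17 ± 14 truncated to [0, 100], HRT
never/past/current ≈ 73/6/21%, five parity/age-at-first-birth strata) and
two standard-normal latent spatial parameters per subject: the polar angle
of the dense blob and the lower-quadrant fat weight.  Case status is
Bernoulli with a logistic model over covariates and latents; the intercept
is auto-calibrated by root finding so the expected case count matches the
requested design, and subjects are then sampled by status to exact counts.
Each subject's phantom realises her latents; the blob spread is tied to
her PD draw so that density and spatial layout remain confounded, as they
are in real breasts.

Not emulated: compression physics, scatter and beam hardening, texture
within tissue classes, craniocaudal views, laterality, and the full
within-image heterogeneity of real parenchyma.  Passing tests on phantoms
therefore demonstrate that the measurement chain recovers planted spatial
structure and that the statistics are calibrated — not that the specific
biological findings would replicate on clinical images.

## Statistical design notes

* **Discretised fPCA.** Histogram curves are densely and regularly
  observed, so functional PCA reduces to PCA of the grid values: the mean
  curve is subtracted, the sample covariance (divisor `n − 1`, uniform
  quadrature weights) is eigendecomposed, eigenfunction signs are fixed by
  a positive first-grid-point convention, and scores are grid inner
  products.  Sparse-data estimators would add machinery without changing
  the estimand.
* **Retention `K`.** The 85% cumulative-variance rule is normative; the
  resulting `K` (typically 1–3 per histogram family) is data dependent.
* **Bootstrap scope.** Within each optimism resample only the supervised
  steps (logistic fit, score construction, score-model fit) are refit; the
  eigenbases are held fixed because they are computed without outcome
  labels.  The AUC test index applies the resample-trained coefficients to
  the original data without refitting; the effect-size index refits the
  trained score's coefficient on the original data, following the usual
  internal-validation scheme.  Resamples whose fits are pathological
  (non-convergence, rank loss, runaway coefficients) are dropped; more
  than 5% of them is reported as an error.
* **Honest-estimate calibration.** On null cohorts of 600 subjects with 13
  noise scores, the honest AUC averages ≈ 0.5 (per-cohort sampling sd
  ≈ 0.015) while the apparent AUC sits near 0.6 — the correction removes
  essentially all of the overfitting optimism.  With ~10 score columns and
  a few hundred subjects the 13-df likelihood-ratio test runs very
  slightly hot at the 5% level, a finite-sample property of the chi-square
  approximation rather than a leak in the pipeline.
* **PD scale.** `sqrt(PD)` is the default adjustment scale; raw PD and a
  five-category coding ([0,5), [5,10), [10,20), [20,40), [40,100]) are
  straightforward alternatives since the cohort table carries raw PD.
* **Stepwise selection** minimises AIC over the component terms only, with
  the adjustment set forced into every model; the scan order is the column
  order and ties keep the current model.
* **Separation and rank problems** in user-facing fits raise typed errors
  rather than returning silently unstable estimates.
* **Degenerate inputs.** An empty hardened tissue class is allowed and
  flagged; the forces histogram of an empty region is the zero vector, so
  its component scores standardise to constants and drop out of the
  likelihood.  A constant curve family is a `degenerate-data` error in
  `fit_fpca()`.

## Problem sizes used by the tests and the acceptance script

Property tests run the line sweep against the brute-force oracle on label
maps up to 64×64; end-to-end recovery uses cohorts of 240 subjects with
64×64 phantoms at the 0.25 mm grid and 180 angles, where the planted
lower-quadrant-fat effect (per-SD log-odds 1) is detected by the global
test in essentially every replicate; optimism-correction calibration uses
600 subjects and 200 resamples.  These sizes were chosen so the whole
suite exercises every stage at full angular resolution while each
simulated study stays in the seconds-to-a-minute range.

## Known limitations

* The pectoral-muscle remover is a deliberately simple straight-line,
  gradient-guided substitute for full texture-gradient segmentation; it is
  adequate for the idealised phantom geometry and flagged as such.
* The four-class partition is fixed; very low-density breasts are still
  split into four strata (an adaptive class count is out of scope).
* FH bins are rasterisation-dependent at the few-percent level at general
  angles; comparisons across images on the same grid are unaffected.
* Synthetic-cohort conclusions transfer to real data only to the extent
  the phantom family captures the relevant geometry (see above).
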