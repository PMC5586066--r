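# mammospat

Spatial organisation of breast tissue from mammograms, and its association
with case–control status.

Mammographic percentage density (PD) — the fraction of the breast area
occupied by radiodense tissue — is an established breast cancer risk
factor, but it says nothing about *where* the dense and fatty tissue lie.
`mammospat` measures that layout on mediolateral-oblique (MLO) mammograms
and tests whether it carries risk information beyond PD, age, BMI, HRT use
and parity/age at first birth.  It is aimed at epidemiologists and
image-analysis researchers working with case–control mammography studies,
and ships a synthetic phantom/cohort generator so the whole chain is
testable without clinical images.

## Method

For one image, segmented into four intensity classes (1 fatty … 4 dense)
by fuzzy C-means, the **forces histogram** between classes *i* and *j* is

FH<sub>ij</sub>(θ) = Σ<sub>lines ∥ θ</sub> Σ<sub>p∈i, q∈j, p ahead of q</sub> 1/‖p−q‖²,

evaluated over 180 directions (2° steps over 0–360°); six histograms
describe an image.  Across images each histogram family is compressed by
functional PCA — eigendecomposition of the sample covariance of the
curves, retaining components up to 85% cumulative variance — and each
image is reduced to standardised component scores fPC<sub>ij</sub><sup>k</sup>.
The scores enter an adjusted logistic regression of case–control status;
a global likelihood-ratio test on all score columns tests the spatial
signal, a coefficient-weighted **spatial-relations score** summarises it,
and Harrell-style bootstrap optimism correction converts apparent per-SD
odds ratios and AUCs into "honest" ones.  DeLong's test compares
correlated AUCs, stepwise AIC selection names the informative components,
and linear determinant models relate them to the covariates.

## Worked example

Simulate a 240-subject case–control study in which fatty tissue
concentrated in the lower quadrants is protective (per-SD log-odds 1 on
the latent fat-position parameter), then run the full image pipeline:

```r
library(mammospat)

cs  <- cohort_spec(n_cases = 100, n_controls = 140,
                   beta = c(sqrt_pd = 0.2, lower_quadrant_fat = 1),
                   seed = 11)
g   <- generate_cohort(cs)
run <- run_pipeline(g$cohort, g$phantom_specs,
                    segmentation = "pipeline",
                    B = 200, seed = 42, stepwise = TRUE)
print(run)
#> <mammospat_run> n=240 subjects, 9 component scores
#>   global LRT: chi2=28.94 on 9 df, p=7e-04
#>   stepwise-selected: fpc14_1, fpc14_2, fpc34_1
#> <validation_report> B=200 bootstrap resamples (0 failed)
#>   per-SD OR of the score: apparent 2.372, honest 1.612
#>   AUC with score:         apparent 0.731, honest 0.648
#>   AUC without score:      apparent 0.600, honest 0.532
```

The global test detects the planted spatial effect (p = 7e-04 on 9 df)
after adjustment for density and the other risk factors; the stepwise
selection picks components of the fatty–dense histograms; and the
bootstrap shows how much of the apparent score performance (per-SD OR
2.37, AUC 0.731) survives optimism correction (honest OR 1.61, honest AUC
0.648).

Unadjusted covariate tests from published case/control category counts are
one call:

```r
lrt_contingency(cases    = c(157, 349, 372, 214, 78),
                controls = c(129, 354, 351, 351, 98))
#> chi2 = 34.01 on 4 df, p = 7e-07
```

## Package tour

| Stage | Functions |
|---|---|
| synthetic data | `phantom_spec`, `generate_phantom`, `cohort_spec`, `generate_cohort`, `generate_curves` |
| preprocessing | `rescale_and_denoise`, `enhance_contrast`, `otsu_multithreshold`, `segment_breast`, `remove_pectoral`, `preprocess_mammogram` |
| tissue partition | `fuzzy_cmeans`, `harden_labels`, `rescale_labelmap`, `segment_tissue` |
| forces histograms | `sweep_lines`, `line_force`, `compute_fh`, `compute_fh_set`, `fh_oracle`, `fh_set_matrix` |
| functional PCA | `fit_fpca`, `project`, `mode_of_variation`, `dominant_angles` |
| association | `fit_logistic`, `likelihood_ratio_test`, `lrt_contingency`, `global_spatial_test`, `build_score`, `per_sd_odds_ratio`, `auc`, `delong_test`, `optimism_bootstrap`, `stepwise_select`, `fpc_determinant_regression` |
| orchestration | `run_pipeline`, `validate_transfer`, `cohort_fh_curves` |

The methods vignette (`vignettes/tissue-organisation-methods.Rmd`) records
the conventions behind the forces histogram, the parameter defaults, what
the phantom generator does and does not emulate, and the statistical
design choices.
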