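# logradiomics

Region-wise multi-scale texture radiomics for parcellated 3-D volumes, with
the statistical machinery to relate regional texture to group membership and
continuous covariates.

## What it does

Classical morphometry compares region volumes or voxel intensities between
cohorts. This package instead characterizes the *texture* of each labeled
region: the input volume (typically a skull-stripped, intensity-normalized
T1-weighted brain MRI with a FreeSurfer-style `aseg` parcellation, both as
NIfTI) is filtered with the Laplacian-of-Gaussian (LoG) operator

$$ f_\sigma = \nabla^2 (G_\sigma * f) $$

at three scales (σ = 0.5, 1.5, 2.0 mm — fine, medium, coarse), and the
distribution of filter responses inside each of 31 sub-cortical regions is
summarized by three quantifier functions: the average **A**, the population
standard deviation **SD**, and the histogram entropy
**E** = −Σₖ pₖ log₂ pₖ over 256 equal-width bins of the region's response
range. Each subject is thus reduced to 31 × 3 × 3 = 279 features.

Three analyses operate on the resulting feature table:

* **Two-group comparison** (e.g. diagnosis, sex): a permutation test on the
  absolute difference of group medians (ABM), 100 000 label permutations by
  default, plus an optional balanced-bootstrap Wilcoxon analysis pooled by
  Fisher's method (−2 Σ ln pᵢ ~ χ²₂ₖ) for relative ranking of features.
* **Covariate correlation** (e.g. age): Spearman rank correlation, a
  two-sided permutation p-value, and a bootstrap 95% lower bound on |ρ|
  (the 5th percentile of 100 resampled correlations).
* **Family-wise error control**: Holm–Bonferroni over all 279 tests,
  significance at corrected p < 0.05.

A Gaussian-random-field phantom generator builds labeled synthetic cohorts
with controllable per-region mean, texture amplitude τ, and correlation
length ℓ, plus group-, sex- and age-linked effects — so the whole pipeline
is validated end to end on data with known ground truth.

## Worked example

Simulate a 50-subject phantom cohort in which the "ASD" group has 40% more
texture amplitude in one of two structures, extract features, and run the
group analysis:

```r
library(logradiomics)

regions <- list(
  phantom_region(1, "left-nucleus",  "sphere", c(10, 16, 16), 6),
  phantom_region(2, "right-nucleus", "sphere", c(23, 16, 16), 6))
baseline <- list(`left-nucleus`  = texture_params(tau = 1),
                 `right-nucleus` = texture_params(tau = 1, ell = 1.5))
effect <- list(effect_spec("right-nucleus", "group", "tau",
                           values = c(ASD = 1.4, TDC = 1.0)))

spec   <- cohort_spec(grid_dim = c(32, 32, 32),
                      n_per_group = c(ASD = 25, TDC = 25), seed = 7)
cohort <- simulate_cohort(spec, regions, baseline, effect)

features <- extract_cohort_features(cohort$volume_source, n = 50,
                                    region_map = cohort$region_map)
dim(features)
#> [1] 50 19        # subject_id + 2 regions x 3 scales x 3 quantifiers

fit <- run_full(cohort, mode = "group", features = features,
                n_permutations = 10000, seed = 7)
subset(fit$results, significant, select = c(feature, abm, p_raw, p_holm))
#>                     feature        abm     p_raw     p_holm
#> 5  right-nucleus__0.500__SD 1.40588146 9.999e-05 0.00179982
#> 11 right-nucleus__1.500__SD 0.06865132 9.999e-05 0.00179982
#> 17 right-nucleus__2.000__SD 0.02521191 9.999e-05 0.00179982
```

Exactly the injected effect is recovered: the SD features of the affected
region are significant after Holm correction at every scale (raw p is the
smallest value achievable with 10 000 permutations, 1/(N+1)), the ABM
column gives the observed median difference on each feature's own scale,
and no feature of the unaffected region is flagged. `run_full` can also
write feature tables, result tables, −log10 p heatmap matrices and a
reproducibility manifest to an output directory; `mode = "sex"` and
`mode = "age"` switch to the sex comparison and the age-correlation
analysis (optionally restricted to a control group).

Real cohorts enter the same way: read volumes with
`read_labeled_volume("brain.nii.gz", "aseg.nii.gz")`, drop
quality-assessment failures with `apply_exclusions()`, and pass the volumes
and a metadata table (`subject_id`, `group`, `sex`, `age`, `site`) to
`run_full()`. A thin command-line wrapper with `simulate` / `extract` /
`analyze-group` / `analyze-correlation` / `sweep` subcommands is installed
at `inst/cli/logradiomics.R`.

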