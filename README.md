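# fcdlong

Longitudinal functional connectivity density (FCD) mapping for
resting-state fMRI, built for small stroke cohorts scanned repeatedly
during recovery. After a subcortical stroke, connectivity in
sensorimotor hubs typically drops and then returns toward control
levels over months, while cognitive-control hubs show the mirrored
excess-then-normalisation course; `fcdlong` provides the full analysis
chain needed to detect and model such trajectories, plus a synthetic
cohort generator so the whole pipeline is testable end to end without
any imaging download.

The package is aimed at neuroimaging methodologists and analysts who
want a transparent, fully tested reference implementation of:

* **FCD mapping** — per-voxel counts of supra-threshold correlations
  (`r > 0.6` within a 50%-of-mean grey-matter mask), split by region
  growing into spatially contiguous **short-range** FCD and
  **long-range** FCD (global − short), grand-mean scaled and smoothed
  (8 mm FWHM).
* **Seed-based FCS** — Fisher-z maps `z = atanh(r)` of seed-ROI mean
  series against every voxel, with one-sample t group masks under
  Bonferroni familywise correction.
* **A random-intercept longitudinal model**, fitted by REML via 1-D
  profiling of the variance ratio:

  `Y_ij = u + b_i + X_ij β1 + X_ij² β2 + ε_ij`,  `b_i ~ N(0, σ_b²)`,
  `ε_ij ~ N(0, σ_e²)`,

  where `X_ij` is days post-onset, a subject-centred clinical score, or
  a regional grey-matter volume. Voxel-wise `β1`/t/p maps are the
  primary output; mean framewise displacement enters as a nuisance
  covariate.
* **Monte-Carlo cluster-extent correction** (AlphaSim-style): smoothed
  null fields in the analysis mask yield the minimum cluster size whose
  familywise error is 0.05 at a cluster-forming voxel p of 0.01.
* **Clinical-table tools** for per-session scan-timing statistics,
  subject-centred score normalisation and paired recovery tests; the
  package ships the study's patient table
  (`inst/extdata/table1_clinical.tsv`).

## Worked example

Clinical descriptives from the packaged patient table:

```r
library(fcdlong)
co <- read_clinical_table(system.file("extdata", "table1_clinical.tsv",
                                      package = "fcdlong"))
session_interval_stats(co)
#> # A tibble: 5 × 4
#>   session mean_day sd_day     n
#>     <int>    <dbl>  <dbl> <int>
#> 1       1      3     2.08     7
#> 2       2     13     1.51     8
#> 3       3     31.4   2.67     8
#> 4       4     97.6  24.5      8
#> 5       5    370.   42.8      7
cohort_demographics(co)
#> # A tibble: 1 × 5
#>   mean_age age_min age_max n_patients n_complete
#> 1       49      41      55          8          6
recovery_test(co, "mi")
#> # A tibble: 2 × 5
#>   method               statistic   p_value direction     n
#> 1 paired_t                  8.83 0.0000483         1     8
#> 2 wilcoxon_signed_rank     36    0.00781           1     8
```

Scans cluster at roughly 3, 13, 31, 98 and 370 days post-onset; six of
eight patients attended all five sessions, and motor scores improve
significantly between the first and last attended session.

The full synthetic analysis — simulate a cohort, preprocess, map FCD,
fit the voxel-wise time model, cluster-correct, and model the detected
regions' trajectories and clinical associations:

```r
rep <- run_full_analysis(run_config(seed = 7))
rep
#> <fcd_report> 8 patients x 5 sessions + 10 controls; 4 significant cluster(s)
#>   clusters: short_pos_1, short_neg_1, long_pos_1, long_neg_1

dplyr::filter(rep$group_tests, region == "short_pos_1", session %in% c(1, 5))
#> # A tibble: 2 × 6
#>   region      session       t  p_value mean_patient mean_control
#> 1 short_pos_1       1 -64.7   2.25e-13       0.0182         2.95
#> 2 short_pos_1       5  -0.092 9.28e- 1       2.94           2.95

dplyr::filter(rep$associations, region == "short_pos_1")
#> # A tibble: 3 × 5
#>   region      predictor   beta1     t  p_value
#> 1 short_pos_1 mi         0.0198  33.5 8.38e-30
#> 2 short_pos_1 nihss     -0.303  -22.1 2.58e-23
#> 3 short_pos_1 gmv       -0.328  -15.0 1.40e-17

autoplot(rep)   # per-region trajectories with the control band
```

Read: the positive-slope short-range FCD cluster (the injected
sensorimotor-like hub) sits far below controls at the first time point
(scaled FCD 0.02 vs 2.95, p ≈ 2e-13) and is indistinguishable from
controls by one year (p = 0.93); its FCD rises with the Motricity Index,
falls with NIHSS severity, and is negatively associated with regional
grey-matter volume. The negative-slope cluster over the cognitive-like
hub shows the mirrored excess-then-normalisation course.

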