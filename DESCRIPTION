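Package: fcdlong
Title: Longitudinal Functional Connectivity Density Mapping After Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise functional connectivity density (FCD) mapping for
    longitudinal resting-state fMRI, with region-growing short-range FCD,
    seed-based Fisher-z functional connectivity strength (FCS), a
    voxel-wise random-intercept mixed-effects model fitted by restricted
    maximum likelihood, and Monte-Carlo cluster-extent correction for
    multiple comparisons. Includes a synthetic longitudinal stroke-cohort
    generator (band-limited community-structured BOLD time series, motion
    traces, lesion signal dropout, clinical-score trajectories) so the
    whole pipeline can be exercised end to end, and tools for descriptive
    analysis of clinical recovery tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    Rcpp,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
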