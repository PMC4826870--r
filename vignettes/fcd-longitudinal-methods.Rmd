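---
title: "Longitudinal functional connectivity density mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal functional connectivity density mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fcdlong` implements a longitudinal resting-state fMRI analysis for small
stroke cohorts scanned repeatedly during recovery: voxel-wise functional
connectivity density (FCD) mapping, seed-based functional connectivity
strength (FCS), a random-intercept mixed-effects model of change over
days post-onset, and Monte-Carlo cluster-extent correction. This
vignette is the package's own account of the methods: the models, their
assumptions, the tunable parameters, the numerical choices, and what the
synthetic cohort generator can and cannot tell you about real data.

## Functional connectivity density

FCD is a voxel-level degree measure. After preprocessing, a pair of
voxels is *functionally connected* when the Pearson correlation of their
time series exceeds a threshold (default `r_threshold = 0.6`, strict
inequality; ties at exactly 0.6 are excluded). Analysis is restricted to
voxels whose temporal-mean signal exceeds half the whole-volume mean
(`gm_fraction = 0.5`), which removes low-signal regions — susceptibility
dropout and, in this package's synthetic data, the lesion core.

For a voxel $x_0$:

* **global FCD** counts all other in-mask voxels connected to $x_0$;
* **short-range FCD** counts the spatially contiguous part, found by
  region growing: starting from the spatial neighbours of $x_0$, a voxel
  is admitted when it is adjacent (26-connectivity by default) to an
  already-admitted voxel and correlates with $x_0$ above threshold;
* **long-range FCD** is global minus short-range.

The growth rule deserves a note. Read literally, growth admits a
candidate when it correlates with the *adjacent admitted* voxel (a
"frontier" rule). Under that rule the grown set need not be a subset of
$x_0$'s global neighbour set, and long-range FCD can go negative. We
implement both rules; the default `seed_correlation` rule (admission
requires correlation with $x_0$ itself) makes the short-range set exactly
the spatially connected component of the global set containing $x_0$, so
$0 \le \mathrm{short} \le \mathrm{global}$ holds everywhere by
construction. The `frontier_correlation` variant is available in
`fcd_config()` for comparison; a unit test exhibits a three-voxel chain
where the two rules differ.

Each count map is grand-mean scaled — divided by its in-mask mean, so the
scaled map averages 1 over the mask. The scaling denominator is the mean
over the grey-matter-restricted mask, since that set is the "whole brain"
of the calculation. Scaled short- and long-range maps are then smoothed
with an 8 mm FWHM Gaussian ($\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$,
in voxel units through the voxel size); the kernel is renormalised within
the mask so edge voxels are not attenuated by the zeros outside, and the
global map is left unsmoothed by default since downstream analysis uses
the short/long split. Constant time series have undefined correlations;
we define them as 0 (never connected) and emit a warning.

The pairwise-correlation computation is tiled over seed blocks
(`block_size`, default 512), so memory stays proportional to
block × mask size rather than mask²; results are identical to the full
matrix. Correctness of all three maps is asserted against an independent
brute-force implementation (explicit correlation matrix, naive set
growth) on dozens of randomised small grids, with exact integer equality.

## Seed-based FCS

Regions with significant FCD change become seed ROIs. For a seed, the
mean time series over seed voxels is correlated with every in-mask voxel
and Fisher-z transformed ($z = \operatorname{atanh} r$, with $r$ clipped
to $\pm(1-10^{-7})$ so $z$ stays finite). Per-subject z-maps from the
control group enter a voxel-wise one-sample t-test ($df = n-1$); the
familywise-corrected mask of significantly connected voxels uses
Bonferroni over the in-mask voxel count. Bonferroni was chosen because
the familywise method is otherwise unspecified at this scale:
deterministic, conservative, and free of random-field assumptions that
would be dubious on a 20³ toy grid. Seed voxels are retained in the map
(they are trivially significant); comparisons that need them excluded do
so via the ROI definition. Patient-versus-control FCS comparisons are
made within the control-derived mask, and FCS uses spatially smoothed
(8 mm) data, matching how the measure is ordinarily computed.

## The longitudinal model

The response at voxel (or region) level is modelled as

$$Y_{ij} = u + b_i + X_{ij}\beta_1 + X_{ij}^2\beta_2 + \varepsilon_{ij},
\qquad b_i \sim N(0, \sigma_b^2),\quad
\varepsilon_{ij} \sim N(0, \sigma_e^2),$$

a common slope with a per-subject random intercept, which uses every
available scan even when sessions are missing. $X_{ij}$ is days
post-onset for the time model, a subject-centred clinical score
(Motricity Index or NIHSS, centred within subject over attended
sessions) for association models, or a regional grey-matter volume for
structure–function models. The quadratic term is estimated but the
linear coefficient $\beta_1$ is the primary output.

Estimation is by REML. Because the only variance ratio is
$\lambda = \sigma_b^2/\sigma_e^2$, the criterion is profiled in one
dimension: given $\lambda$, the GLS solution and $\hat\sigma_e^2$ are
closed-form through per-subject Woodbury identities (each subject's
block of $V = I + \lambda ZZ^\top$ inverts analytically), and
$\log\lambda$ is optimised over $[-12, 12]$ by bounded 1-D search. The
boundary $\sigma_b^2 = 0$ is evaluated exactly and wins ties, so a
boundary fit reproduces OLS to machine precision — asserted to 1e-8 in
tests, alongside agreement with `lme4::lmer` (used purely as an
independent cross-check) and with a brute-force grid search over the
REML criterion.

Inference on $\beta_1$ uses a Wald t with $df = n_\mathrm{obs} -
\mathrm{rank}(X)$. No degrees-of-freedom correction (Satterthwaite,
Kenward–Roger) is applied; with 8 subjects × 5 occasions this residual
df is mildly liberal, and the simulated type-I error of the test sits
near 0.055 at nominal 0.05 (checked over 1000 null fits), inside the
0.03–0.07 band we consider acceptable for this design. The predictor is
centred before squaring by default (`center_predictor = TRUE`) purely
for conditioning — with a quadratic term this re-parameterises the
intercept and linear coefficient ($\beta_1^{u} = \beta_1^{c} -
2\beta_2\bar x$) without changing the fitted model, which the tests
assert. Mean framewise displacement enters voxel-wise fits as an
optional additional fixed effect (default on), treating motion as a
nuisance covariate throughout.

## Monte-Carlo cluster-extent correction

Voxel-wise p-maps are corrected AlphaSim-style. Per iteration the
analysis mask is filled with iid standard normal noise, smoothed at the
imposed FWHM (8 mm; smoothness is imposed by convolution, not estimated
from residuals, matching the fixed-FWHM mode of the classic program),
restandardised within the mask, and thresholded at the z-quantile of the
cluster-forming p (default 0.01, one-sided on the |statistic| map;
sidedness is configurable). Components are labelled under the
connection-radius neighbourhood — all integer offsets within 5 mm, which
at 3 mm isotropic voxels is the 18-neighbourhood — and the maximal
component size recorded. The cluster-extent threshold is the smallest
$k$ with empirical $P(\max \ge k) \le 0.05$. Tests verify that fresh
null fields exceed the derived threshold at close to the nominal rate
(empirical FWER ≈ 0.05 at 500 fresh fields) and that the threshold is
non-decreasing in FWHM. A cluster-extent threshold is a property of the
specific mask, grid and smoothness it was calibrated on; thresholds
computed on the package's toy grids are not comparable to values
reported for whole-brain grey-matter masks.

## Preprocessing

Within each session, every voxel series is replaced by its OLS residual
on an intercept, the six rigid-motion parameters, and the white-matter
and ventricle mean signals (generator-supplied in the synthetic
pipeline; no tissue segmentation is performed). Residuals are then
band-pass filtered to 0.01–0.08 Hz with an ideal FFT filter: Fourier
coefficients outside the band, including DC, are zeroed. The ideal
filter was preferred to a Butterworth design because it is exactly
idempotent and deterministic, which makes pipeline properties testable
to machine precision; the regress-then-filter order is fixed.
Framewise displacement is the Power convention:
$\mathrm{FD}_t = \sum|\Delta d| + 50\,\mathrm{mm}\cdot\sum|\Delta\theta|$,
translations in mm plus rotations converted to arc length on a 50 mm
sphere, first frame 0. Slice-timing correction, realignment and spatial
normalisation are out of scope: the synthetic data are generated already
aligned on a common grid.

## The synthetic cohort generator

The generator exists so that every downstream stage can be exercised —
and its statistical claims audited — without any data download. Defaults
emulate the study conditions: eight patients scanned at five time points
(3, 13, 31, 98, 370 days post-onset, the printed interval means), ten
controls scanned once, 3 mm isotropic voxels on a 20³ grid, TR 2 s, 170
retained volumes, and a 0.01–0.08 Hz latent passband.

Each community (two bilateral sensorimotor-like hubs sharing one latent
signal, two bilateral cognitive-like hubs sharing another; 64 voxels
each) assigns its voxels a loading $l$ on a band-limited latent produced
by FFT-domain filtering of white noise — chosen over AR processes for
exact spectral control and determinism given the seed. A voxel series is
`amplitude * (l * latent + nuisance + white noise)` on top of a positive
mean intensity; the lesion box gets 10% of the mean intensity, so the
50% grey-matter criterion excludes it exactly the way real signal
dropout enters the pipeline. After band-pass filtering only the in-band
fraction $f \approx 0.28$ of the white-noise variance survives, so the
expected within-community correlation is $l^2 / (l^2 + f\sigma^2)$ with
$\sigma = 0.5$. The default loadings place controls' sensorimotor hubs
well above the $r = 0.6$ threshold ($l = 0.6$, $r \approx 0.84$) and
patients' at-onset hubs well below ($l = 0.2$, $r \approx 0.36$), with a
linear-in-days recovery reaching the control loading at one year;
cognitive hubs run the mirrored course (patient $l$ from 0.55 down to
the control 0.30, i.e. initial excess normalising by one year). No
effect size is claimed to match the original study — none is published —
so these were chosen once for comfortable recoverability at the study's
sample sizes and are fully config-exposed.

Clinical trajectories are coupled to the injected physiology: each
patient's MI rises linearly in the sensorimotor recovery fraction (plus
noise, clamped to 0–200) and NIHSS falls with it; regional grey-matter
volume for sensorimotor regions carries a component anti-correlated with
the connectivity recovery, so the structure–function association model
has a real signal to find. Motion traces are smooth random walks. All
randomness derives deterministically from one base seed through a
per-(subject, session) seed scheme.

What the generator does *not* emulate: hemodynamic response shapes,
scanner artefacts and drifts, EPI distortion, spatially varying noise,
anatomical variability, or realistic lesion geometry. Passing tests
therefore demonstrate that the *algorithms* are correct and the
*inference* calibrated under the assumed signal model — not that the
pipeline's biological conclusions transfer to any particular real
dataset.

## End-to-end analysis and problem sizes

`run_full_analysis()` chains the stages in analysis order: simulate →
preprocess → FCD per session → voxel-wise time model on the scaled,
smoothed short- and long-range maps (mean FD as covariate) → cluster
correction (positive- and negative-slope clusters separately) → detected
clusters become seed ROIs → control-derived FCS masks and per-session
ROI-pair FCS → patient-versus-control Welch tests per time point
(binned by session index, matching how such trajectories are plotted) →
clinical and GMV association models → trajectory tables and figures.
Reruns with the same configuration are numerically identical; when an
output directory is given, tables are written as TSV with a JSON
provenance sidecar (seed, parameters, derived cluster threshold,
versions).

Problem sizes were chosen so a complete run stays comfortable on a
single CPU: the default 20³ grid with 50 sessions completes the whole
chain in about three minutes, the oracle-equivalence sweep uses fifty
4–6³ grids, mixed-model calibration uses 500 recovery replicates and
1000 null fits, and the cluster-null calibration uses 1000 iterations on
a 15³ mask with 500 fresh fields for the familywise-error check. The
unit suite uses a further-reduced 12³ cohort (4 patients × 3 sessions)
for pipeline-level tests.

## Known limitations

* Random intercepts only: no random slopes, no serial (AR(1)) residual
  correlation within subject.
* Wald inference with residual df; small-sample df corrections are not
  implemented.
* Binarised (count) FCD only — no weighted degree, surface-based or
  sliding-window variants.
* The Bonferroni FCS mask is conservative; on real whole-brain grids a
  random-field or permutation approach may be preferable.
* The cluster-null simulation imposes smoothness rather than estimating
  it from residuals; on real data estimated smoothness is usually the
  safer choice.
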