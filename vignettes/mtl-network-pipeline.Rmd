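---
title: "Methods: seed-based medial temporal lobe network analysis with planted ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-based medial temporal lobe network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtlnet)
```

## The scientific problem

The perirhinal (PRC) and parahippocampal (PHC) cortices are the cortical
hubs of two large-scale systems converging on the medial temporal lobe: the
anterior-temporal (AT) network and the posterior-medial (PM) network.  Their
resting-state functional connectivity changes differently with healthy aging
and along the Alzheimer's continuum, which makes scalar summaries of AT and
PM connectivity candidate markers of disease stage and progression.

`mtlnet` implements the full analysis chain that turns resting-state BOLD
runs into such summaries and statistical conclusions:

1. **Preprocessing** — bandpass filtering (0.01–0.08 Hz), nuisance
   regression (white matter, CSF, global signal, their first differences,
   six motion parameters), framewise displacement (FD), and motion-based
   run exclusion (translation > 3 mm or mean absolute Euler rotation
   > 1.5°).
2. **Seed connectivity** — mean PRC/PHC seed time courses correlated with
   every grey-matter voxel, Fisher z-transformed, optionally smoothed; a
   signal-dropout analysis mask from dual grey-matter segmentations
   thresholded at 0.25.
3. **Network mask inference** — one-sample and paired sign-flip permutation
   t-tests with threshold-free cluster enhancement (TFCE) and max-statistic
   family-wise error (FWE) correction at α = 0.05; the AT mask is the
   intersection of the PRC one-sample and PRC > PHC paired results, the PM
   mask the intersection of the PHC one-sample and PHC > PRC results.
4. **Index extraction** — participant-specific masks (group mask ∧ grey
   matter ≥ 0.5, seeds removed), and the network index as the mean of
   strictly positive Fisher-z values in unsmoothed maps.
5. **Statistics** — REML linear mixed models with by-participant random
   intercepts and Satterthwaite type II/III F-tests, ranked-group penalized
   smooths (k = 6), baseline ANCOVA with estimated-marginal-mean contrasts,
   and Holm–Bonferroni correction within the declared test family.

Because no participant data are distributable, the package ships a
first-class synthetic-data generator with known ground truth, and every
claim the pipeline makes is validated as *recovery of planted truth*.

## The synthetic-data generator

### Image mode

`generate_run()` synthesizes a 4D BOLD run on a small grid (default
20×20×12 voxels of 3 mm, 120 volumes, TR 2.382 s — desk-scale, with the
acquisition's TR).  Four disjoint cuboids are placed deterministically:
PRC seed, PHC seed, AT network, PM network; the bottom and top slices act
as CSF and white matter for nuisance structure.

The signal model is a shared-latent-course model.  For a network loading
$\lambda \in [0, 1)$, seed voxels carry a latent series $u_t$ plus small
idiosyncratic noise, and each network voxel is
$a\,u_t + \sqrt{1-a^2}\,\varepsilon_t$ with $a$ solved so that the
*population* correlation between the seed-mean series and the network voxel
equals $\lambda$ exactly (the seed-mean reliability correction
$a = \lambda\sqrt{1 + \sigma_s^2/k}$, with seed noise SD
$\sigma_s = 0.1$ over $k$ seed voxels).  On top of this, configurable
nuisance is added: voxelwise linear drift, a global component, WM/CSF slab
components, and a motion-coupled component driven by a random-walk motion
trace.  Setting `nuisance_scale = 0` gives the pure signal model under
which the loading calibration is exact; the calibration property tests use
that setting, while end-to-end pipeline tests run with nuisance on and rely
on preprocessing to remove it.

Latent courses and noise are white in time.  Since seed and voxel series
pass through the identical bandpass filter, the correlation structure
survives filtering; we do not synthesize autocorrelated (band-limited)
BOLD spectra, which is a known simplification.

### Table mode

`generate_cohort()` emits a long-format per-visit cohort table emulating
the study structure: six groups (cognitively unimpaired young, middle-aged,
older amyloid-negative, older amyloid-positive, MCI, AD-dementia) with
default sizes 85/60/56/8/26/26, baseline ages drawn uniformly from each
group's observed range (e.g. [60, 84.6] for older controls), education,
MMSE and MDRS from the group means/SDs clamped to the observed ranges, one
to three visits spaced ≈18 months apart (SD 4 months), and a small fraction
of younger participants on a variant fMRI sequence.  Amyloid and FDG SUVR
and hippocampal volumes are generated as scalars per visit; 18/26 MCI
patients are converters with onset delays spanning 0–85 months that count
down across visits.

The young-adult SUVR spread (SD 0.095 around 1.10) is calibrated so that
the amyloid-positivity threshold — the 99.9th type-7 percentile of a
45-subject young sample, in effect the sample maximum, about 2.2 SD above
the mean — lands near 1.31.

`plant_effects()` writes deterministic `at_true` / `pm_true` columns as an
exactly linear function of the selected predictors, with default slopes
equal to the package's headline effect sizes (Fisher-z per unit):

| effect | default | unit |
|---|---|---|
| age on AT | +0.0003 | per year |
| age on PM | −0.0007 | per year |
| amyloid on AT | +0.1601 | per SUVR |
| glucose metabolism on AT | −0.1013 | per SUVR |
| hippocampal volume on AT | −0.0694 | per SD of normalized volume |
| MMSE on AT | −0.0047 | per point |
| MDRS on AT | −0.0018 | per point |
| delay to dementia on AT | −0.0136 | per month |

Emitted indexes are `*_true` plus i.i.d. Gaussian noise.  The residual SD
is not identifiable from published group summaries; `noise_sd = 0.05` is a
free default chosen so that single-cohort fits have realistic precision
(e.g. an age-slope SE of ≈1.5×10⁻⁴, matching the order of the reported
confidence intervals).  A per-subject random intercept SD is available and
defaults to 0.

Hippocampal volume enters the planted model on a standardized scale:
normalized volume `raw/(TIV×1000)` is z-scored against fixed normative
constants (mean 4.5×10⁻⁶, SD 6×10⁻⁷) shared by the generator and the
analysis side (`hippo_volume_z()`), so planted and recovered slopes live on
the same scale regardless of the realized sample.

## Numerical and design choices

- **FD convention.** The procedure names FD without a formula; we use the
  common sum-of-absolute-frame-differences convention with rotations
  converted to arc length on a 50 mm sphere (parameterized).
- **Motion exclusion.** "Mean absolute Euler angle" is computed per
  rotation axis (mean over time of |angle|), and the largest axis is
  compared with the 1.5° limit; translations use the maximum over time and
  axes against 3 mm.
- **Filter.** FFT-mask bandpass after voxelwise linear detrend, giving an
  analytic pass/stop contract (in-band power ratio ≥ 0.95, out-of-band
  ≤ 0.05 in tests).  Confound columns are filtered with the identical
  operator before regression so that residualization cannot reintroduce
  out-of-band power.  The source description's per-seed "low-frequency
  drift removal" is subsumed by the detrend step.
- **Ordering.** bandpass → confound extraction from the filtered run →
  regression.  The source does not fix this ordering; this one keeps the
  regression consistent in the frequency domain.
- **Tissue threshold.** WM/CSF means use probability ≥ 0.9 (not stated in
  the source; avoids partial-volume contamination; configurable).
- **Dropout mask combination.** "Combined" is implemented as the
  *intersection* of the two thresholded grey-matter maps, since the mask
  exists to exclude signal loss; union would re-admit dropout voxels.  Both
  behaviors are exposed.
- **AT mask combination.** The AT rule's "combining" is read as
  intersection by symmetry with the PM rule's "overlap"; a union option
  exists behind `combine_at = "union"`.
- **TFCE.** E = 0.5, H = 2, 26-connectivity, 100 integration steps
  (`dh = max/100`) — the conventional defaults of the cited tooling; none
  are stated in the source.  The implementation is a single descending
  union-find sweep (C++), proven equal to a brute-force per-threshold
  connected-component labeller to 1e−8 in the tests.
- **Permutations.** Sign-flip null with the image-wide maximum TFCE
  statistic.  All 2ⁿ sign patterns are enumerated when 2ⁿ ≤ 4096 *and* the
  requested `n_perm` covers them (p-values then are multiples of 1/2ⁿ);
  otherwise `n_perm` random flips with the +1-smoothed estimator
  `(1+k)/(n_perm+1)`, bounding the p floor.  Tests are one-sided (greater)
  throughout mask building.
- **Zero-variance voxels** get t capped via an SD floor (1e−10) so constant
  signals are detected rather than erroring; zero-variance voxels in
  correlation maps get r = 0 with a logged count.
- **Percentile convention.** Linear interpolation between closest ranks
  (R type 7); configurable upstream, logged.
- **Amyloid status without a baseline scan.** Later scans all below
  threshold → negative at baseline (as in the source); any later scan above
  threshold → `undetermined`, since later positivity cannot be dated back.
- **Covariate coding.** Sex as a factor (reference coding for type II,
  sum-to-zero for type III), education in years, age in years.  Pairwise
  post hoc p-values are unadjusted (matching the reporting convention);
  the 10-test association family uses Holm.
- **Mixed-model numerics** are delegated to validated solvers (lme4 /
  lmerTest / mgcv / emmeans); this package owns design construction,
  covariate coding, and the uniform result contract.  Hand-rolled REML is
  deliberately out of scope.

### Group-map smoothing in recovery runs

The default group-inference smoothing is 6.3 mm FWHM, as in the source
pipeline, and index extraction always uses unsmoothed maps.  For
*recovery* benchmarks on synthetic data, however, the pipeline is run with
group smoothing disabled (`group_smooth_fwhm_mm = 0`): the planted networks
are piecewise-constant cuboids with no intrinsic spatial autocorrelation,
and at the synthetic SNR (loading 0.7, 20 subjects) a ~0.9-voxel-σ kernel
makes the one-voxel boundary shell significant, dilating every recovered
mask by construction.  That dilation is a property of the synthetic
geometry, not of the inference machinery, so the recovery criterion is
evaluated without smoothing while the smoothing operator is verified by its
own convolution-oracle and conservation tests.  Recovery is judged on the
masks actually used downstream — group mask within grey matter with seed
voxels removed — against the planted voxel sets, by Dice coefficient.

### edf of ranked-group smooths

For a linear truth over six discrete ranks, the penalized smooth's
effective degrees of freedom concentrate at 1, but single draws show chance
nonlinearity in the per-rank noise means in roughly a fifth of replicates
(the effect is scale-invariant, so shrinking the noise does not remove it).
The linear-limit property is therefore asserted on the median over
replicates.

## Problem sizes used by the validation suite

The suite favors many small problems over few large ones: FWE control uses
200 null datasets of 12 maps on a 16³ grid with 500 permutations each;
mask recovery uses 20 subjects on the default grid at loading 0.7 with 500
permutations; coverage uses 100 replicate cohorts of 200 (age model) and
114 (association model) participants; the converter model is averaged over
50 replicate cohorts of ~18 converters.  These sizes make the whole suite
run in a few minutes while keeping Monte-Carlo error well inside the
asserted tolerances.

## What passing tests do and do not show

The generator reproduces the *structure* of the study — group sizes, age
ranges, visit spacing, biomarker ranges, planted linear effects — but not
real BOLD physics: no spatial autocorrelation of noise, no susceptibility
dropout geometry, no anatomical variability, spherical-cow ROI shapes, and
linear noise-free covariate relationships apart from the planted terms.
Passing recovery tests therefore demonstrates that the *pipeline* is
correct and unbiased under its own assumptions (no circularity, correct
FWE control, calibrated CIs), not that the scientific findings would
replicate in new cohorts.  Known limitations also include: permutation
designs without covariate adjustment, no cluster-extent alternative to
TFCE, and conversion modelled as a linear delay regression rather than a
hazard model.
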