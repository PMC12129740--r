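# mtlnet

Seed-based analysis of the two medial temporal lobe (MTL) networks —
anterior-temporal (AT), hubbed on the perirhinal cortex, and
posterior-medial (PM), hubbed on the parahippocampal cortex — from
resting-state fMRI, with end-to-end validation on synthetic data with
known ground truth.

## Who this is for

Researchers studying MTL network connectivity across aging and the
Alzheimer's continuum who need (a) a reproducible implementation of the
seed-to-mask-to-index pipeline, and (b) a way to verify, on data where the
truth is known, that every stage — permutation inference, extraction,
mixed models — does what it claims.

## What it computes

**Network masks.** Per-subject seed connectivity maps
(r = corr(seed mean, voxel), z = atanh(r)) enter one-sample and paired
sign-flip permutation *t*-tests enhanced with threshold-free cluster
enhancement,

  TFCE(v) = Σ_h e(h, v)^E · h^H · dh    (E = 0.5, H = 2),

with family-wise error control by the permutation distribution of the
image-wide maximum (P_FWE < 0.05).  AT = sig(PRC one-sample) ∩
sig(PRC > PHC); PM = sig(PHC one-sample) ∩ sig(PHC > PRC).

**Connectivity indexes.** Within participant-specific masks (group mask ∧
grey matter ≥ 0.5, seeds removed), the index is the mean of strictly
positive Fisher-z values of the unsmoothed map — a scalar proxy for global
network connectivity per subject and visit.

**Statistics.** Linear mixed models (REML, by-participant random
intercepts, Satterthwaite type II/III F-tests) of the indexes on age,
Alzheimer's stage (ANCOVA + estimated-marginal-mean contrasts,
time-by-group interactions), biomarkers (amyloid and FDG SUVR, normalized
hippocampal volume, MMSE, MDRS; Holm–Bonferroni over the 10-test family)
and months-to-dementia in MCI converters; ranked-group penalized smooths
(k = 6) for continuum trajectories.

**Synthetic data.** `generate_run()` synthesizes 4D BOLD with planted
seed-coupled networks at controlled loadings plus realistic nuisance;
`generate_cohort()` emits cohort tables with planted linear effects
(defaults: age on PM −0.0007/yr, amyloid on AT +0.1601/SUVR, …).  The
generator's ground truth makes mask recovery and coefficient recovery
testable.

## Worked example

Recover a planted age effect from a synthetic 200-subject longitudinal
cohort:

```r
library(mtlnet)

cfg <- cohort_config(group_sizes = c("CU-young" = 85, "CU-middle" = 60,
                                     "CU-oldneg" = 55),
                     pm_terms = "age")          # plant the PM age slope
gen <- generate_cohort(cfg, seed = 1)
fit <- fit_lmm(gen$cohort,
               model_spec("pm_index", c("age_years", "sex",
                                        "education_years",
                                        "sequence_variant")))
fit$coefficients[fit$coefficients$term == "age_years", ]
#>       term  estimate     ci_lo     ci_hi
#>  age_years -0.000642 -0.000945 -0.000339
fit$f_tests[fit$f_tests$term == "age_years", ]
#>       term    F df_num df_den        p
#>  age_years 17.5      1    153 4.73e-05
```

The planted slope (−0.0007 Fisher-z per year) sits inside the recovered
95% CI, and the F-test flags the age effect, as it should at this noise
level and sample size.

The full image pipeline — synthesis, preprocessing, connectivity,
permutation inference, extraction — runs in seconds at desk scale:

```r
icfg <- run_config(mode = "image", seed = 7, n_subjects = 12,
                   loadings = c(at = 0.7, pm = 0.7), n_perm = 500,
                   group_smooth_fwhm_mm = 0, output_dir = tempfile())
out <- run_all(icfg)
c(out$dice_at, out$dice_pm)     # Dice vs planted networks
#> [1] 1 1
head(out$indexes, 3)
#>   subject_id at_index pm_index
#> 1      S0001    0.831    0.873
#> 2      S0002    0.735    0.920
#> 3      S0003    0.776    0.794
```

Dice = 1 means the recovered AT/PM masks coincide exactly with the planted
networks; the positive-voxel indexes are near atanh(0.7) ≈ 0.87, the
planted coupling.

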