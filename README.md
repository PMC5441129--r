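# sfcpipe

Striatal functional connectivity (SFC) analysis for de novo Parkinson's
disease cohorts, as an R package. It is aimed at neuroimaging researchers
who want a tested, permutation-based re-implementation of the classic
multi-stage design — seed-based resting-state connectivity, cluster-extent
inference adjusted for non-stationary smoothness, cluster eigenvariates,
and cross-modal partial-correlation / mediation / Bayesian-network
statistics linking connectivity, DAT-SPECT striatal binding and MDS-UPDRS
symptom scores — together with a synthetic cohort generator that emulates
the statistical structure of PPMI-style data, so the whole pipeline runs
and is testable without any data download.

## What it computes

**Connectivity.** For each subject, the series is cleaned with the
24-parameter motion model (6 rigid-body parameters p, their backward
differences Δp, and p², Δp²), linearly detrended and bandpassed to
0.01–0.08 Hz; the SFC map is the Fisher transform z = atanh(r) of the
Pearson correlation r between each gray-matter voxel and the mean time
course of a 5 mm spherical seed at the striatal DAT-SPECT group-difference
peak.

**Cluster inference.** Voxel-wise OLS of z-maps on UPDRS I, II, III
(jointly or singly; one-sided, negative direction) with age, sex, dominant
side and three medication covariates. Clusters form at voxel p < 0.01;
each cluster's extent is normalized by locally estimated smoothness
(resels per voxel, FWHM = sqrt(4·log 2 / Var(∂u)) per axis from
standardized residuals), and family-wise error is controlled at 5% by a
permutation null of the maximum normalized extent, with exact cluster
p-values p = (1 + #{null ≥ observed}) / (1 + n_perm). A validity check
scores fresh random reassignments of the clinical table against the null
and reports the fraction declared significant (nominally 5%) with a 99%
exact binomial CI.

**Cross-modal statistics.** Partial correlations (residual-based; equal to
(r_xy − r_xz·r_yz)/√((1−r_xz²)(1−r_yz²)) for one control), a
significance-based mediation rule, Steiger's z-test for dependent
overlapping correlations, shared variance r², and three-phase dependency
(TPDA) Bayesian-network structure learning with Gaussian conditional
mutual information −½·log(1 − ρ²) as the dependency test and R² as the
edge magnitude.

All tabular results are tibbles; fitted objects support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

Simulate a study-sized cohort (87 patients, 20³ grid of 3 mm voxels, 150
timepoints at TR 2.4 s, two planted networks coupled to UPDRS II and III at
r = −0.46 and −0.42), run connectivity and cluster inference, and correlate
each significant cluster's eigenvariate with its subscale:

```r
library(sfcpipe)

spec <- cohort_spec(rng_seed = 20150114)          # study-sized defaults
clin <- generate_clinical(spec)
round(cor(clin$updrs_i, clin$updrs_ii), 2)        # 0.45 in this draw
shared_variance(cor(clin$updrs_i, clin$updrs_ii)) # 20 (%)

sfc <- cohort_sfc_maps(spec, clin)                # 87 Fisher-z maps
design <- regression_design(
  cbind(updrs_i = clin$updrs_i, updrs_ii = clin$updrs_ii,
        updrs_iii = clin$updrs_iii),
  clinical_covariates(clin))
fit <- cluster_fwe(sfc$z, design, sfc$mask, voxel_p = 0.01,
                   cluster_alpha = 0.05, n_perm = 499, rng_seed = 1)
fit
#> <cluster_fwe_result> 3 regressor(s), 499 permutations, 232 cluster(s), 2 significant
td <- tidy(fit); td[td$significant, ]
#> # A tibble: 2 × 10
#>   regressor cluster_id n_voxels extent_resels peak_t peak_x peak_y peak_z
#>   <chr>          <int>    <int>         <dbl>  <dbl>  <int>  <int>  <int>
#> 1 updrs_ii          54       22          8.76   3.77     15     13     13
#> 2 updrs_iii         45       25          9.55   4.45     12      2     13

eig <- cluster_eigenvariates(fit, sfc$z, clinical_covariates(clin))
d <- cbind(clin, eig)
partial_correlation(d, "updrs_ii_c54", "updrs_ii",
                    c("age", "on_ldopa", "on_da", "on_other"))
#>   x            y             r           p     n    df band
#>   updrs_ii_c54 updrs_ii -0.514 0.000000662    87    81 significant
partial_correlation(d, "updrs_iii_c45", "updrs_iii",
                    c("age", "on_ldopa", "on_da", "on_other"))
#>   x             y              r          p     n    df band
#>   updrs_iii_c45 updrs_iii -0.482 0.00000406    87    81 significant
```

Both planted networks are detected as significant clusters and their
eigenvariates recover negative partial correlations with the intended
subscales (−0.51 and −0.48 here; the planted population values are −0.46
and −0.42, and the single-cohort estimates carry sampling error of about
±0.1 at n = 87). The end-to-end driver `run_full(run_config(), out_dir)`
chains all stages — simulation, seed selection, connectivity, clusters,
eigenvariates, cross-modal statistics, Bayesian network — and writes every
stage's table plus a `summary.json` recording all thresholds and seeds.

## The methods vignette

`vignettes/sfc-pipeline-methods.Rmd` documents the models and their
assumptions, the permutation substitutions for the parametric corrections,
the synthetic generator's design (what it emulates and what it does not),
all numerical conventions (clamps, tie-breaks, edge handling, CI methods)
and known limitations.
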