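---
title: "Striatal functional connectivity analysis: models, calibration and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Striatal functional connectivity analysis: models, calibration and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sfcpipe)
```

## The analysis

`sfcpipe` implements a multi-stage analysis of the relationship between
striatal dopaminergic loss, striatal functional connectivity (SFC) at rest,
and clinical symptom severity in de novo Parkinson's disease, of the kind
run on PPMI-style cohorts (resting-state fMRI, DAT-SPECT striatal binding
ratios, MDS-UPDRS scores). The stages are:

1. **Seed selection.** A two-group voxel-wise GLM (diagnosis + age + sex) on
   DAT-SPECT maps; the striatal voxel with the maximum patient-vs-control t
   becomes the center of a 5 mm spherical seed.
2. **Connectivity.** Per subject: 24-parameter motion regression (6 motion
   parameters, their backward-difference "accelerations", and both sets
   squared), linear detrend, ideal bandpass to 0.01–0.08 Hz, then the
   Fisher z-transformed Pearson correlation of every gray-matter voxel with
   the mean seed time course.
3. **Cluster inference.** Voxel-wise OLS of the SFC maps on UPDRS I, II and
   III jointly (or each subscale/total separately), one-sided for negative
   associations, controlling age, sex, dominant side and three binary
   medication flags. Clusters form at voxel p < 0.01; cluster-level
   family-wise error is controlled at 5% by a permutation null of the
   maximum smoothness-normalized cluster extent.
4. **Eigenvariates.** Each significant cluster is summarized per subject by
   the first singular component of the covariate-adjusted subjects × voxels
   matrix.
5. **Cross-modal statistics.** Partial correlations between eigenvariates,
   DAT regional values and UPDRS subscales controlling the demographic
   covariates; a significance-based mediation rule; Steiger's z-test for
   dependent overlapping correlations.
6. **Network structure.** Three-phase dependency (TPDA) Bayesian network
   learning over the clinical and imaging variables, with determination
   coefficients (squared Pearson correlations) on the edges.

All tabular results are tibbles; fitted objects support `tidy()`,
`glance()` and `autoplot()`.

## Permutation inference in place of parametric corrections

Classic implementations of this design use parametric corrections
(random-field voxel FWE; a non-stationarity-adjusted parametric cluster
threshold). This package replaces both with permutation max-statistic
procedures — the central methodological substitution:

* **Voxel level** (`voxel_fwe()`): group labels are permuted and the null
  distribution of the maximum t over the mask yields adjusted p-values
  `(1 + #{null max >= t}) / (1 + n_perm)`. Exact under exchangeability, no
  smoothness assumptions.
* **Cluster level** (`cluster_fwe()`): the clinical regressor block is
  permuted jointly across subjects — a random reassignment of clinical data
  to scans that preserves inter-subscale correlations — while covariates
  stay attached to the imaging rows. The null statistic is the maximum
  *resel-normalized* cluster extent.

The non-stationarity adjustment normalizes each cluster's extent by locally
estimated smoothness. `local_smoothness()` estimates, per voxel and axis,
the variance `lambda` of spatial derivatives of the per-voxel-standardized
model residuals; `FWHM_axis = sqrt(4 log 2 / lambda)` (in voxels) and the
resels-per-voxel value is `prod(1 / FWHM_axis)`. A cluster's normalized
extent is the sum of resels per voxel over its members, so extents are
comparable between smooth and rough regions. The estimator is validated in
the tests: on fields smoothed with a known 8 mm kernel the median estimated
FWHM is within 15% of 8 mm, and on unsmoothed iid fields it matches the
discrete-theory value `sqrt(4 log 2 / 2)` voxels. Mask-edge voxels whose
spatial neighbor falls outside the mask receive the in-mask median
roughness; zero-variance voxels are flagged and excluded (they can never be
supra-threshold, since their t is defined as 0).

The smoothness map is re-estimated from each permutation's own residuals.
This matters: reusing the observed-fit smoothness across permutations
breaks exchangeability, because observed clusters lie exactly where
residualizing the observed regressors roughens the field — their
normalized extents are inflated relative to a null normalized by the same
fixed map. In a 500-run null calibration at n = 16 the fixed-map shortcut
roughly doubled the nominal 5% rate, while per-permutation re-estimation
is exact (5.0% measured); the package therefore always re-estimates, and
the calibration suite in the tests pins this behavior down.

**Validity check.** `validity_check()` is a procedure-level audit of the
kind used to defend cluster thresholds against inflated false-positive
rates: it scores fresh random reassignments of the clinical
table against the already-estimated permutation null and reports the
fraction showing at least one significant cluster, with a 99%
Clopper–Pearson interval. Two design points matter. First, the fresh
reassignments are scored against a *fixed* null estimated from separate
permutations — ranking permutations within their own null would make the
answer 5% by construction and test nothing. Second, the rate is defined per
contrast family (one regressor's contrast): with three contrasts each
controlled at 5%, "any contrast significant" would approach 14% even for a
perfectly calibrated procedure, whereas the audited quantity is the
per-family rate, nominally 5%.

## The synthetic cohort generator

The generator (`cohort_spec()`, `generate_clinical()`,
`generate_imaging()`, `cohort_sfc_maps()`) is first-class, tested code: it
defines the study conditions under which every downstream stage is
exercised.

**Clinical scores.** UPDRS I/II/III are drawn from a latent Gaussian copula
with inter-subscale correlations 0.56, 0.33 and 0.46, then mapped
monotonically to integers — `round(mean + sd * z)` clamped into the
target ranges (I: 0–23, II: 1–23, III: 6–47; means 6.9, 6.8, 19.8; SDs
5.1, 4.7, 10.0). The map preserves rank correlations; clamping and rounding
attenuate the Pearson correlation by about 0.01 (0.56 latent ≈ 0.55
observed), well inside the ±0.03 recovery band checked in the tests.
Because only means, SDs and ranges are specified, the marginal *shape* is
a design choice: the copula-with-clamping shape matches those targets in
expectation only. The total is the exact sum of the parts. Age, sex,
dominant side and the three medication flags follow frequencies typical
of a de novo PD cohort.

**Imaging.** Each subject's 4D series is iid Gaussian noise
(`noise_sd = 1`) plus three injections: a band-limited unit-SD seed signal
in the 5 mm seed sphere; the same signal scaled by the subject's coupling
in each planted network template; and a motion artifact (a random linear
mixture of the subject's simulated motion traces added to a random 10% of
voxels, which the 24-parameter regression demonstrably removes — a test
asserts the full chain is invariant to adding nuisance mixtures). The seed
signal is band-limited to 0.01–0.08 Hz so the planted coupling survives the
pipeline's own bandpass, while the white noise loses about two thirds of
its power there — an intended gain in effective SNR.

**Coupling calibration.** The coupling of network *k* is affine in the
*observed* (integer) target subscale plus an orthogonalized noise term:
with `zu` the sample-standardized subscale and `e` a Gaussian draw
residualized against `zu` and re-standardized, the coupling is
`base + sd * (rho * zu + sqrt(1 - rho^2) * e)`. The sample correlation
between coupling and subscale therefore equals the requested `rho`
*exactly*, so end-to-end recovery experiments measure pipeline attenuation
rather than generator sampling noise. Defaults plant two disjoint networks:
one coupled to UPDRS II at r = −0.46 and one to UPDRS III at r = −0.42 —
strong but realistic clinical-imaging coupling magnitudes for a de novo PD
cohort.

The coupling amplitude regime (`coupling_base = 0.25`,
`coupling_sd = 0.075` at unit noise) keeps seed–voxel correlations near
0.4, where the coupling → Fisher-z map is close to linear; a strong-coupling
regime would compress the planted effect nonlinearly and bias recovery.

**DAT-SPECT.** Regional striatal binding ratios for four regions
(ipsi/contralateral putamen and caudate) with a patient-vs-control
reduction of `dat_effect` (default 1.0 SBR units) at the seed-containing
ipsilateral putamen, scaled-down reductions elsewhere, and — by default —
zero correlation with the connectivity couplings (`dat_sfc_corr = 0`), the
independence the cross-modal analyses probe. 3D SBR maps paint the regional
values into boxes around the seed (mirrored contralaterally) for the
seed-selection GLM.

**Default problem sizes.** 20×20×20 voxels at 3 mm, 150 timepoints at TR
2.4 s, 87 subjects. These are the package's desk-scale study conditions:
large enough that cluster geometry, smoothness estimation and permutation
nulls behave as on full-size data, small enough that full permutation
suites run on a laptop. The calibration experiments in the tests use 60
subjects with a 499-permutation null and 500 scored reassignments
(validity), 1000 subjects with 99–199 permutations (effect recovery), and
500 reduced-grid null runs (p-value uniformity).

**What the generator does not emulate** — and hence what passing tests do
not show about real data: spatial autocorrelation of physiological noise
(noise is white before smoothing), scanner drift and multi-site effects,
anatomical structure (templates are cuboids; no gray/white geometry),
on/off-medication visit structure, and any nonlinear coupling between
symptoms and connectivity. Calibration results transfer to real data only
insofar as exchangeability under permutation holds there.

## Numerical and convention choices

* **Processing order** is fixed: smoothing (optional) → motion regression →
  detrend → bandpass → correlation. Published pipeline descriptions often
  leave this order open; here it is documented and deterministic. A flag (`smooth_fwhm_mm`)
  controls whether series are smoothed before connectivity; the default
  pipeline smooths at 8 mm, synthetic-grid experiments skip it.
* **Acceleration** in the 24-parameter model is the backward temporal
  difference with a leading zero.
* **Fisher z clamp**: voxel correlations are clamped to `|r| <= 1 - 1e-12`
  before `atanh` (z ≈ 13.9), keeping maps finite; zero-variance voxels get
  z = 0 with a logged count. The scalar `fisher_z()` rejects `|r| >= 1`
  instead.
* **Bandpass** is an ideal rectangular DFT filter retaining bins with
  `low <= f <= high`, DC removed. Edge bins are decided by the bin's exact
  frequency.
* **Smoothing edges** are replicate-nearest, so constants are preserved;
  0-based voxel indexing throughout, distances between voxel centers in mm.
* **Seed membership**: center-to-center Euclidean distance `<= radius`;
  a 5 mm sphere on a 3 mm grid has 19 voxels.
* **Cluster connectivity** defaults to 18 (face + edge), the common SPM
  convention; 6 and 26 are available.
* **Tie-breaks**: seed-peak ties resolve to the lexicographically smallest
  (x, y, z); cluster labels follow column-major scan order; TPDA pair order
  is mutual-information rank with lexicographic name tie-break, making the
  learned skeleton independent of column order.
* **Significance rule**: permutation p-values are `(1 + b) / (1 + B)` and
  significance is `p <= alpha`, which makes the nominal level exact on the
  achievable grid.
* **Eigenvariate sign** is fixed by positive correlation with the cluster's
  mean adjusted signal; "adjusted" means covariates are residualized out of
  every voxel (intercept always included) *before* the decomposition, with
  a flag to skip adjustment. Single-voxel clusters return the adjusted
  voxel values.
* **Confidence intervals** for the validity proportion are Clopper–Pearson
  (exact binomial) at 99%; the method is named in the output so the
  interval is reproducible.
* **Missing data**: listwise deletion with subject ids logged, matching
  designs where different analyses retain different subject subsets (e.g.
  fewer subjects have both imaging modalities). Partial correlations accept
  any control set, so both
  "control one DAT region" and "control all four" variants of the
  cross-modal analyses are expressible; neither is asserted as canonical.
* **Holm correction** across the partial-correlation family is available
  but off by default (uncorrected reporting is conventional for these
  exploratory families); p in [0.05, 0.10) is labelled "marginal".

## TPDA for continuous data

The three-phase learner is instantiated for linear-Gaussian data: the
dependency oracle is the Gaussian conditional mutual information
`-0.5 log(1 - rho^2)` with `rho` the partial correlation, tested via the
Fisher z statistic at `alpha = 0.05` (an alpha-based threshold replaces the
absolute CMI epsilon of the original discrete formulation, whose
discretization strategy is not specified). Drafting ranks marginally
dependent pairs by mutual information and adds an edge when no adjacency
path yet explains the dependence; thickening adds deferred pairs unless a
cut set drawn from path-adjacent neighbors separates them; thinning
re-examines edges on cycles. At the variable counts involved (≤ ~12) the
cut-set search is exhaustive over the bounded candidate sets rather than
greedy — cheaper than it sounds and free of the greedy search's
order sensitivity. Orientation is by collider detection against recorded
separating sets plus Meek-style propagation; anything unresolved is
reported bidirected, and conflicting collider orientations are also
reported bidirected rather than silently overwritten.

Known limitation (inherent to conditional-independence learning, not this
implementation): a "shielded collider" a → b with a → c ← b and
reinforcing coefficients makes the partial correlation of the direct edge
given the collider vanish almost exactly — the distribution is
near-unfaithful and the edge unrecoverable by any CI test. The skeleton
precision/recall properties are therefore evaluated on triangle-free DAGs
with positive coefficients ≥ 0.5, the regime in which the algorithm's
monotone-faithfulness assumption holds.

## Known limitations

* No spatial normalization, segmentation or resampling: all volumes must
  share one grid (out of scope by design; synthetic data are generated in a
  common grid).
* The ideal DFT bandpass assumes the series length; it is not a causal
  filter and wraps circularly, which is standard for resting-state
  connectivity but unsuitable for event-locked analyses.
* Permutation inference assumes exchangeability of subjects under the
  null; heteroscedastic subgroups would need restricted permutation
  schemes not implemented here.
* The mediation rule is purely significance-based; it is not an effect
  decomposition and inherits the usual caveats of significance-thresholded
  reasoning.
* Anatomical labelling of clusters is out of scope; clusters are reported
  by geometry and statistics only.
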