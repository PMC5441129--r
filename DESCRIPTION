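Package: sfcpipe
Title: Seed-Based Striatal Functional Connectivity Analysis with
    Permutation Cluster Inference and Cross-Modal Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a multi-stage striatal functional
    connectivity (SFC) analysis for de novo Parkinson's disease cohorts:
    seed-based resting-state connectivity mapping (24-parameter motion
    regression, linear detrend, 0.01-0.08 Hz bandpass, Fisher-z seed
    correlation maps), two-group voxel-wise GLMs with permutation max-T
    family-wise error correction and striatal seed-peak selection, voxel-wise
    multiple regression of SFC maps on UPDRS subscales with cluster-extent
    inference adjusted for non-stationary smoothness via a permutation null of
    resel-normalized cluster extent, cluster eigenvariate extraction,
    partial-correlation mediation analysis, Steiger's z-test for dependent
    overlapping correlations, and three-phase dependency (TPDA) Bayesian
    network structure learning.  A synthetic-cohort generator emulates the
    statistical structure of PPMI-style inputs (UPDRS subscale correlations,
    planted connectivity networks coupled to symptom severity, DAT-SPECT
    striatal binding ratios) so every stage is exercisable without any data
    download.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
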