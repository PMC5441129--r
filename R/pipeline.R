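#' Run configuration for the end-to-end pipeline
#'
#' Collects everything [run_full()] needs: the synthetic-cohort
#' specification, the inference thresholds, permutation count and analysis
#' mode.  `run_config()` builds one from arguments (or a YAML file via
#' `yaml_path`) with full defaulting; every effective value is written into
#' the run summary so defaulted decisions stay auditable.
#'
#' @param cohort a [cohort_spec()] (default: the standard study-sized spec).
#' @param voxel_p cluster-forming voxel p (default 0.01).
#' @param cluster_alpha cluster FWE level (default 0.05).
#' @param fwe_alpha voxel FWE level for the DAT seed search (default 0.05).
#' @param n_perm permutations for cluster inference (>= 100 for reported
#'   runs).
#' @param mode `"joint"` (UPDRS I, II, III in one model) or `"single"`
#'   (separate models per subscale and total).
#' @param rng_seed master seed of the run.
#' @param yaml_path optional YAML file; its entries override the defaults
#'   (top-level keys as above, `cohort:` holding [cohort_spec()] arguments).
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(), voxel_p = 0.01,
                       cluster_alpha = 0.05, fwe_alpha = 0.05,
                       n_perm = 1000L, mode = c("joint", "single"),
                       rng_seed = 1L, yaml_path = NULL) {
  if (!is.null(yaml_path)) {
    cfg <- yaml::read_yaml(yaml_path)
    if (!is.null(cfg$cohort)) cohort <- do.call(cohort_spec, cfg$cohort)
    for (nm in c("voxel_p", "cluster_alpha", "fwe_alpha", "n_perm", "mode", "rng_seed")) {
      if (!is.null(cfg[[nm]])) assign(nm, cfg[[nm]])
    }
  }
  mode <- match.arg(mode)
  for (v in list(voxel_p = voxel_p, cluster_alpha = cluster_alpha, fwe_alpha = fwe_alpha)) {
    if (v <= 0 || v >= 1) stop("thresholds must lie in (0, 1)", call. = FALSE)
  }
  if (n_perm < 100L) stop("n_perm must be >= 100 for reported runs", call. = FALSE)
  structure(list(cohort = cohort, voxel_p = voxel_p,
                 cluster_alpha = cluster_alpha, fwe_alpha = fwe_alpha,
                 n_perm = as.integer(n_perm), mode = mode,
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

write_tsv_ <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis end to end
#'
#' Runs the complete analysis flow on a synthetic cohort: simulate ->
#' (optional) DAT-based seed selection -> per-subject SFC maps -> voxel-wise
#' regression with permutation cluster inference -> eigenvariates ->
#' cross-modal partial correlations, mediation and Steiger comparisons ->
#' Bayesian network.  Every stage writes its outputs into `out_dir` as it
#' completes (TSV tables, a machine-readable `summary.json` recording every
#' threshold and seed), so a failing stage aborts with its name while
#' partial outputs persist.  The run is deterministic given the config's
#' `rng_seed`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a list with the main stage results (`clinical`,
#'   `seed`, `clusters`, `eigenvariates`, `crossmodal`, `mediation`,
#'   `steiger`, `bn`, `summary`).
#' @export
run_full <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- config$cohort
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  clinical <- stage("simulate", {
    cl <- generate_clinical(spec)
    write_tsv_(cl, file.path(out_dir, "clinical.tsv"))
    cl
  })

  dat <- stage("simulate", {
    couplings <- planted_couplings(spec, clinical)
    regions <- generate_dat_regions(spec, spec$n_subjects, "pd", couplings)
    tb <- tibble::tibble(subject_id = clinical$subject_id,
                         tibble::as_tibble(regions))
    write_tsv_(tb, file.path(out_dir, "dat_regions.tsv"))
    tb
  })

  seed <- stage("seed", {
    if (spec$n_controls > 0L) {
      cohort <- generate_cohort(spec)
      striatal <- Reduce(`|`, dat_region_masks(spec))
      sm <- fit_group_glm(cohort$dat_maps, cohort$dat_regions$group,
                          mask = array(TRUE, spec$grid_dims))
      select_seed_peak(sm, striatal)
    } else spec$seed
  })

  sfc <- stage("connectivity", cohort_sfc_maps(spec, clinical, seed = seed))

  design <- stage("clusters", {
    interest <- switch(config$mode,
      joint = cbind(updrs_i = clinical$updrs_i, updrs_ii = clinical$updrs_ii,
                    updrs_iii = clinical$updrs_iii),
      single = cbind(updrs_total = clinical$updrs_total))
    regression_design(interest, clinical_covariates(clinical),
                      subject_id = clinical$subject_id)
  })

  fit <- stage("clusters", {
    f <- cluster_fwe(sfc$z, design, sfc$mask, voxel_p = config$voxel_p,
                     cluster_alpha = config$cluster_alpha,
                     n_perm = config$n_perm, rng_seed = config$rng_seed)
    write_tsv_(dplyr::select(f$clusters, -"voxels"),
               file.path(out_dir, "clusters.tsv"))
    # significant-cluster label volume (row number in clusters.tsv)
    labels <- array(0, spec$grid_dims)
    sig <- which(f$clusters$significant)
    for (i in seq_along(sig)) labels[f$clusters$voxels[[sig[i]]]] <- sig[i]
    write_volume(vol_map(labels, spec$voxel_size_mm),
                 file.path(out_dir, "cluster_labels.nii.gz"))
    f
  })

  eig <- stage("eigen", {
    e <- cluster_eigenvariates(fit, sfc$z, clinical_covariates(clinical))
    write_tsv_(tibble::tibble(subject_id = clinical$subject_id, e),
               file.path(out_dir, "eigenvariates.tsv"))
    e
  })

  merged <- dplyr::bind_cols(clinical, dat[, -1L, drop = FALSE], eig)
  covars <- c("age", "on_ldopa", "on_da", "on_other")
  merged$sex_male <- as.numeric(merged$sex == "male")
  covars <- c(covars, "sex_male")

  cross <- stage("crossmodal", {
    imaging_vars <- c(names(eig), names(dat)[-1L])
    prs <- expand.grid(y = imaging_vars,
                       x = c("updrs_i", "updrs_ii", "updrs_iii"),
                       stringsAsFactors = FALSE)[, c("x", "y")]
    tb <- crossmodal_correlations(merged, prs, covars)
    write_tsv_(tb, file.path(out_dir, "crossmodal.tsv"))
    tb
  })

  med <- stage("crossmodal", {
    if (ncol(eig) > 0L) {
      tb <- dplyr::bind_rows(lapply(names(dat)[-1L], function(reg)
        dplyr::bind_rows(lapply(c("updrs_ii", "updrs_iii"), function(u)
          mediation_test(merged, u, reg, mediator = names(eig)[1L],
                         covariates = covars)))))
      write_tsv_(tb, file.path(out_dir, "mediation.tsv"))
      tb
    } else tibble::tibble()
  })

  stg <- stage("crossmodal", {
    if (ncol(eig) > 0L) {
      tb <- dplyr::bind_rows(lapply(c("updrs_i", "updrs_ii", "updrs_iii"), function(u) {
        r1 <- stats::cor(merged[[u]], merged[[names(eig)[1L]]])
        r2 <- stats::cor(merged[[u]], merged$ipsi_putamen)
        r12 <- stats::cor(merged[[names(eig)[1L]]], merged$ipsi_putamen)
        dplyr::mutate(steiger_z(r1, r2, r12, nrow(merged)), subscale = u)
      }))
      write_tsv_(tb, file.path(out_dir, "steiger.tsv"))
      tb
    } else tibble::tibble()
  })

  bn <- stage("bn", {
    bn_vars <- c("updrs_i", "updrs_ii", "updrs_iii", names(dat)[-1L], names(eig))
    g <- tpda_learn(merged[, bn_vars, drop = FALSE])
    write_bn_graph(g, dot_path = file.path(out_dir, "bn_graph.dot"),
                   tsv_path = file.path(out_dir, "bn_edges.tsv"))
    g
  })

  summary <- list(
    thresholds = list(voxel_p = config$voxel_p,
                      cluster_alpha = config$cluster_alpha,
                      fwe_alpha = config$fwe_alpha),
    n_perm = config$n_perm, mode = config$mode, rng_seed = config$rng_seed,
    cohort = list(n_subjects = spec$n_subjects, n_controls = spec$n_controls,
                  grid_dims = spec$grid_dims, voxel_size_mm = spec$voxel_size_mm,
                  n_timepoints = spec$n_timepoints, tr_seconds = spec$tr_seconds,
                  seed_center = seed$center_voxel, seed_radius_mm = seed$radius_mm,
                  coupling_effects = spec$coupling_effects,
                  coupling_targets = spec$coupling_targets,
                  noise_sd = spec$noise_sd, rng_seed = spec$rng_seed),
    n_clusters = nrow(fit$clusters),
    n_significant_clusters = sum(fit$clusters$significant))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(clinical = clinical, dat_regions = dat, seed = seed,
                 sfc = sfc, fit = fit, clusters = fit$clusters,
                 eigenvariates = eig, crossmodal = cross, mediation = med,
                 steiger = stg, bn = bn, summary = summary))
}
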