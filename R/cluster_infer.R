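#' Regression design for voxel-wise SFC analysis
#'
#' Pairs the regressors of interest (UPDRS subscales, jointly or singly) with
#' the covariates of no interest (age, sex, dominant side, three binary
#' medication flags).  Subjects with missing values are dropped listwise with
#' a message naming them.
#'
#' @param interest numeric matrix or data frame of regressors of interest
#'   (named columns).
#' @param covariates optional numeric matrix/data frame of covariates.
#' @param subject_id optional ids used in listwise-deletion messages.
#' @return An object of class `regression_design` with elements `interest`,
#'   `covariates`, `complete` (logical keep-vector over the original rows).
#' @export
regression_design <- function(interest, covariates = NULL, subject_id = NULL) {
  interest <- as.matrix(interest)
  if (is.null(colnames(interest)))
    colnames(interest) <- paste0("regressor_", seq_len(ncol(interest)))
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  n <- nrow(interest)
  complete <- stats::complete.cases(interest) &
    (if (is.null(covariates)) TRUE else stats::complete.cases(covariates))
  if (!all(complete)) {
    ids <- if (is.null(subject_id)) which(!complete) else subject_id[!complete]
    message("dropping ", sum(!complete), " subject(s) with missing values: ",
            paste(ids, collapse = ", "))
  }
  interest <- interest[complete, , drop = FALSE]
  if (!is.null(covariates)) {
    covariates <- covariates[complete, , drop = FALSE]
    # prune covariates collinear with [intercept | interest | earlier covariates]
    # once, so the design matrix is full rank by construction
    base <- cbind(1, interest)
    keep <- logical(ncol(covariates))
    for (j in seq_len(ncol(covariates))) {
      cand <- cbind(base, covariates[, keep, drop = FALSE],
                    covariates[, j, drop = FALSE])
      keep[j] <- qr(cand)$rank == ncol(cand)
    }
    if (!all(keep)) {
      message("pruning collinear covariate column(s): ",
              paste(colnames(covariates)[!keep], collapse = ", "))
      covariates <- covariates[, keep, drop = FALSE]
    }
    if (ncol(covariates) == 0L) covariates <- NULL
  }
  structure(list(interest = interest, covariates = covariates,
                 complete = complete),
            class = "regression_design")
}

design_matrix <- function(design) {
  cbind(intercept = 1, design$interest, design$covariates)
}

#' Voxel-wise multiple regression of SFC maps on clinical regressors
#'
#' Fits, at every in-mask voxel, an OLS model of the Fisher-z SFC values on
#' all regressors of interest jointly plus the covariates, and returns one t
#' map per regressor for the negative direction (the analysis tests for
#' negative associations between SFC and symptom severity, so positive
#' values of the returned t statistic mean a stronger negative association).
#'
#' @param z subjects x voxels matrix of Fisher-z SFC values (e.g. from
#'   [cohort_sfc_maps()]), already restricted to in-mask voxels.
#' @param design a [regression_design()].
#' @return A list: `t` (regressors x voxels matrix of negative-direction t),
#'   `dof`, `resid` (subjects x voxels residual matrix), `regressors`.
#' @export
fit_voxelwise_regression <- function(z, design) {
  stopifnot(inherits(design, "regression_design"))
  z <- as.matrix(z)[design$complete, , drop = FALSE]
  X <- design_matrix(design)
  k <- ncol(design$interest)
  if (nrow(z) <= ncol(X) + 2L) stop("need n > p + 2 subjects", call. = FALSE)
  fit <- voxelwise_ols(z, X, which_cols = 1L + seq_len(k))
  list(t = -fit$t, dof = fit$dof, resid = fit$resid,
       regressors = colnames(design$interest))
}

## -- connected components ----------------------------------------------------

conn_offsets <- function(connectivity = 18L) {
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nn <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = nn == 1L,
                 "18" = nn >= 1L & nn <= 2L,
                 "26" = nn >= 1L)
  off[keep, , drop = FALSE]
}

# Label the TRUE voxels of a logical 3D array into connected components.
# Returns an integer array (0 = background); labels are assigned in
# column-major scan order, so labeling is deterministic.
label_components <- function(supra, connectivity = 18L) {
  d <- dim(supra)
  labels <- array(0L, d)
  idx <- which(supra)
  if (length(idx) == 0L) return(labels)
  off <- conn_offsets(connectivity)
  coords <- arrayInd(idx, d)
  in_set <- array(FALSE, d); in_set[idx] <- TRUE
  cur <- 0L
  for (s in seq_along(idx)) {
    if (labels[idx[s]] != 0L) next
    cur <- cur + 1L
    queue <- matrix(coords[s, ], 1L)
    labels[idx[s]] <- cur
    while (nrow(queue) > 0L) {
      v <- queue[nrow(queue), ]
      queue <- queue[-nrow(queue), , drop = FALSE]
      nb <- sweep(off, 2L, v, `+`)
      ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
            nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
            nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
      nb <- nb[ok, , drop = FALSE]
      if (nrow(nb) == 0L) next
      lin <- nb[, 1L] + d[1L] * (nb[, 2L] - 1L) + d[1L] * d[2L] * (nb[, 3L] - 1L)
      new <- lin[in_set[lin] & labels[lin] == 0L]
      if (length(new) > 0L) {
        labels[new] <- cur
        queue <- rbind(queue, arrayInd(new, d))
      }
    }
  }
  labels
}

#' Form supra-threshold clusters from a t map
#'
#' Applies the one-sided cluster-forming threshold (`t > qt(1 - voxel_p,
#' dof)`) and labels the surviving voxels into connected components
#' (18-connectivity by default, the SPM convention; 6 and 26 available).
#' An empty supra-threshold set yields an empty table, not an error.
#'
#' @param tmap 3D t array (negative-direction t from
#'   [fit_voxelwise_regression()], or any t map).
#' @param dof degrees of freedom used to convert `voxel_p` to a t threshold.
#' @param voxel_p one-sided cluster-forming voxel p (default 0.01).
#' @param connectivity 6, 18 or 26.
#' @param mask optional logical 3D restriction.
#' @param rpv optional resels-per-voxel array from [local_smoothness()]; when
#'   supplied, each cluster also gets its smoothness-normalized (resel)
#'   extent.
#' @return A tibble with one row per cluster: `cluster_id`, `n_voxels`,
#'   `extent_resels` (NA without `rpv`), `peak_t`, `peak_x/y/z` (0-based) and
#'   a `voxels` list-column of linear indices.
#' @export
form_clusters <- function(tmap, dof, voxel_p = 0.01, connectivity = 18L,
                          mask = NULL, rpv = NULL) {
  stopifnot(is.array(tmap), length(dim(tmap)) == 3L)
  if (voxel_p <= 0 || voxel_p >= 1) stop("voxel_p must lie in (0, 1)", call. = FALSE)
  thr <- stats::qt(1 - voxel_p, dof)
  supra <- tmap > thr
  if (!is.null(mask)) supra <- supra & mask
  labels <- label_components(supra, connectivity)
  cluster_table(labels, tmap, rpv)
}

cluster_table <- function(labels, tmap, rpv = NULL) {
  ncl <- max(labels)
  if (ncl == 0L) {
    return(tibble::tibble(cluster_id = integer(), n_voxels = integer(),
                          extent_resels = numeric(), peak_t = numeric(),
                          peak_x = integer(), peak_y = integer(),
                          peak_z = integer(), voxels = list()))
  }
  d <- dim(labels)
  rows <- lapply(seq_len(ncl), function(id) {
    vox <- which(labels == id)
    peak <- vox[which.max(tmap[vox])]
    pc <- arrayInd(peak, d)[1L, ] - 1L
    tibble::tibble(cluster_id = id, n_voxels = length(vox),
                   extent_resels = if (is.null(rpv)) NA_real_ else sum(rpv[vox]),
                   peak_t = tmap[peak],
                   peak_x = pc[1L], peak_y = pc[2L], peak_z = pc[3L],
                   voxels = list(vox))
  })
  dplyr::bind_rows(rows)
}

#' Local smoothness (resels per voxel) from standardized residuals
#'
#' Estimates per-voxel smoothness of the residual field from the variance of
#' spatial derivatives of the per-voxel-standardized residual images: along
#' each axis `FWHM = sqrt(4 log 2 / var(derivative))` (in voxels), and the
#' resels-per-voxel value is the product over axes of `1 / FWHM_axis`.
#' Cluster extent normalized by this map (the sum of resels per voxel over
#' the cluster) is comparable across regions of differing smoothness, which
#' is the non-stationarity adjustment used by [cluster_fwe()].
#'
#' @param resid subjects x voxels residual matrix (>= 10 residual maps).
#' @param mask logical 3D array whose `TRUE` entries correspond to the
#'   columns of `resid`.
#' @return A list: `rpv` (3D resels-per-voxel array, NA outside the mask),
#'   `fwhm_voxels` (3D array, geometric-mean FWHM per voxel in voxels),
#'   `flagged` (indices of zero-variance voxels, excluded and set NA).
#' @export
local_smoothness <- function(resid, mask) {
  resid <- as.matrix(resid)
  if (nrow(resid) < 10L) stop("need at least 10 residual maps", call. = FALSE)
  d <- dim(mask)
  if (any(d < 2L)) stop("grid too thin for smoothness estimation", call. = FALSE)
  vox <- which(as.vector(mask))
  stopifnot(length(vox) == ncol(resid))
  ss <- sqrt(colSums(resid^2))
  flagged <- vox[ss == 0]
  U <- t(resid) / ifelse(ss == 0, 1, ss)        # voxels x n, unit-norm rows
  nv <- prod(d)
  Ufull <- matrix(NA_real_, nv, ncol(U))
  Ufull[vox, ] <- U
  lin <- array(seq_len(nv), d)
  lambda <- vector("list", 3L)
  for (a in 1:3) {
    idx_hi <- pmin(seq_len(d[a]) + 1L, d[a])    # forward diff, backward at top edge
    idx_lo <- idx_hi - 1L
    hi <- as.vector(switch(a, lin[idx_hi, , ], lin[, idx_hi, ], lin[, , idx_hi]))
    lo <- as.vector(switch(a, lin[idx_lo, , ], lin[, idx_lo, ], lin[, , idx_lo]))
    la <- rowSums((Ufull[hi, , drop = FALSE] - Ufull[lo, , drop = FALSE])^2)
    # mask-edge voxels whose neighbor lies outside: use the in-mask median
    la_in <- la[vox]
    med <- stats::median(la_in, na.rm = TRUE)
    la_in[!is.finite(la_in)] <- med
    la_full <- rep(NA_real_, nv)
    la_full[vox] <- la_in
    lambda[[a]] <- la_full
  }
  fourlog2 <- 4 * log(2)
  fwhm_ax <- lapply(lambda, function(l) sqrt(fourlog2 / pmax(l, 1e-12)))
  rpv <- array(1 / (fwhm_ax[[1L]] * fwhm_ax[[2L]] * fwhm_ax[[3L]]), d)
  fwhm_gm <- array((fwhm_ax[[1L]] * fwhm_ax[[2L]] * fwhm_ax[[3L]])^(1 / 3), d)
  if (length(flagged) > 0L) { rpv[flagged] <- NA_real_; fwhm_gm[flagged] <- NA_real_ }
  list(rpv = rpv, fwhm_voxels = fwhm_gm, flagged = flagged)
}

#' Cluster-extent family-wise error correction by permutation, adjusted for
#' non-stationary smoothness
#'
#' The observed model is fit voxel-wise; clusters are formed per regressor at
#' the one-sided `voxel_p` threshold and their extents are normalized by the
#' local smoothness (resels-per-voxel) of the model residuals.  The rows of
#' the regressor-of-interest block are then permuted jointly `n_perm` times
#' (covariates stay attached to the imaging rows, matching a random
#' reassignment of the clinical data to scans that preserves the
#' inter-subscale correlations), and the maximum normalized cluster extent
#' per permutation — each normalized by that permutation's own residual
#' smoothness, keeping observed and permuted statistics exchangeable —
#' forms the null distribution.  A cluster is
#' significant when its corrected p-value, `(1 + #\{null max >= observed
#' extent\}) / (1 + n_perm)`, is at most `cluster_alpha`.  This permutation
#' null of resel-normalized extent replaces the parametric non-stationary
#' cluster correction with the same adjustment target and no stationarity or
#' distributional assumptions.
#'
#' @inheritParams fit_voxelwise_regression
#' @param grid_dims integer triple; with `mask`, defines the voxel grid.
#' @param mask logical 3D analysis mask whose `TRUE` entries correspond to
#'   the columns of `z`.
#' @param voxel_p one-sided cluster-forming threshold (default 0.01).
#' @param cluster_alpha cluster-level FWE level (default 0.05).
#' @param n_perm number of permutations (>= 20; >= 200 recommended).
#' @param connectivity cluster connectivity (6/18/26, default 18).
#' @param rng_seed seed for the permutation stream.
#' @return An object of class `cluster_fwe_result`: `clusters` (tibble with
#'   `regressor`, cluster geometry, `extent_resels`, `p_corrected`,
#'   `significant`), `null_max` (n_perm x regressors matrix), `dof`,
#'   `t_threshold`, `smoothness` (from [local_smoothness()]), plus the
#'   inputs needed to score fresh reassignments ([validity_check()]).
#' @export
cluster_fwe <- function(z, design, mask, voxel_p = 0.01, cluster_alpha = 0.05,
                        n_perm = 1000L, connectivity = 18L, rng_seed = 1L) {
  if (n_perm < 20L) stop("n_perm < 20 gives too coarse a p-value resolution", call. = FALSE)
  if (cluster_alpha <= 0 || cluster_alpha >= 1) stop("cluster_alpha must lie in (0,1)", call. = FALSE)
  d <- dim(mask)
  fit <- fit_voxelwise_regression(z, design)
  sm <- local_smoothness(fit$resid, mask)
  thr <- stats::qt(1 - voxel_p, fit$dof)
  k <- length(fit$regressors)
  vox <- which(as.vector(mask))

  clusters_of <- function(tvec, rpv) {
    tarr <- array(-Inf, d); tarr[vox] <- tvec
    supra <- array(FALSE, d); supra[vox] <- tvec > thr
    labels <- label_components(supra, connectivity)
    cluster_table(labels, tarr, rpv)
  }
  max_extent_of <- function(tvec, rpv) {
    tb <- clusters_of(tvec, rpv)
    if (nrow(tb) == 0L) 0 else max(tb$extent_resels, na.rm = TRUE)
  }

  obs <- lapply(seq_len(k), function(j) clusters_of(fit$t[j, ], sm$rpv))

  # Each permutation's cluster extents are normalized by the smoothness of
  # that permutation's own residuals.  Reusing the observed-fit smoothness
  # breaks exchangeability: observed clusters lie exactly where residualizing
  # the observed regressors roughens the field, inflating their normalized
  # extents relative to the null's (empirically ~2x the nominal rate at
  # n = 16).  Re-estimating per permutation makes the statistic the same
  # function of (data, assignment) throughout, restoring exactness.
  zc <- as.matrix(z)[design$complete, , drop = FALSE]
  Xcov <- design$covariates
  n <- nrow(zc)
  set.seed(rng_seed)
  null_max <- matrix(0, n_perm, k)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    dperm <- structure(list(interest = design$interest[perm, , drop = FALSE],
                            covariates = Xcov, complete = rep(TRUE, n)),
                       class = "regression_design")
    fb <- fit_voxelwise_regression(zc, dperm)
    rpv_b <- local_smoothness(fb$resid, mask)$rpv
    for (j in seq_len(k)) null_max[b, j] <- max_extent_of(fb$t[j, ], rpv_b)
  }
  colnames(null_max) <- fit$regressors

  clusters <- dplyr::bind_rows(lapply(seq_len(k), function(j) {
    tb <- obs[[j]]
    if (nrow(tb) == 0L) return(tibble::tibble())
    tb$regressor <- fit$regressors[j]
    tb$p_corrected <- vapply(tb$extent_resels, function(e)
      (1 + sum(null_max[, j] >= e)) / (1 + n_perm), numeric(1))
    tb$significant <- tb$p_corrected <= cluster_alpha
    tb
  }))
  if (nrow(clusters) > 0L) {
    clusters <- dplyr::relocate(clusters, "regressor")
  }
  structure(list(clusters = clusters, null_max = null_max, dof = fit$dof,
                 t_threshold = thr, smoothness = sm, mask = mask,
                 voxel_p = voxel_p, cluster_alpha = cluster_alpha,
                 connectivity = connectivity, regressors = fit$regressors,
                 n_perm = n_perm),
            class = "cluster_fwe_result")
}

#' @export
print.cluster_fwe_result <- function(x, ...) {
  cat(sprintf("<cluster_fwe_result> %d regressor(s), %d permutations, %d cluster(s), %d significant\n",
              length(x$regressors), x$n_perm, nrow(x$clusters),
              sum(x$clusters$significant)))
  invisible(x)
}

#' Permutation validity check of the cluster-inference procedure
#'
#' Scores `n_check` fresh random reassignments of the clinical table to the
#' SFC maps against the null distribution already estimated by
#' [cluster_fwe()], and reports, for one designated regressor's contrast,
#' the proportion showing at least one significant cluster together with a
#' 99% Clopper-Pearson (exact binomial) confidence interval.  Under a valid
#' procedure the proportion matches the nominal cluster alpha.
#'
#' @param fit a `cluster_fwe_result`.
#' @param z,design the same SFC matrix and design passed to [cluster_fwe()].
#' @param n_check number of fresh reassignments (>= 100).
#' @param regressor name (or index) of the contrast checked (default first).
#' @param conf_level confidence level of the binomial CI (default 0.99).
#' @param rng_seed seed for the fresh reassignment stream.
#' @return A one-row tibble: `n_checked`, `n_positive`, `proportion`,
#'   `ci_low`, `ci_high`, `conf_level`, `ci_method`.
#' @export
validity_check <- function(fit, z, design, n_check = 1000L, regressor = 1L,
                           conf_level = 0.99, rng_seed = 2L) {
  stopifnot(inherits(fit, "cluster_fwe_result"))
  if (n_check < 100L) stop("n_check must be >= 100", call. = FALSE)
  j <- if (is.character(regressor)) match(regressor, fit$regressors) else regressor
  stopifnot(!is.na(j), j >= 1L, j <= length(fit$regressors))
  d <- dim(fit$mask)
  vox <- which(as.vector(fit$mask))
  zc <- as.matrix(z)[design$complete, , drop = FALSE]
  n <- nrow(zc)
  null_j <- fit$null_max[, j]
  set.seed(rng_seed)
  hits <- 0L
  for (b in seq_len(n_check)) {
    perm <- sample.int(n)
    dperm <- structure(list(interest = design$interest[perm, , drop = FALSE],
                            covariates = design$covariates,
                            complete = rep(TRUE, n)),
                       class = "regression_design")
    fb <- fit_voxelwise_regression(zc, dperm)
    rpv_b <- local_smoothness(fb$resid, fit$mask)$rpv  # per-reassignment, as in cluster_fwe
    tarr <- array(-Inf, d); tarr[vox] <- fb$t[j, ]
    supra <- array(FALSE, d); supra[vox] <- fb$t[j, ] > fit$t_threshold
    labels <- label_components(supra, fit$connectivity)
    tb <- cluster_table(labels, tarr, rpv_b)
    if (nrow(tb) > 0L) {
      # same decision rule as cluster_fwe, scored against the stored null
      p <- (1 + sum(null_j >= max(tb$extent_resels, na.rm = TRUE))) / (1 + fit$n_perm)
      if (p <= fit$cluster_alpha) hits <- hits + 1L
    }
  }
  binom_proportion(hits, n_check, conf_level)
}

#' Proportion with exact binomial confidence interval
#'
#' @param x number of positives.
#' @param n number of trials (>= 100 in pipeline use).
#' @param conf_level confidence level (default 0.99).
#' @return A one-row tibble (see [validity_check()]).
#' @export
binom_proportion <- function(x, n, conf_level = 0.99) {
  ci <- stats::binom.test(x, n, conf.level = conf_level)$conf.int
  tibble::tibble(n_checked = n, n_positive = x, proportion = x / n,
                 ci_low = ci[1L], ci_high = ci[2L],
                 conf_level = conf_level, ci_method = "clopper-pearson")
}
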