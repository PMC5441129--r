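#' Voxel-wise statistical map
#'
#' Container for a voxel-wise t map: the 3D t array, its degrees of freedom
#' and the analysis mask.
#'
#' @param t 3D numeric array of t statistics (0 outside the mask).
#' @param dof residual degrees of freedom.
#' @param mask logical 3D array.
#' @param voxel_size_mm voxel edge length in mm.
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(t, dof, mask, voxel_size_mm) {
  stopifnot(is.array(t), length(dim(t)) == 3L, all(dim(t) == dim(mask)))
  if (!all(is.finite(t[mask]))) stop("non-finite t values inside the mask", call. = FALSE)
  structure(list(t = t, dof = dof, mask = mask, voxel_size_mm = voxel_size_mm),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s, dof %d, %d in-mask voxels, max t %.3g\n",
              paste(dim(x$t), collapse = "x"), x$dof, sum(x$mask),
              max(x$t[x$mask])))
  invisible(x)
}

# Assemble the two-group design: intercept, PD indicator, covariates.
group_design_matrix <- function(diagnosis, covariates) {
  diagnosis <- as.character(diagnosis)
  stopifnot(all(diagnosis %in% c("pd", "hc")))
  if (length(unique(diagnosis)) < 2L) stop("both groups must be non-empty", call. = FALSE)
  X <- cbind(intercept = 1, pd = as.numeric(diagnosis == "pd"))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (anyNA(covariates)) stop("covariates must be complete", call. = FALSE)
    X <- cbind(X, covariates)
  }
  X
}

#' Two-group voxel-wise general linear model
#'
#' Per-voxel OLS with diagnosis as a factor and optional covariates
#' (conventionally age and sex for DAT-SPECT comparisons, plus total
#' intracranial volume for structural comparisons).  The returned t
#' map is for the control-minus-PD contrast, i.e. positive t means reduced
#' signal in patients.
#'
#' @param maps list of [vol_map()], one per subject.
#' @param diagnosis character vector, `"pd"` or `"hc"` per subject.
#' @param covariates optional numeric matrix/data frame of covariates.
#' @param mask optional logical analysis mask (default: all voxels).
#' @return A [stat_map()] (dof = n - p).
#' @export
fit_group_glm <- function(maps, diagnosis, covariates = NULL, mask = NULL) {
  stopifnot(length(maps) == length(diagnosis))
  if (min(table(diagnosis)) < 2L) stop("need at least 2 subjects per group", call. = FALSE)
  d <- dim(maps[[1L]])
  if (is.null(mask)) mask <- array(TRUE, d)
  Y <- maps_matrix(maps, mask)
  X <- group_design_matrix(diagnosis, covariates)
  fit <- voxelwise_ols(Y, X, which_cols = 2L)
  tarr <- array(0, d)
  tarr[as.vector(mask)] <- -fit$t[1L, ]   # hc - pd
  stat_map(tarr, fit$dof, mask, voxel_size(maps[[1L]]))
}

#' Voxel-level family-wise error correction by permutation max-T
#'
#' Permutes the diagnosis labels, records the maximum t over the mask in each
#' permutation, and assigns each voxel the adjusted p-value
#' `(1 + #\{null max >= observed t\}) / (1 + n_perm)`.  This distribution-free
#' max-statistic procedure stands in for the parametric random-field
#' voxel-FWE correction; it is exact under exchangeability of the group
#' labels.  Voxels are declared significant at adjusted p <= `alpha`.
#'
#' @inheritParams fit_group_glm
#' @param alpha family-wise error level in (0, 1).
#' @param n_perm number of label permutations (>= 100).
#' @param rng_seed seed for the permutation stream.
#' @return A list: `significant` (logical 3D array), `p_adjusted` (3D array,
#'   1 outside the mask), `statmap`, `null_max` (length `n_perm`).
#' @export
voxel_fwe <- function(maps, diagnosis, covariates = NULL, alpha = 0.05,
                      n_perm = 1000L, mask = NULL, rng_seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  d <- dim(maps[[1L]])
  if (is.null(mask)) mask <- array(TRUE, d)
  Y <- maps_matrix(maps, mask)
  X <- group_design_matrix(diagnosis, covariates)
  obs <- voxelwise_ols(Y, X, which_cols = 2L)
  tobs <- -obs$t[1L, ]
  set.seed(rng_seed)
  null_max <- vapply(seq_len(n_perm), function(b) {
    Xp <- X
    Xp[, 2L] <- X[sample.int(nrow(X)), 2L]
    max(-voxelwise_ols(Y, Xp, which_cols = 2L, warn_rank = FALSE)$t[1L, ])
  }, numeric(1))
  p_adj <- vapply(tobs, function(t0) (1 + sum(null_max >= t0)) / (1 + n_perm),
                  numeric(1))
  parr <- array(1, d); parr[as.vector(mask)] <- p_adj
  sig <- array(FALSE, d); sig[as.vector(mask)] <- p_adj <= alpha
  tarr <- array(0, d); tarr[as.vector(mask)] <- tobs
  list(significant = sig, p_adjusted = parr,
       statmap = stat_map(tarr, obs$dof, mask, voxel_size(maps[[1L]])),
       null_max = null_max)
}

#' Select the striatal seed peak
#'
#' Returns the voxel with the maximum t statistic inside the striatal mask
#' (the seed convention: the striatal voxel with the largest DAT-SPECT
#' reduction relative to healthy controls), as a 5 mm [seed_spec()].  Ties are
#' broken by lexicographic voxel order (x, then y, then z; 0-based).
#'
#' @param statmap a [stat_map()].
#' @param striatal_mask logical 3D array restricting the search.
#' @param radius_mm seed sphere radius (default 5 mm).
#' @return A [seed_spec()] centered at the peak voxel.
#' @export
select_seed_peak <- function(statmap, striatal_mask, radius_mm = 5) {
  stopifnot(inherits(statmap, "stat_map"), all(dim(striatal_mask) == dim(statmap$t)))
  if (!any(striatal_mask)) stop("striatal mask is empty", call. = FALSE)
  tvals <- statmap$t
  tvals[!striatal_mask] <- -Inf
  if (all(!is.finite(tvals))) stop("no finite t values inside the striatal mask", call. = FALSE)
  mx <- max(tvals)
  cands <- arrayInd(which(tvals == mx), dim(tvals)) - 1L
  cands <- cands[order(cands[, 1L], cands[, 2L], cands[, 3L]), , drop = FALSE]
  seed_spec(cands[1L, ], radius_mm = radius_mm)
}
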