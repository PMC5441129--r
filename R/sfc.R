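#' Fisher z-transform
#'
#' `atanh(r)`, the variance-stabilizing transform applied to Pearson
#' correlations throughout the pipeline.  At this scalar level `|r| >= 1` is
#' an error; voxel-wise maps clamp instead (see [sfc_map()]).
#'
#' @param r correlation value(s) with `|r| < 1`.
#' @return `atanh(r)`.
#' @examples
#' fisher_z(0.5)  # 0.5493
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1 for the Fisher z-transform", call. = FALSE)
  atanh(r)
}

# clamp used at the map level so z stays finite (z cap ~ 13.9)
R_CLAMP <- 1 - 1e-12

#' Seed-based Fisher-z connectivity map
#'
#' The seed time course is the unweighted mean of the (already preprocessed)
#' series over the resolved seed voxels; each in-mask voxel gets the Fisher
#' z-transformed Pearson correlation of its time series with the seed time
#' course.  Correlations with `|r| >= 1 - 1e-12` are clamped before `atanh`
#' so maps stay finite; zero-variance voxels get z = 0 (their count is
#' reported as an attribute).
#'
#' @param series a preprocessed [vol_series()] (motion-regressed, detrended,
#'   bandpassed; see [preprocess_series()]).
#' @param seed a [seed_spec()].
#' @param mask logical 3D analysis mask (default: all voxels).
#' @return A `vol_map` of Fisher-z values (0 outside the mask), with
#'   attributes `seed` and `n_zero_variance`.
#' @export
sfc_map <- function(series, seed, mask = NULL) {
  stopifnot(inherits(series, "vol_series"), inherits(seed, "seed_spec"))
  d <- dim(series)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  stopifnot(all(dim(mask) == d[1:3]))
  seed_mask <- resolve_seed(seed, d[1:3], voxel_size(series))
  if (!any(seed_mask & mask)) {
    stop("seed sphere lies entirely outside the analysis mask", call. = FALSE)
  }
  y <- matrix(unclass(series), prod(d[1:3]), d[4L])   # V x T
  seed_tc <- colMeans(y[as.vector(seed_mask & mask), , drop = FALSE])
  vox <- which(as.vector(mask))
  yv <- y[vox, , drop = FALSE]
  yv <- yv - rowMeans(yv)
  s0 <- seed_tc - mean(seed_tc)
  denom_seed <- sqrt(sum(s0^2))
  sds <- sqrt(rowSums(yv^2))
  r <- as.vector(yv %*% s0) / (sds * denom_seed)
  zero_var <- sds == 0 | denom_seed == 0
  r[zero_var] <- 0
  r <- pmin(pmax(r, -R_CLAMP), R_CLAMP)
  z <- atanh(r)
  z[zero_var] <- 0
  out <- array(0, d[1:3])
  out[vox] <- z
  out <- vol_map(out, voxel_size_mm = voxel_size(series))
  attr(out, "seed") <- seed
  attr(out, "n_zero_variance") <- sum(zero_var)
  out
}
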