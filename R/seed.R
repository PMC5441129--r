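#' Spherical seed specification
#'
#' A seed is a sphere of radius `radius_mm` around the center of the voxel at
#' `center_voxel` (0-based index triple).  Membership is decided by the
#' Euclidean distance between voxel centers in mm: a voxel belongs to the seed
#' iff that distance is `<= radius_mm`, so the center voxel is always
#' included.  The study's seed was a 5 mm sphere around the striatal peak
#' voxel of the DAT-SPECT group difference.
#'
#' @param center_voxel integer triple, 0-based voxel index of the sphere center.
#' @param radius_mm positive radius in mm (default 5).
#' @return An object of class `seed_spec`.
#' @examples
#' seed_spec(c(10, 10, 10))
#' @export
seed_spec <- function(center_voxel, radius_mm = 5) {
  stopifnot(length(center_voxel) == 3L, all(center_voxel == round(center_voxel)),
            all(center_voxel >= 0))
  stopifnot(is.numeric(radius_mm), length(radius_mm) == 1L)
  if (radius_mm <= 0) stop("radius_mm must be > 0", call. = FALSE)
  structure(list(center_voxel = as.integer(center_voxel),
                 radius_mm = as.numeric(radius_mm)),
            class = "seed_spec")
}

#' @export
print.seed_spec <- function(x, ...) {
  cat(sprintf("<seed_spec> center voxel (%s), radius %.3g mm\n",
              paste(x$center_voxel, collapse = ", "), x$radius_mm))
  invisible(x)
}

#' Resolve a seed sphere to a voxel mask
#'
#' @param seed a [seed_spec()].
#' @param grid_dims integer triple, voxels per axis.
#' @param voxel_size_mm voxel edge length in mm.
#' @return Logical 3D array marking seed membership.
#' @examples
#' sum(resolve_seed(seed_spec(c(5, 5, 5), 5), c(11, 11, 11), 3))  # 19 voxels
#' @export
resolve_seed <- function(seed, grid_dims, voxel_size_mm) {
  stopifnot(inherits(seed, "seed_spec"), length(grid_dims) == 3L)
  ctr <- seed$center_voxel
  if (any(ctr < 0L) || any(ctr > grid_dims - 1L)) {
    stop("seed center (", paste(ctr, collapse = ", "),
         ") lies outside the grid", call. = FALSE)
  }
  half <- floor(seed$radius_mm / voxel_size_mm)
  mask <- array(FALSE, grid_dims)
  for (dx in -half:half) for (dy in -half:half) for (dz in -half:half) {
    if (sqrt(dx^2 + dy^2 + dz^2) * voxel_size_mm <= seed$radius_mm) {
      v <- ctr + c(dx, dy, dz)
      if (all(v >= 0L) && all(v <= grid_dims - 1L)) {
        mask[v[1L] + 1L, v[2L] + 1L, v[3L] + 1L] <- TRUE
      }
    }
  }
  mask
}
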