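#' Volume containers
#'
#' `vol_map()` wraps a 3D array of voxel values and `vol_series()` a 4D array
#' indexed (x, y, z, t), together with the voxel geometry needed by the rest
#' of the pipeline.  The grid is regular and isotropic; voxel positions are
#' taken at voxel centers and all voxel indices in the package are 0-based.
#'
#' @param data numeric array; 3D for `vol_map`, 4D for `vol_series`.
#' @param voxel_size_mm positive scalar, edge length of a voxel in mm.
#' @param tr_seconds positive scalar, repetition time of the series in seconds.
#' @return An object of class `vol_map` or `vol_series` (a classed array with
#'   `voxel_size_mm` and, for series, `tr_seconds` attributes).
#' @examples
#' m <- vol_map(array(rnorm(27), c(3, 3, 3)), voxel_size_mm = 3)
#' dim(m)
#' @export
vol_map <- function(data, voxel_size_mm) {
  data <- as_finite_array(data, ndim = 3)
  stopifnot(is.numeric(voxel_size_mm), length(voxel_size_mm) == 1L, voxel_size_mm > 0)
  structure(data, voxel_size_mm = as.numeric(voxel_size_mm), class = c("vol_map", "array"))
}

#' @rdname vol_map
#' @export
vol_series <- function(data, voxel_size_mm, tr_seconds) {
  data <- as_finite_array(data, ndim = 4)
  stopifnot(is.numeric(voxel_size_mm), length(voxel_size_mm) == 1L, voxel_size_mm > 0)
  stopifnot(is.numeric(tr_seconds), length(tr_seconds) == 1L, tr_seconds > 0)
  structure(data,
            voxel_size_mm = as.numeric(voxel_size_mm),
            tr_seconds = as.numeric(tr_seconds),
            class = c("vol_series", "array"))
}

as_finite_array <- function(data, ndim) {
  if (!is.array(data) || length(dim(data)) != ndim) {
    stop("expected a ", ndim, "D array, got ",
         if (is.array(data)) paste0(length(dim(data)), "D") else class(data)[1L],
         call. = FALSE)
  }
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1", call. = FALSE)
  if (!all(is.finite(data))) stop("non-finite voxel values are not allowed", call. = FALSE)
  storage.mode(data) <- "double"
  data
}

#' @export
print.vol_map <- function(x, ...) {
  cat(sprintf("<vol_map> %s voxels, %.3g mm isotropic\n",
              paste(dim(x), collapse = " x "), voxel_size(x)))
  invisible(x)
}

#' @export
print.vol_series <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<vol_series> %s voxels x %d timepoints, %.3g mm, TR %.3g s\n",
              paste(d[1:3], collapse = " x "), d[4L], voxel_size(x), tr(x)))
  invisible(x)
}

#' Voxel geometry accessors
#' @param x a `vol_map` or `vol_series`.
#' @return `voxel_size()` the voxel edge length in mm; `tr()` the repetition
#'   time in seconds.
#' @export
voxel_size <- function(x) attr(x, "voxel_size_mm")

#' @rdname voxel_size
#' @export
tr <- function(x) attr(x, "tr_seconds")

#' Read and write NIfTI-1 volumes
#'
#' 3D files become `vol_map`, 4D files `vol_series`.  Round-trip
#' write-then-read preserves the data bit-exactly (float64 on disk).
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return `read_volume()` a `vol_map` or `vol_series`; `write_volume()` the
#'   path, invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (!(length(d) %in% c(3L, 4L))) {
    stop("'", path, "': expected a 3D or 4D NIfTI volume, got ",
         length(d), " dimensions", call. = FALSE)
  }
  arr <- array(as.numeric(img), dim = d)
  if (!all(is.finite(arr))) {
    stop("'", path, "': contains non-finite voxel values", call. = FALSE)
  }
  pd <- RNifti::pixdim(img)
  vs <- pd[1L]
  if (length(d) == 3L) {
    vol_map(arr, voxel_size_mm = vs)
  } else {
    trs <- if (length(pd) >= 4L && pd[4L] > 0) pd[4L] else 1
    vol_series(arr, voxel_size_mm = vs, tr_seconds = trs)
  }
}

#' @rdname read_volume
#' @param x a `vol_map` or `vol_series`.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "vol_map") || inherits(x, "vol_series"))
  nd <- length(dim(x))
  pixdim <- rep(voxel_size(x), 3L)
  if (nd == 4L) pixdim <- c(pixdim, tr(x))
  arr <- unclass(x)
  attributes(arr) <- list(dim = dim(x), pixdim = pixdim)
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

## -- Gaussian smoothing ------------------------------------------------------

# 1D convolution along one axis of a 3D array with replicate-nearest edges.
conv_axis <- function(arr, kernel, axis) {
  half <- (length(kernel) - 1L) / 2L
  n <- dim(arr)[axis]
  out <- array(0, dim(arr))
  for (k in seq_along(kernel)) {
    off <- k - 1L - half
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)   # replicate edges
    shifted <- switch(axis,
                      arr[idx, , , drop = FALSE],
                      arr[, idx, , drop = FALSE],
                      arr[, , idx, drop = FALSE])
    out <- out + kernel[k] * shifted
  }
  out
}

gaussian_kernel_1d <- function(sigma_vox) {
  half <- max(1L, ceiling(4 * sigma_vox))
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

#' Gaussian spatial smoothing
#'
#' Separable Gaussian smoothing with `sigma = fwhm / (2 sqrt(2 log 2))` per
#' axis, specified in mm and converted to voxels through the volume's voxel
#' size.  Series are smoothed per timepoint.  Edges use replicate-nearest
#' padding, so a constant image stays constant.  `fwhm_mm = 0` is the
#' identity.
#'
#' @param x a `vol_map` or `vol_series`.
#' @param fwhm_mm non-negative full-width at half maximum in mm.
#' @return An object of the same class as `x`.
#' @export
gaussian_smooth <- function(x, fwhm_mm) {
  stopifnot(is.numeric(fwhm_mm), length(fwhm_mm) == 1L)
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0", call. = FALSE)
  if (fwhm_mm == 0) return(x)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size(x)
  kernel <- gaussian_kernel_1d(sigma_vox)
  smooth3d <- function(a) {
    for (axis in 1:3) a <- conv_axis(a, kernel, axis)
    a
  }
  if (inherits(x, "vol_map")) {
    vol_map(smooth3d(unclass(x)), voxel_size_mm = voxel_size(x))
  } else {
    d <- dim(x)
    out <- unclass(x)
    for (t in seq_len(d[4L])) {
      out[, , , t] <- smooth3d(array(out[, , , t], d[1:3]))
    }
    vol_series(out, voxel_size_mm = voxel_size(x), tr_seconds = tr(x))
  }
}

#' Gray-matter mask from a probability map
#'
#' Thresholds a tissue-probability map with a strict inequality: a voxel is in
#' the mask iff its probability is strictly greater than `threshold`.
#'
#' @param map a `vol_map` with values in \[0, 1\].
#' @param threshold scalar in \[0, 1); default 0.2.
#' @return A logical 3D array of the same shape.
#' @export
make_gm_mask <- function(map, threshold = 0.2) {
  stopifnot(inherits(map, "vol_map"))
  if (any(map < 0) || any(map > 1)) {
    stop("probability map values must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold < 1)
  array(unclass(map) > threshold, dim = dim(map))
}
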