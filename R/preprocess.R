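#' Build the 24-parameter nuisance design from motion traces
#'
#' Expands a T x 6 motion-parameter matrix (3 translations, 3 rotations) into
#' the 24-parameter confound model: the 6 motion parameters, their 6
#' "acceleration" parameters (backward temporal difference with a leading 0),
#' and the squares of both, in the column order
#' `[motion | accel | motion^2 | accel^2]`.
#'
#' @param motion numeric T x 6 matrix of motion parameters.
#' @return A T x 24 numeric matrix of class `nuisance_design`.
#' @examples
#' m <- matrix(rnorm(60), 10, 6)
#' dim(build_nuisance_matrix(m))
#' @export
build_nuisance_matrix <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) {
    stop("motion must have exactly 6 columns, got ", ncol(motion), call. = FALSE)
  }
  if (nrow(motion) < 3L) stop("need at least 3 timepoints", call. = FALSE)
  accel <- rbind(0, diff(motion))
  out <- cbind(motion, accel, motion^2, accel^2)
  colnames(out) <- c(paste0("mot", 1:6), paste0("acc", 1:6),
                     paste0("mot_sq", 1:6), paste0("acc_sq", 1:6))
  class(out) <- c("nuisance_design", class(out))
  out
}

# OLS residualization of the columns of y (T x V) on design (T x p),
# intercept always included.  Rank-deficient columns are dropped with a
# warning.  Returns residuals.
residualize <- function(y, design = NULL) {
  y <- as.matrix(y)
  X <- cbind(`(intercept)` = rep(1, nrow(y)), design)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning(sprintf("design is rank deficient; dropping %d dependent column(s)",
                    ncol(X) - qrX$rank), call. = FALSE)
    qrX <- qr(X[, sort(keep), drop = FALSE])
  }
  y - qr.fitted(qrX, y)
}

#' Regress nuisance signals out of a series
#'
#' Per-voxel ordinary-least-squares residualization of the time series on the
#' nuisance design, with an intercept always included.  The output time
#' series are orthogonal to every design column.
#'
#' @param series a [vol_series()].
#' @param design T x p nuisance matrix (e.g. from [build_nuisance_matrix()]).
#' @return A `vol_series` of residuals.
#' @export
regress_out <- function(series, design) {
  stopifnot(inherits(series, "vol_series"))
  design <- as.matrix(design)
  d <- dim(series)
  if (nrow(design) != d[4L]) {
    stop("design has ", nrow(design), " rows but the series has ",
         d[4L], " timepoints", call. = FALSE)
  }
  y <- t(matrix(unclass(series), prod(d[1:3]), d[4L]))  # T x V
  res <- residualize(y, design)
  vol_series(array(t(res), d), voxel_size_mm = voxel_size(series),
             tr_seconds = tr(series))
}

#' Linear detrending
#'
#' Removes the per-voxel least-squares line (intercept + slope in time).
#'
#' @param series a [vol_series()].
#' @return A detrended `vol_series`.
#' @export
detrend_linear <- function(series) {
  stopifnot(inherits(series, "vol_series"))
  regress_out(series, matrix(seq_len(dim(series)[4L]), ncol = 1L))
}

#' Ideal bandpass filter
#'
#' Frequency-domain rectangular filter: Fourier bins with frequency `f`
#' satisfying `low_hz <= f <= high_hz` are retained, everything else
#' (including the DC component) is zeroed.  Defaults are the resting-state
#' band 0.01-0.08 Hz.
#'
#' @param series a [vol_series()] (its `tr()` sets the sampling rate).
#' @param low_hz,high_hz passband edges in Hz; `high_hz` must exceed `low_hz`
#'   and be below the Nyquist frequency `1 / (2 TR)`.
#' @return A filtered `vol_series`.
#' @export
bandpass <- function(series, low_hz = 0.01, high_hz = 0.08) {
  stopifnot(inherits(series, "vol_series"))
  if (high_hz <= low_hz) stop("high_hz must be greater than low_hz", call. = FALSE)
  nyquist <- 1 / (2 * tr(series))
  if (high_hz >= nyquist) {
    stop(sprintf("high_hz (%.4g Hz) must be below the Nyquist frequency (%.4g Hz)",
                 high_hz, nyquist), call. = FALSE)
  }
  d <- dim(series)
  nt <- d[4L]
  y <- t(matrix(unclass(series), prod(d[1:3]), nt))     # T x V
  freqs <- bin_freqs(nt, tr(series))
  keep <- freqs >= low_hz & freqs <= high_hz & freqs > 0
  Y <- stats::mvfft(y)
  Y[!keep, ] <- 0
  res <- Re(stats::mvfft(Y, inverse = TRUE)) / nt
  vol_series(array(t(res), d), voxel_size_mm = voxel_size(series),
             tr_seconds = tr(series))
}

# Absolute frequency (Hz) of each DFT bin of a length-n series sampled at TR.
bin_freqs <- function(n, tr_seconds) {
  k <- seq_len(n) - 1L
  k[k > n / 2] <- k[k > n / 2] - n
  abs(k) / (n * tr_seconds)
}

#' Standard preprocessing chain for connectivity analysis
#'
#' Applies, in this fixed order: optional spatial smoothing, 24-parameter
#' motion regression, linear detrending, and bandpass filtering.  The order
#' (nuisance regression before filtering) is fixed for reproducibility.
#'
#' @param series a [vol_series()].
#' @param motion T x 6 motion-parameter matrix, or `NULL` to skip.
#' @param smooth_fwhm_mm spatial smoothing FWHM in mm (0 = none).
#' @param low_hz,high_hz passband in Hz.
#' @return A preprocessed `vol_series`.
#' @export
preprocess_series <- function(series, motion = NULL, smooth_fwhm_mm = 0,
                              low_hz = 0.01, high_hz = 0.08) {
  if (smooth_fwhm_mm > 0) series <- gaussian_smooth(series, smooth_fwhm_mm)
  if (!is.null(motion)) series <- regress_out(series, build_nuisance_matrix(motion))
  series <- detrend_linear(series)
  bandpass(series, low_hz = low_hz, high_hz = high_hz)
}

#' Motion quality-control flag
#'
#' Flags subjects whose maximum absolute translation exceeds one voxel
#' size, a common exclusion rule in resting-state quality control.
#'
#' @param motion T x 6 motion matrix (first three columns translations in mm).
#' @param voxel_size_mm voxel size in mm.
#' @return `TRUE` if motion is within one voxel, else `FALSE`.
#' @export
motion_within_limit <- function(motion, voxel_size_mm) {
  motion <- as.matrix(motion)
  max(abs(motion[, 1:3])) <= voxel_size_mm
}
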