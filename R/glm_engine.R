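# Shared voxel-wise OLS machinery.
#
# Y is subjects x voxels, X subjects x p (intercept included by the caller).
# Rank-deficient designs keep the earliest independent columns and drop the
# rest with a warning, so "diagnosis collinear with a covariate" has defined
# behavior (the later column goes).

keep_independent_cols <- function(X, warn = TRUE) {
  qrX <- qr(X)
  if (qrX$rank == ncol(X)) return(seq_len(ncol(X)))
  keep <- integer(0)
  for (j in seq_len(ncol(X))) {
    cand <- c(keep, j)
    if (qr(X[, cand, drop = FALSE])$rank == length(cand)) keep <- cand
  }
  if (warn) {
    dropped <- setdiff(seq_len(ncol(X)), keep)
    nms <- colnames(X)[dropped]
    warning("design is rank deficient; dropping column(s): ",
            paste(if (is.null(nms)) dropped else nms, collapse = ", "),
            call. = FALSE)
  }
  keep
}

# t statistics for the given coefficient columns (indices into X's columns).
# Returns list(t = length(which_cols) x V matrix, dof, resid = n x V).
voxelwise_ols <- function(Y, X, which_cols, warn_rank = TRUE) {
  n <- nrow(Y)
  stopifnot(nrow(X) == n)
  keep <- keep_independent_cols(X, warn = warn_rank)
  if (!all(which_cols %in% keep)) {
    stop("a regressor of interest is collinear with earlier design columns",
         call. = FALSE)
  }
  Xk <- X[, keep, drop = FALSE]
  p <- ncol(Xk)
  dof <- n - p
  if (dof < 1L) stop("not enough subjects for the design (dof < 1)", call. = FALSE)
  XtXinv <- chol2inv(chol(crossprod(Xk)))
  B <- XtXinv %*% crossprod(Xk, Y)            # p x V
  resid <- Y - Xk %*% B
  s2 <- colSums(resid^2) / dof                # V
  rows <- match(which_cols, keep)
  tmat <- matrix(0, length(rows), ncol(Y))
  for (i in seq_along(rows)) {
    se <- sqrt(pmax(XtXinv[rows[i], rows[i]] * s2, .Machine$double.xmin))
    tmat[i, ] <- B[rows[i], ] / se
  }
  tmat[, s2 == 0] <- 0
  list(t = tmat, dof = dof, resid = resid)
}

# Convert a list of vol_map to a subjects x in-mask-voxels matrix.
maps_matrix <- function(maps, mask) {
  vox <- which(as.vector(mask))
  Y <- matrix(0, length(maps), length(vox))
  for (i in seq_along(maps)) Y[i, ] <- as.vector(unclass(maps[[i]]))[vox]
  Y
}
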