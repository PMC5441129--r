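#' Cluster eigenvariate, adjusted for covariates of no interest
#'
#' Summarizes a cluster by one number per subject: the subject-side first
#' singular vector of the subjects x voxels matrix of (Fisher-z) SFC values
#' within the cluster, after the covariates have been residualized out of
#' every voxel (intercept always included).  The underlying voxel weight
#' vector has unit norm; the sign is fixed so the scores correlate positively
#' with the cluster's mean adjusted signal.  A single-voxel cluster returns
#' its adjusted voxel values directly (degenerate but well defined).
#'
#' @param z subjects x voxels matrix of in-mask Fisher-z values.
#' @param voxels integer vector of column indices forming the cluster (e.g.
#'   a `voxels` entry of a cluster table mapped into mask-column space, see
#'   [cluster_eigenvariates()]).
#' @param covariates optional numeric matrix of covariates of no interest;
#'   `NULL` skips adjustment.
#' @return A numeric vector of per-subject scores with attributes `weights`
#'   (unit-norm voxel loadings) and `sign_fixed`.
#' @export
extract_eigenvariate <- function(z, voxels, covariates = NULL) {
  z <- as.matrix(z)
  if (length(voxels) == 0L) stop("cluster is empty", call. = FALSE)
  M <- z[, voxels, drop = FALSE]
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == nrow(M))
    M <- residualize(M, covariates)
  } else {
    M <- residualize(M, NULL)   # remove per-voxel mean for a scale-free score
  }
  if (ncol(M) == 1L) {
    scores <- as.numeric(M)
    attr(scores, "weights") <- 1
    attr(scores, "sign_fixed") <- FALSE
    return(scores)
  }
  sv <- svd(M, nu = 1L, nv = 1L)
  scores <- as.numeric(sv$u[, 1L] * sv$d[1L])
  weights <- as.numeric(sv$v[, 1L])
  flip <- stats::cor(scores, rowMeans(M))
  if (is.finite(flip) && flip < 0) { scores <- -scores; weights <- -weights }
  attr(scores, "weights") <- weights
  attr(scores, "sign_fixed") <- TRUE
  scores
}

#' Eigenvariates for every significant cluster of a fitted model
#'
#' Convenience wrapper: runs [extract_eigenvariate()] for each (by default
#' significant) cluster of a [cluster_fwe()] result and returns them as a
#' tibble column per cluster, named `<regressor>_c<cluster_id>`.
#'
#' @param fit a `cluster_fwe_result`.
#' @param z the subjects x voxels matrix the model was fit on.
#' @param covariates covariates of no interest to adjust for.
#' @param only_significant keep only significant clusters (default TRUE).
#' @return A tibble of per-subject eigenvariate scores (subjects in rows).
#' @export
cluster_eigenvariates <- function(fit, z, covariates = NULL,
                                  only_significant = TRUE) {
  stopifnot(inherits(fit, "cluster_fwe_result"))
  tb <- fit$clusters
  if (only_significant) tb <- tb[tb$significant, , drop = FALSE]
  if (nrow(tb) == 0L) return(tibble::tibble(.rows = nrow(as.matrix(z))))
  vox_lookup <- match(seq_len(prod(dim(fit$mask))), which(as.vector(fit$mask)))
  out <- lapply(seq_len(nrow(tb)), function(i) {
    cols <- vox_lookup[tb$voxels[[i]]]
    as.numeric(extract_eigenvariate(z, cols[!is.na(cols)], covariates))
  })
  names(out) <- paste0(tb$regressor, "_c", tb$cluster_id)
  tibble::as_tibble(out)
}

#' Leave-one-out prediction r-squared
#'
#' Utility for quantifying how much symptom variance a cluster summary
#' explains out of sample: each subject's score is predicted from a linear
#' model (predictors vs outcome) fit on all other subjects, and the squared
#' correlation between predicted and observed outcomes is returned.
#'
#' @param outcome numeric vector (e.g. a UPDRS subscale).
#' @param predictors numeric vector or matrix (e.g. an eigenvariate).
#' @return Squared Pearson correlation of LOO predictions with the outcome.
#' @export
loo_r2 <- function(outcome, predictors) {
  X <- cbind(1, as.matrix(predictors))
  n <- length(outcome)
  stopifnot(nrow(X) == n, n > ncol(X) + 1L)
  pred <- vapply(seq_len(n), function(i) {
    b <- stats::lm.fit(X[-i, , drop = FALSE], outcome[-i])$coefficients
    b[is.na(b)] <- 0
    sum(X[i, ] * b)
  }, numeric(1))
  stats::cor(pred, outcome)^2
}
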