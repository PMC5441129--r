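# Shared fixtures: everything is generated in code at test time.

tiny_spec <- function(n_subjects = 12, grid = c(12L, 12L, 12L), rng_seed = 42L, ...) {
  cohort_spec(n_subjects = n_subjects, grid_dims = grid,
              seed_center = c(3L, 3L, 3L), rng_seed = rng_seed, ...)
}

random_series <- function(dims = c(4, 4, 4), nt = 20, voxel = 3, tr = 2,
                          seed = 1) {
  set.seed(seed)
  vol_series(array(rnorm(prod(dims) * nt), c(dims, nt)),
             voxel_size_mm = voxel, tr_seconds = tr)
}

# series holding one sinusoid at frequency f_hz in every voxel
sinusoid_series <- function(f_hz, nt = 200, tr = 2, dims = c(2, 2, 2)) {
  tc <- sin(2 * pi * f_hz * (0:(nt - 1)) * tr)
  vol_series(array(rep(tc, each = prod(dims)), c(dims, nt)),
             voxel_size_mm = 3, tr_seconds = tr)
}

rms <- function(x) sqrt(mean(unclass(x)^2))

residualize_fixture <- function(M) sweep(M, 2, colMeans(M))

simulate_motion_fixture <- function(nt, seed = 8) {
  set.seed(seed)
  cbind(matrix(cumsum(rnorm(nt * 3, 0, 0.02)), nt, 3),
        matrix(cumsum(rnorm(nt * 3, 0, 4e-4)), nt, 3))
}

# correlated trivariate Gaussian sample via Cholesky
trivariate <- function(n, r12, r13, r23, seed = 1) {
  set.seed(seed)
  S <- matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3)
  Z <- matrix(rnorm(n * 3), n, 3) %*% chol(S)
  data.frame(x = Z[, 1], y = Z[, 2], z = Z[, 3])
}

# random linear-Gaussian DAG over p nodes (topological order 1..p).  Two
# restrictions keep the system faithful, the regime the three-phase learner
# assumes: positive edge coefficients (random signs can cancel path effects)
# and no triangles (a shielded collider a -> b, a -> c <- b makes the
# partial correlation of the direct edge given the collider vanish almost
# exactly under reinforcing coefficients -- a near-unfaithful configuration
# unrecoverable by any conditional-independence test)
random_dag_data <- function(p = 6, n = 2000, edge_prob = 0.3, seed = 1,
                            coef_min = 0.5, coef_max = 0.9) {
  set.seed(seed)
  amat <- matrix(FALSE, p, p)
  sym <- function() amat | t(amat)
  for (j in 2:p) for (i in 1:(j - 1)) {
    if (runif(1) < edge_prob) {
      closes_triangle <- any(sym()[i, ] & sym()[j, ])
      if (!closes_triangle) amat[i, j] <- TRUE
    }
  }
  X <- matrix(0, n, p)
  for (j in 1:p) {
    X[, j] <- rnorm(n)
    parents <- which(amat[, j])
    for (i in parents) {
      X[, j] <- X[, j] + runif(1, coef_min, coef_max) * X[, i]
    }
  }
  colnames(X) <- paste0("v", 1:p)
  list(data = as.data.frame(X), amat = amat)
}

skeleton_metrics <- function(graph, amat) {
  p <- nrow(amat)
  vars <- paste0("v", 1:p)
  truth <- amat | t(amat)
  est <- matrix(FALSE, p, p, dimnames = list(vars, vars))
  if (nrow(graph$edges) > 0) {
    for (e in seq_len(nrow(graph$edges))) {
      i <- match(graph$edges$from[e], vars); j <- match(graph$edges$to[e], vars)
      est[i, j] <- est[j, i] <- TRUE
    }
  }
  tp <- sum(est & truth & upper.tri(truth))
  fp <- sum(est & !truth & upper.tri(truth))
  fn <- sum(!est & truth & upper.tri(truth))
  c(tp = tp, fp = fp, fn = fn)
}
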