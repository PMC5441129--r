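null_z <- function(n, nv, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * nv), n, nv)
}

test_that("voxel-wise regression t matches the closed-form simple-regression F", {
  set.seed(41)
  n <- 30
  x <- rnorm(n)
  z <- null_z(n, 5, seed = 42) + outer(x, c(0.8, -0.5, 0, 0.3, 0))
  des <- regression_design(cbind(score = x))
  fit <- fit_voxelwise_regression(z, des)
  for (v in 1:5) {
    lmfit <- summary(lm(z[, v] ~ x))
    expect_equal(fit$t[1, v]^2, lmfit$fstatistic[["value"]], tolerance = 1e-8)
    # negative-direction convention: positive t for negative slopes
    expect_equal(sign(fit$t[1, v]), -sign(coef(lmfit)[2, 1]))
  }
  expect_equal(fit$dof, n - 2)
})

test_that("regressor orthogonal to covariates equals the marginal fit", {
  set.seed(43)
  n <- 40
  cov1 <- rnorm(n)
  x <- residuals(lm(rnorm(n) ~ cov1))           # exactly orthogonal
  z <- null_z(n, 4, seed = 44)
  with_cov <- fit_voxelwise_regression(z, regression_design(cbind(s = x), cbind(cov1)))
  # coefficients equal the marginal fit when the regressor is orthogonal
  for (v in 1:4) {
    marg <- coef(lm(z[, v] ~ x))[2]
    full <- coef(lm(z[, v] ~ x + cov1))[2]
    expect_equal(unname(full), unname(marg), tolerance = 1e-10)
  }
  expect_equal(ncol(with_cov$t), 4L)
})

test_that("row permutation leaves the multiset of t values unchanged", {
  set.seed(45)
  n <- 25
  x <- cbind(a = rnorm(n), b = rnorm(n))
  covs <- cbind(c1 = rnorm(n))
  z <- null_z(n, 30, seed = 46)
  f1 <- fit_voxelwise_regression(z, regression_design(x, covs))
  perm <- sample(n)
  f2 <- fit_voxelwise_regression(z[perm, ], regression_design(x[perm, ], covs[perm, , drop = FALSE]))
  expect_equal(sort(f1$t[1, ]), sort(f2$t[1, ]), tolerance = 1e-8)
})

test_that("listwise deletion drops subjects with missing clinical values", {
  x <- cbind(s = c(1, 2, NA, 4, 5, 6, 7, 8, 9, 10))
  expect_message(des <- regression_design(x, subject_id = paste0("s", 1:10)),
                 "s3")
  expect_equal(sum(des$complete), 9)
})

test_that("cluster forming separates blobs and respects connectivity", {
  d <- c(8, 8, 8)
  tm <- array(0, d)
  tm[2:3, 2:3, 2] <- 10
  tm[6:7, 6:7, 6] <- 10
  tb <- form_clusters(tm, dof = 50, voxel_p = 0.01)
  expect_equal(nrow(tb), 2L)
  expect_equal(sort(tb$n_voxels), c(4L, 4L))
  # corner-touching voxels: separate under 18-connectivity, joined under 26
  tc <- array(0, d); tc[4, 4, 4] <- 10; tc[5, 5, 5] <- 10
  expect_equal(nrow(form_clusters(tc, 50, connectivity = 18L)), 2L)
  expect_equal(nrow(form_clusters(tc, 50, connectivity = 26L)), 1L)
  # edge-touching: joined under 18, separate under 6
  te <- array(0, d); te[4, 4, 4] <- 10; te[5, 5, 4] <- 10
  expect_equal(nrow(form_clusters(te, 50, connectivity = 6L)), 2L)
  expect_equal(nrow(form_clusters(te, 50, connectivity = 18L)), 1L)
  # full supra-threshold grid -> one cluster covering everything
  tfull <- array(10, d)
  tb_full <- form_clusters(tfull, 50)
  expect_equal(nrow(tb_full), 1L)
  expect_equal(tb_full$n_voxels, prod(d))
  # empty supra-threshold set -> empty table, not an error
  expect_equal(nrow(form_clusters(array(0, d), 50)), 0L)
})

test_that("local smoothness recovers the applied kernel and the iid limit", {
  set.seed(47)
  d <- c(16, 16, 16)
  n <- 30
  smoothed <- matrix(0, n, prod(d))
  for (i in seq_len(n)) {
    m <- gaussian_smooth(vol_map(array(rnorm(prod(d)), d), 3), 8)
    smoothed[i, ] <- as.vector(unclass(m))
  }
  mask <- array(TRUE, d)
  sm <- local_smoothness(smoothed, mask)
  med_fwhm_mm <- median(sm$fwhm_voxels, na.rm = TRUE) * 3
  expect_equal(med_fwhm_mm, 8, tolerance = 0.15)
  # unsmoothed iid noise: discrete-field theory gives sqrt(4 log 2 / 2) voxels
  iid <- matrix(rnorm(20 * prod(d)), 20, prod(d))
  sm_iid <- local_smoothness(iid, mask)
  expect_equal(median(sm_iid$fwhm_voxels, na.rm = TRUE), sqrt(4 * log(2) / 2),
               tolerance = 0.05)
  expect_error(local_smoothness(iid[1:5, ], mask), "at least 10")
})

test_that("under constant smoothness, normalized extent preserves extent order", {
  set.seed(48)
  d <- c(10, 10, 10)
  resid <- matrix(rnorm(25 * prod(d)), 25, prod(d))
  mask <- array(TRUE, d)
  sm <- local_smoothness(resid, mask)
  tm <- array(0, d)
  tm[2:3, 2, 2] <- 10          # 2 voxels
  tm[6:9, 6:7, 6] <- 10        # 8 voxels
  tb <- form_clusters(tm, 20, rpv = sm$rpv)
  expect_equal(order(tb$n_voxels), order(tb$extent_resels))
})

test_that("cluster FWE on null data controls the error rate and bounds p", {
  set.seed(49)
  d <- c(8L, 8L, 8L)
  mask <- array(TRUE, d)
  n <- 24
  z <- null_z(n, prod(d), seed = 50)
  des <- regression_design(cbind(score = rnorm(n)))
  fit <- cluster_fwe(z, des, mask, n_perm = 99, rng_seed = 51)
  expect_true(all(fit$clusters$p_corrected >= 1 / 100 - 1e-12))
  expect_true(all(fit$clusters$p_corrected <= 1))
  expect_lt(sum(fit$clusters$significant), max(1, nrow(fit$clusters)))
  expect_error(cluster_fwe(z, des, mask, n_perm = 10), "n_perm")
})

test_that("a planted network coupled to the regressor is detected", {
  sp <- tiny_spec(n_subjects = 90, grid = c(12L, 12L, 12L), rng_seed = 52)
  cl <- generate_clinical(sp)
  sfc <- cohort_sfc_maps(sp, cl)
  des <- regression_design(cbind(updrs_ii = cl$updrs_ii), clinical_covariates(cl))
  fit <- cluster_fwe(sfc$z, des, sfc$mask, n_perm = 99, rng_seed = 53)
  sig <- fit$clusters[fit$clusters$significant, ]
  expect_gt(nrow(sig), 0)
  tmpl <- which(as.vector(sp$network_templates[[1]]))
  overlap <- max(vapply(sig$voxels, function(v) length(intersect(v, tmpl)),
                        numeric(1)))
  expect_gt(overlap, 0)   # a significant cluster overlaps the planted network
  # and the overlapping cluster is mostly inside/around the template
  best <- sig$voxels[[which.max(vapply(sig$voxels, function(v)
    length(intersect(v, tmpl)), numeric(1)))]]
  expect_gt(length(intersect(best, tmpl)) / length(best), 0.5)
})

test_that("validity check reports the exact binomial CI of the stated method", {
  out <- binom_proportion(49, 1000, 0.99)
  expect_equal(out$proportion, 0.049)
  # independent Clopper-Pearson oracle via the beta quantile identities
  expect_equal(out$ci_low, qbeta(0.005, 49, 1000 - 49 + 1), tolerance = 1e-10)
  expect_equal(out$ci_high, qbeta(0.995, 49 + 1, 1000 - 49), tolerance = 1e-10)
  zero <- binom_proportion(0, 500)
  expect_equal(zero$proportion, 0)
  expect_equal(zero$ci_low, 0)
})

test_that("tidy and glance summarize a cluster fit", {
  set.seed(54)
  d <- c(6L, 6L, 6L)
  z <- null_z(20, prod(d), seed = 55)
  des <- regression_design(cbind(s = rnorm(20)))
  fit <- cluster_fwe(z, des, array(TRUE, d), n_perm = 49, rng_seed = 56)
  td <- tidy(fit)
  expect_false("voxels" %in% names(td))
  gl <- glance(fit)
  expect_equal(gl$n_perm, 49)
  expect_equal(gl$n_clusters, nrow(fit$clusters))
})
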