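test_that("24-parameter nuisance expansion matches hand enumeration", {
  col <- c(0, 1, 2, 3, 4)
  motion <- cbind(col, 0, 0, 0, 0, 0)
  X <- build_nuisance_matrix(motion)
  expect_equal(ncol(X), 24L)
  expect_equal(unname(X[, 1]), col)                       # motion
  expect_equal(unname(X[, 7]), c(0, 1, 1, 1, 1))          # accel (backward diff)
  expect_equal(unname(X[, 13]), c(0, 1, 4, 9, 16))        # motion^2
  expect_equal(unname(X[, 19]), c(0, 1, 1, 1, 1))         # accel^2
  expect_true(all(build_nuisance_matrix(matrix(0, 8, 6)) == 0))
  expect_error(build_nuisance_matrix(matrix(0, 2, 6)), "3 timepoints")
  expect_error(build_nuisance_matrix(matrix(0, 8, 5)), "6 columns")
})

test_that("regress_out matches a brute-force normal-equations oracle", {
  set.seed(11)
  s <- random_series(c(3, 3, 2), nt = 25, seed = 11)
  design <- matrix(rnorm(25 * 4), 25, 4)
  res <- regress_out(s, design)
  X <- cbind(1, design)
  P <- X %*% solve(crossprod(X)) %*% t(X)
  y <- t(matrix(unclass(s), 18, 25))
  oracle <- y - P %*% y
  expect_equal(t(matrix(unclass(res), 18, 25)), oracle, tolerance = 1e-10)
  # residuals orthogonal to every design column
  expect_lt(max(abs(crossprod(X, t(matrix(unclass(res), 18, 25))))) /
              max(abs(y)), 1e-8)
})

test_that("regress_out handles degenerate designs as specified", {
  s <- random_series(c(2, 2, 2), nt = 20, seed = 2)
  # series equal to a design column -> residual ~ 0
  d1 <- matrix(rnorm(20), 20, 1)
  s1 <- vol_series(array(rep(d1, each = 8), c(2, 2, 2, 20)), 3, 2)
  expect_lt(max(abs(unclass(regress_out(s1, d1)))), 1e-10)
  # design of zeros -> demeaned input (after dropping the dependent column)
  expect_warning(r0 <- regress_out(s, matrix(0, 20, 1)), "rank deficient")
  y <- t(matrix(unclass(s), 8, 20))
  expect_equal(t(matrix(unclass(r0), 8, 20)), sweep(y, 2, colMeans(y)),
               tolerance = 1e-12)
})

test_that("bandpass follows the analytic spectrum and removes DC", {
  # 0.15 Hz lies outside 0.01-0.08 -> essentially annihilated
  s_out <- sinusoid_series(0.15)
  expect_lt(rms(bandpass(s_out)) / rms(s_out), 0.01)
  # 0.04 Hz on an exact DFT bin (k = 16 at T=200, TR=2) -> retained
  s_in <- sinusoid_series(0.04)
  expect_gt(rms(bandpass(s_in)) / rms(s_in), 0.99)
  # constant series -> all zeros
  const <- vol_series(array(5, c(2, 2, 2, 100)), 3, 2)
  expect_lt(max(abs(unclass(bandpass(const)))), 1e-10)
  expect_error(bandpass(s_in, 0.08, 0.01), "greater than")
  expect_error(bandpass(s_in, 0.01, 0.4), "Nyquist")
})

test_that("detrend_linear removes the per-voxel best-fit line", {
  nt <- 30
  tc <- 2 + 0.5 * seq_len(nt)
  s <- vol_series(array(rep(tc, each = 4), c(2, 2, 1, nt)), 3, 2)
  expect_lt(max(abs(unclass(detrend_linear(s)))), 1e-10)
})

test_that("seed spheres resolve by center-to-center distance", {
  # radius 5 mm, 3 mm voxels: center + 6 face (3 mm) + 12 edge (4.243 mm);
  # corners at 5.196 mm excluded
  expect_equal(sum(resolve_seed(seed_spec(c(5, 5, 5), 5), c(11, 11, 11), 3)), 19)
  # radius below voxel size -> singleton
  expect_equal(sum(resolve_seed(seed_spec(c(5, 5, 5), 2), c(11, 11, 11), 3)), 1)
  # 1 mm voxels: brute-force enumeration over the 11^3 neighborhood
  brute <- sum(sqrt(rowSums(expand.grid(-5:5, -5:5, -5:5)^2)) <= 5)
  expect_equal(sum(resolve_seed(seed_spec(c(5, 5, 5), 5), c(11, 11, 11), 1)), brute)
  expect_error(resolve_seed(seed_spec(c(50, 5, 5), 5), c(11, 11, 11), 3),
               "outside the grid")
})

test_that("sfc_map computes Fisher-z seed correlations with clamping", {
  set.seed(21)
  d <- c(7, 7, 7); nt <- 150
  arr <- array(rnorm(prod(d) * nt), c(d, nt))
  seed <- seed_spec(c(3, 3, 3), 4)   # radius < 2 voxels at 3 mm -> small sphere
  sm <- resolve_seed(seed, d, 3)
  tc <- rnorm(nt)
  for (v in which(as.vector(sm))) {
    ijk <- arrayInd(v, d)
    arr[ijk[1], ijk[2], ijk[3], ] <- tc   # identical seed voxels
  }
  arr[7, 7, 7, ] <- tc                     # voxel identical to seed mean
  arr[1, 1, 1, ] <- 0                      # zero-variance voxel
  s <- vol_series(arr, 3, 2)
  z <- sfc_map(s, seed)
  expect_equal(z[7, 7, 7], atanh(1 - 1e-12))          # capped, finite
  expect_equal(z[1, 1, 1], 0)
  expect_equal(attr(z, "n_zero_variance"), 1L)
  # a white-noise voxel stays modest: |r| < 0.3 at T=150
  expect_lt(abs(tanh(z[5, 5, 5])), 0.3)
  # oracle check on one voxel
  r <- cor(arr[4, 5, 6, ], colMeans(matrix(arr, prod(d), nt)[as.vector(sm), ]))
  expect_equal(z[4, 5, 6], atanh(r), tolerance = 1e-12)
})

test_that("fisher_z is odd, strictly increasing, and inverts tanh", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(all(diff(fisher_z(r)) > 0))
  x <- seq(-3, 3, by = 0.25)
  expect_equal(atanh(tanh(x)), x, tolerance = 1e-12)
  expect_error(fisher_z(1), "< 1")
})

test_that("the preprocessing chain is invariant to added nuisance signal", {
  set.seed(31)
  d <- c(4, 4, 2); nt <- 60
  motion <- simulate_motion_fixture(nt)
  base <- array(rnorm(prod(d) * nt), c(d, nt))
  s1 <- vol_series(base, 3, 2)
  X <- build_nuisance_matrix(motion)
  contaminated <- base
  mix <- X %*% rnorm(24)
  for (t in seq_len(nt)) contaminated[, , , t] <- contaminated[, , , t] + mix[t]
  s2 <- vol_series(contaminated, 3, 2)
  p1 <- preprocess_series(s1, motion)
  p2 <- preprocess_series(s2, motion)
  expect_equal(unclass(p1)[], unclass(p2)[], tolerance = 1e-8)
})

test_that("motion QC flags excursions above one voxel size", {
  m <- matrix(0, 20, 6)
  expect_true(motion_within_limit(m, 3))
  m[10, 2] <- 3.5
  expect_false(motion_within_limit(m, 3))
})
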