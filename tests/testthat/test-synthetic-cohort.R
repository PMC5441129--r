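test_that("clinical generator reproduces the requested correlation structure", {
  # independence case: identity correlation matrix
  sp0 <- tiny_spec(n_subjects = 2000, updrs_corr = diag(3) + 0,
                   rng_seed = 3)
  dimnames(sp0$updrs_corr) <- NULL
  cl0 <- generate_clinical(sp0)
  cc <- cor(cbind(cl0$updrs_i, cl0$updrs_ii, cl0$updrs_iii))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.08)
  # default (printed) structure at n = 5000
  cl <- generate_clinical(tiny_spec(n_subjects = 5000, rng_seed = 17))
  expect_equal(cor(cl$updrs_i, cl$updrs_ii), 0.56, tolerance = 0.03 / 0.56)
  expect_equal(cor(cl$updrs_i, cl$updrs_iii), 0.33, tolerance = 0.05 / 0.33)
  expect_equal(cor(cl$updrs_ii, cl$updrs_iii), 0.46, tolerance = 0.04 / 0.46)
})

test_that("subscale totals, ranges and reproducibility hold by construction", {
  sp <- tiny_spec(n_subjects = 200, rng_seed = 9)
  cl <- generate_clinical(sp)
  expect_identical(cl$updrs_total, cl$updrs_i + cl$updrs_ii + cl$updrs_iii)
  expect_true(all(cl$updrs_i >= 0 & cl$updrs_i <= 23))
  expect_true(all(cl$updrs_ii >= 1 & cl$updrs_ii <= 23))
  expect_true(all(cl$updrs_iii >= 6 & cl$updrs_iii <= 47))
  expect_identical(cl, generate_clinical(sp))            # same seed, same cohort
  expect_false(identical(cl, generate_clinical(tiny_spec(n_subjects = 200,
                                                         rng_seed = 10))))
})

test_that("non-PSD correlation matrices are rejected naming the eigenvalue", {
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(tiny_spec(updrs_corr = bad), "eigenvalue")
  asym <- diag(3); asym[1, 2] <- 0.5
  expect_error(tiny_spec(updrs_corr = asym), "symmetric")
})

test_that("templates may not overlap the seed sphere", {
  d <- c(12L, 12L, 12L)
  tmpl <- array(FALSE, d); tmpl[3:5, 3:5, 3:5] <- TRUE   # contains seed center
  expect_error(cohort_spec(n_subjects = 8, grid_dims = d, seed_center = c(3, 3, 3),
                           network_templates = list(tmpl),
                           coupling_effects = -0.4,
                           coupling_targets = "updrs_ii"),
               "overlaps the seed")
})

test_that("short series are rejected (bandpass resolution)", {
  expect_error(tiny_spec(n_timepoints = 32), ">= 64")
})

test_that("planted couplings are calibrated to the observed scores", {
  sp <- tiny_spec(n_subjects = 150, rng_seed = 4)
  cl <- generate_clinical(sp)
  cp <- sfcpipe:::planted_couplings(sp, cl)
  expect_equal(cor(cp[, 1], cl$updrs_ii), -0.46, tolerance = 1e-10)
  expect_equal(cor(cp[, 2], cl$updrs_iii), -0.42, tolerance = 1e-10)
})

test_that("null cohorts carry no clinical-connectivity coupling", {
  sp <- tiny_spec(n_subjects = 60, grid = c(10L, 10L, 10L),
                  coupling_effects = c(0, 0), rng_seed = 6)
  cl <- generate_clinical(sp)
  sfc <- cohort_sfc_maps(sp, cl)
  tm <- which(as.vector(sp$network_templates[[1]]))
  net_z <- rowMeans(sfc$z[, match(tm, sfc$vox_idx)])
  for (u in list(cl$updrs_i, cl$updrs_ii, cl$updrs_iii)) {
    expect_lt(abs(cor(net_z, u)), 3 / sqrt(60))   # 3 SE of a null correlation
  }
})

test_that("the noiseless high-coupling limit drives seed-template r to 1", {
  sp <- tiny_spec(n_subjects = 4, grid = c(10L, 10L, 10L),
                  noise_sd = 1e-4, coupling_base = 1, coupling_sd = 1e-6,
                  seed_amplitude = 1, rng_seed = 12)
  cl <- generate_clinical(sp)
  cp <- sfcpipe:::planted_couplings(sp, cl)
  subj <- generate_subject_series(sp, cp[1, ], 1)
  pre <- preprocess_series(subj$series, subj$motion)
  z <- sfc_map(pre, sp$seed)
  tm <- which(as.vector(sp$network_templates[[1]]))
  expect_gt(min(tanh(as.vector(unclass(z))[tm])), 0.999)
})

test_that("DAT is independent of coupling by default and correlates on demand", {
  sp <- tiny_spec(n_subjects = 1000, rng_seed = 13)
  cl <- generate_clinical(sp)
  cp <- sfcpipe:::planted_couplings(sp, cl)
  dat <- sfcpipe:::generate_dat_regions(sp, 1000, "pd", cp)
  expect_lt(abs(cor(dat[, "ipsi_putamen"], cp[, 1])), 0.07)
  sp2 <- tiny_spec(n_subjects = 1000, dat_sfc_corr = 0.5, rng_seed = 13)
  dat2 <- sfcpipe:::generate_dat_regions(sp2, 1000, "pd", cp)
  expect_equal(cor(dat2[, "ipsi_putamen"], cp[, 1]), 0.5, tolerance = 0.1)
})

test_that("the PD group shows the planted DAT reduction against controls", {
  sp <- tiny_spec(n_subjects = 100, n_controls = 100, grid = c(10L, 10L, 10L),
                  rng_seed = 14)
  cohort <- generate_cohort(sp)
  tb <- cohort$dat_regions
  diff <- mean(tb$ipsi_putamen[tb$group == "hc"]) -
    mean(tb$ipsi_putamen[tb$group == "pd"])
  expect_equal(diff, sp$dat_effect, tolerance = 0.2)
})

test_that("cohort files round-trip through the documented on-disk formats", {
  sp <- cohort_spec(n_subjects = 4, grid_dims = c(8L, 8L, 8L),
                    seed_center = c(2, 2, 2), n_timepoints = 64, rng_seed = 15)
  cohort <- generate_cohort(sp)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "clinical.tsv")))
  back <- read_volume(file.path(dir, paste0(cohort$clinical$subject_id[1], "_rest.nii.gz")))
  # voxel data are bit-exact; header pixdims live in float32, so TR is only
  # compared at float precision
  expect_identical(array(as.numeric(back), dim(back)),
                   array(as.numeric(cohort$volumes[[1]]), dim(back)))
  expect_equal(tr(back), 2.4, tolerance = 1e-6)
  motion <- as.matrix(read.table(file.path(dir, paste0(cohort$clinical$subject_id[1],
                                                       "_motion.txt"))))
  expect_equal(unname(motion), unname(cohort$motion[[1]]), tolerance = 1e-12)
  clin <- read.delim(file.path(dir, "clinical.tsv"))
  expect_equal(clin$updrs_total, cohort$clinical$updrs_total)
})
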