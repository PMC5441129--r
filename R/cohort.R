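#' Synthetic cohort specification
#'
#' Collects every knob of the synthetic PPMI-style cohort generator: grid
#' geometry, seed location, planted connectivity networks and their coupling
#' to UPDRS subscales, the inter-subscale correlation structure, DAT-SPECT
#' group effects, and noise.  Defaults emulate a de novo PD resting-state
#' cohort of 87 patients with inter-subscale
#' correlations 0.56 / 0.33 / 0.46, two disjoint connectivity networks whose
#' coupling to the striatal seed decreases with UPDRS II (population
#' r = -0.46) and UPDRS III (r = -0.42), a DAT striatal-binding reduction in
#' the seed-containing region for patients versus controls, and a DAT signal
#' statistically independent of connectivity.
#'
#' @param n_subjects number of PD subjects (default 87, the rsMRI cohort size).
#' @param n_controls number of healthy controls (DAT/structural arm only;
#'   default 0).
#' @param grid_dims integer triple of voxels per axis (default 20^3, small
#'   enough for desk-scale permutation suites).
#' @param voxel_size_mm voxel edge length in mm (default 3).
#' @param n_timepoints resting-state series length (default 150; must be at
#'   least 64 so the passband spans several Fourier bins).
#' @param tr_seconds repetition time in seconds (default 2.4).
#' @param seed_center 0-based voxel index triple of the striatal seed center.
#' @param network_templates list of logical 3D masks, one planted network
#'   each; must be disjoint from the 5 mm seed sphere.  `NULL` builds two
#'   default cuboid templates ("SFC II"-like and "SFC III"-like).
#' @param coupling_effects numeric, one per template: population correlation
#'   between that network's coupling strength and its target subscale
#'   (negative: higher symptom severity, weaker coupling).
#' @param coupling_targets character, one per template, each one of
#'   `"updrs_i"`, `"updrs_ii"`, `"updrs_iii"`.
#' @param updrs_corr 3x3 symmetric positive semi-definite correlation matrix
#'   of the latent subscale Gaussians (defaults 0.56, 0.33, 0.46).
#' @param updrs_means,updrs_sds,updrs_ranges per-subscale marginal targets;
#'   defaults are the printed cohort values (means 6.9, 6.8, 19.8; SDs 5.1,
#'   4.7, 10.0; ranges 0-23, 1-23, 6-47).
#' @param coupling_base,coupling_sd mean and spread of the planted coupling
#'   amplitude (low-SNR regime keeps the coupling-to-Fisher-z map near
#'   linear).
#' @param seed_amplitude amplitude of the seed signal inside the seed sphere.
#' @param dat_effect group mean striatal-binding-ratio reduction at the
#'   seed-containing region, PD versus control (default 1.0 SBR units).
#' @param dat_sfc_corr population correlation between the seed-region DAT
#'   value and the first network's coupling (default 0: DAT independent of
#'   connectivity, the independence hypothesis the cross-modal analyses
#'   probe).
#' @param noise_sd SD of the iid Gaussian voxel noise (default 1).
#' @param rng_seed integer master seed; per-subject streams are derived from
#'   it by fixed offsets so cohorts are reproducible under subsetting.
#' @return An object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(n_subjects = 10, grid_dims = c(12, 12, 12))
#' spec$n_subjects
#' @export
cohort_spec <- function(n_subjects = 87,
                        n_controls = 0,
                        grid_dims = c(20L, 20L, 20L),
                        voxel_size_mm = 3,
                        n_timepoints = 150L,
                        tr_seconds = 2.4,
                        seed_center = NULL,
                        network_templates = NULL,
                        coupling_effects = c(-0.46, -0.42),
                        coupling_targets = c("updrs_ii", "updrs_iii"),
                        updrs_corr = default_updrs_corr(),
                        updrs_means = c(6.9, 6.8, 19.8),
                        updrs_sds = c(5.1, 4.7, 10.0),
                        updrs_ranges = default_updrs_ranges(),
                        coupling_base = 0.25,
                        coupling_sd = 0.075,
                        seed_amplitude = 1,
                        dat_effect = 1.0,
                        dat_sfc_corr = 0,
                        noise_sd = 1,
                        rng_seed = 1L) {
  grid_dims <- as.integer(grid_dims)
  stopifnot(length(grid_dims) == 3L, all(grid_dims >= 4L),
            n_subjects >= 1, n_controls >= 0, voxel_size_mm > 0,
            tr_seconds > 0, noise_sd > 0)
  if (n_timepoints < 64L) {
    stop("n_timepoints must be >= 64 for adequate bandpass resolution", call. = FALSE)
  }
  if (is.null(seed_center)) seed_center <- grid_dims %/% 4L
  check_updrs_corr(updrs_corr)
  stopifnot(length(coupling_effects) == length(coupling_targets),
            all(coupling_targets %in% c("updrs_i", "updrs_ii", "updrs_iii")),
            all(abs(coupling_effects) < 1))
  if (is.null(network_templates)) {
    network_templates <- default_templates(grid_dims, length(coupling_effects))
  }
  seed <- seed_spec(seed_center, radius_mm = 5)
  seed_mask <- resolve_seed(seed, grid_dims, voxel_size_mm)
  for (k in seq_along(network_templates)) {
    tm <- network_templates[[k]]
    stopifnot(is.logical(tm), all(dim(tm) == grid_dims))
    if (any(tm & seed_mask)) {
      stop("network template ", k, " overlaps the seed sphere", call. = FALSE)
    }
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_controls = as.integer(n_controls),
    grid_dims = grid_dims, voxel_size_mm = voxel_size_mm,
    n_timepoints = as.integer(n_timepoints), tr_seconds = tr_seconds,
    seed_center = as.integer(seed_center), seed = seed,
    network_templates = network_templates,
    coupling_effects = coupling_effects, coupling_targets = coupling_targets,
    updrs_corr = updrs_corr, updrs_means = updrs_means, updrs_sds = updrs_sds,
    updrs_ranges = updrs_ranges,
    coupling_base = coupling_base, coupling_sd = coupling_sd,
    seed_amplitude = seed_amplitude,
    dat_effect = dat_effect, dat_sfc_corr = dat_sfc_corr,
    noise_sd = noise_sd, rng_seed = as.integer(rng_seed)),
    class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("<cohort_spec> %d PD + %d HC, grid %s @ %g mm, ",
                     "%d timepoints (TR %g s), %d planted network(s)\n"),
              x$n_subjects, x$n_controls, paste(x$grid_dims, collapse = "x"),
              x$voxel_size_mm, x$n_timepoints, x$tr_seconds,
              length(x$network_templates)))
  invisible(x)
}

default_updrs_corr <- function() {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- 0.56
  m[1, 3] <- m[3, 1] <- 0.33
  m[2, 3] <- m[3, 2] <- 0.46
  dimnames(m) <- list(c("updrs_i", "updrs_ii", "updrs_iii"),
                      c("updrs_i", "updrs_ii", "updrs_iii"))
  m
}

default_updrs_ranges <- function() {
  list(updrs_i = c(0L, 23L), updrs_ii = c(1L, 23L), updrs_iii = c(6L, 47L))
}

check_updrs_corr <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(3L, 3L)))
  if (max(abs(m - t(m))) > 1e-10 || max(abs(diag(m) - 1)) > 1e-10) {
    stop("updrs_corr must be symmetric with unit diagonal", call. = FALSE)
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop(sprintf("updrs_corr is not positive semi-definite (smallest eigenvalue %.4g)",
                 min(ev)), call. = FALSE)
  }
  invisible(m)
}

# Two disjoint cuboid network templates placed away from the (default) seed
# quadrant; sized ~4 voxels per axis on the default 20^3 grid.
default_templates <- function(grid_dims, n_networks) {
  stopifnot(n_networks <= 3L)
  span <- function(lo_frac, len) {
    lo <- pmax(1L, as.integer(round(grid_dims * lo_frac)))
    hi <- pmin(grid_dims, lo + len - 1L)
    Map(seq, lo, hi)
  }
  len <- pmax(3L, grid_dims %/% 5L)
  corners <- list(c(0.65, 0.65, 0.65), c(0.65, 0.10, 0.65), c(0.10, 0.65, 0.65))
  lapply(seq_len(n_networks), function(k) {
    idx <- span(corners[[k]], len)
    m <- array(FALSE, grid_dims)
    m[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
    m
  })
}

# Fixed per-subject / per-stage RNG offsets.  Subject streams do not depend
# on cohort size, so subsetting a cohort reproduces the retained subjects.
subject_seed <- function(spec, i, stage = 0L) {
  (spec$rng_seed + 7919L * stage + i) %% .Machine$integer.max
}

#' Generate the clinical table of a synthetic cohort
#'
#' Subscale scores are drawn from a latent Gaussian copula with the requested
#' inter-subscale correlation matrix, then monotonically mapped to integers:
#' `round(mean + sd * z)` clamped into the printed ranges.  The map preserves
#' rank correlations and reproduces the printed means, SDs and ranges; the
#' UPDRS total is the exact sum of parts I-III.  Age, sex, dominant side and
#' the three binary medication flags are drawn from marginals typical of a
#' de novo PD cohort.
#'
#' @param spec a [cohort_spec()].
#' @return A tibble with one row per subject: `subject_id`, `group`,
#'   `updrs_i`, `updrs_ii`, `updrs_iii`, `updrs_total`, `age`, `sex`,
#'   `dominant_side`, `on_ldopa`, `on_da`, `on_other`.
#' @examples
#' clin <- generate_clinical(cohort_spec(n_subjects = 20, grid_dims = c(12, 12, 12)))
#' all(clin$updrs_total == clin$updrs_i + clin$updrs_ii + clin$updrs_iii)
#' @export
generate_clinical <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_subjects < 4L) stop("need at least 4 subjects", call. = FALSE)
  check_updrs_corr(spec$updrs_corr)
  n <- spec$n_subjects
  set.seed(subject_seed(spec, 0L, stage = 1L))
  L <- chol(spec$updrs_corr + diag(1e-12, 3))
  z <- matrix(stats::rnorm(n * 3L), n, 3L) %*% L
  scores <- vapply(1:3, function(j) {
    rng <- spec$updrs_ranges[[j]]
    as.integer(pmin(pmax(round(spec$updrs_means[j] + spec$updrs_sds[j] * z[, j]),
                         rng[1L]), rng[2L]))
  }, integer(n))
  age <- as.integer(pmin(pmax(round(stats::rnorm(n, 61, 10.5)), 38L), 78L))
  sex <- ifelse(stats::runif(n) < 59 / 87, "male", "female")
  side <- sample(c("left", "symmetric", "right"), n, replace = TRUE,
                 prob = c(33, 2, 52) / 87)
  tibble::tibble(
    subject_id = sprintf("pd%04d", seq_len(n)),
    group = "pd",
    updrs_i = scores[, 1L], updrs_ii = scores[, 2L], updrs_iii = scores[, 3L],
    updrs_total = scores[, 1L] + scores[, 2L] + scores[, 3L],
    age = age, sex = sex, dominant_side = side,
    on_ldopa = as.integer(stats::runif(n) < 32 / 87),
    on_da = as.integer(stats::runif(n) < 19 / 87),
    on_other = as.integer(stats::runif(n) < 19 / 87))
}

# Planted coupling amplitudes: affine in the (sample-standardized, observed)
# target subscale plus an orthogonalized Gaussian noise term.  The noise is
# residualized against the standardized subscale and re-standardized, so the
# sample correlation between coupling and subscale equals the requested
# effect exactly (the population correlation likewise); recovery tests then
# measure pipeline attenuation, not generator sampling noise.
# Returns an n x K matrix.
planted_couplings <- function(spec, clinical) {
  n <- nrow(clinical)
  K <- length(spec$coupling_effects)
  set.seed(subject_seed(spec, 0L, stage = 2L))
  couplings <- matrix(0, n, K)
  for (k in seq_len(K)) {
    u <- clinical[[spec$coupling_targets[k]]]
    zu <- as.numeric(scale(u))
    rho <- spec$coupling_effects[k]
    eps <- stats::rnorm(n)
    eperp <- as.numeric(residualize(matrix(eps, ncol = 1L),
                                    matrix(zu, ncol = 1L)))
    eperp <- eperp / stats::sd(eperp)
    couplings[, k] <- spec$coupling_base +
      spec$coupling_sd * (rho * zu + sqrt(1 - rho^2) * eperp)
  }
  colnames(couplings) <- paste0("network_", seq_len(K))
  couplings
}

# Band-limited unit-SD latent signal: white noise restricted to the
# connectivity passband so the planted coupling survives the pipeline's own
# bandpass filter.
bandlimited_signal <- function(nt, tr_seconds, low_hz = 0.01, high_hz = 0.08) {
  x <- stats::rnorm(nt)
  freqs <- bin_freqs(nt, tr_seconds)
  keep <- freqs >= low_hz & freqs <= high_hz & freqs > 0
  X <- stats::fft(x)
  X[!keep] <- 0
  s <- Re(stats::fft(X, inverse = TRUE)) / nt
  s / stats::sd(s)
}

# Simulated head motion: slow random-walk translations (mm) and rotations
# (radians), T x 6.
simulate_motion <- function(nt) {
  trans <- vapply(1:3, function(j) cumsum(stats::rnorm(nt, 0, 0.02)), numeric(nt))
  rot <- vapply(1:3, function(j) cumsum(stats::rnorm(nt, 0, 4e-4)), numeric(nt))
  m <- cbind(trans, rot)
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  m
}

#' Generate one subject's resting-state series
#'
#' The series is: iid Gaussian voxel noise, plus a band-limited seed signal
#' injected into the seed sphere, plus the same signal scaled by the
#' subject's planted coupling injected into each network template, plus a
#' motion artifact (a random linear mixture of the subject's 6 motion traces
#' added to a random 10% of voxels, so the 24-parameter regression
#' demonstrably removes it).  Each subject draws from its own RNG stream, so
#' any subject can be regenerated in isolation.
#'
#' @param spec a [cohort_spec()].
#' @param couplings numeric vector, the subject's coupling per network (row of
#'   the matrix in the cohort's `truth`).
#' @param i subject index (selects the RNG stream).
#' @return A list with elements `series` (a [vol_series()]) and `motion`
#'   (T x 6 matrix).
#' @export
generate_subject_series <- function(spec, couplings, i) {
  stopifnot(inherits(spec, "cohort_spec"),
            length(couplings) == length(spec$network_templates))
  set.seed(subject_seed(spec, i, stage = 3L))
  d <- spec$grid_dims
  nt <- spec$n_timepoints
  nv <- prod(d)
  motion <- simulate_motion(nt)
  s <- bandlimited_signal(nt, spec$tr_seconds)
  dat <- matrix(stats::rnorm(nv * nt, sd = spec$noise_sd), nv, nt)
  seed_idx <- which(as.vector(resolve_seed(spec$seed, d, spec$voxel_size_mm)))
  dat[seed_idx, ] <- dat[seed_idx, ] + rep(spec$seed_amplitude * s, each = length(seed_idx))
  for (k in seq_along(spec$network_templates)) {
    idx <- which(as.vector(spec$network_templates[[k]]))
    dat[idx, ] <- dat[idx, ] + rep(couplings[k] * s, each = length(idx))
  }
  n_art <- max(1L, round(0.10 * nv))
  art_idx <- sample.int(nv, n_art)
  # random mixing weights; rotations (radians, ~1e-2) up-weighted so both
  # blocks contribute comparable artifact amplitude
  w <- matrix(stats::rnorm(n_art * 6L), n_art, 6L) %*%
    diag(c(rep(0.5, 3L), rep(25, 3L)))
  dat[art_idx, ] <- dat[art_idx, ] + w %*% t(motion)
  list(series = vol_series(array(dat, c(d, nt)), spec$voxel_size_mm, spec$tr_seconds),
       motion = motion)
}

# Striatal region masks for the DAT maps: ipsilateral putamen (contains the
# seed center), ipsilateral caudate (offset box), contralateral mirrors
# across the x axis.
dat_region_masks <- function(spec) {
  d <- spec$grid_dims
  box <- function(center) {
    center <- pmin(pmax(center, 1L), d - 2L)  # keep the 3-wide box in grid
    m <- array(FALSE, d)
    m[center[1L] + 0:2, center[2L] + 0:2, center[3L] + 0:2] <- TRUE
    m
  }
  ctr <- spec$seed_center  # 0-based; box() takes 1-based lower corner
  ipsi_put <- ctr        # seed center inside
  ipsi_cau <- ctr + c(0L, 4L, 0L)
  mirror <- function(v) c(d[1L] - 3L - v[1L], v[2L], v[3L])
  list(ipsi_putamen = box(ipsi_put + 1L),
       contra_putamen = box(mirror(ipsi_put) + 1L),
       ipsi_caudate = box(ipsi_cau + 1L),
       contra_caudate = box(mirror(ipsi_cau) + 1L))
}

# Healthy-control SBR means per region; PD reductions are scaled from
# dat_effect (full effect at the seed-containing ipsilateral putamen).
DAT_HC_MEANS <- c(ipsi_putamen = 2.0, contra_putamen = 2.0,
                  ipsi_caudate = 2.6, contra_caudate = 2.6)
DAT_REDUCTION_SCALE <- c(ipsi_putamen = 1, contra_putamen = 0.8,
                         ipsi_caudate = 0.5, contra_caudate = 0.5)
DAT_SD <- 0.35

# Per-subject regional SBR values.  The seed-region value can be correlated
# with the first network's coupling via dat_sfc_corr (default 0).
generate_dat_regions <- function(spec, n, group, couplings = NULL) {
  set.seed(subject_seed(spec, 0L, stage = if (group == "pd") 4L else 5L))
  out <- matrix(0, n, 4L, dimnames = list(NULL, names(DAT_HC_MEANS)))
  for (j in seq_len(4L)) {
    mu <- DAT_HC_MEANS[j] - if (group == "pd") spec$dat_effect * DAT_REDUCTION_SCALE[j] else 0
    eta <- stats::rnorm(n)
    if (j == 1L && group == "pd" && !is.null(couplings) && spec$dat_sfc_corr != 0) {
      cz <- as.numeric(scale(couplings[, 1L]))
      eta <- spec$dat_sfc_corr * cz + sqrt(1 - spec$dat_sfc_corr^2) * eta
    }
    out[, j] <- mu + DAT_SD * eta
  }
  out
}

generate_dat_maps <- function(spec, regions, group) {
  masks <- dat_region_masks(spec)
  d <- spec$grid_dims
  set.seed(subject_seed(spec, 0L, stage = if (group == "pd") 6L else 7L))
  lapply(seq_len(nrow(regions)), function(i) {
    m <- array(stats::rnorm(prod(d), mean = 0.5, sd = 0.1), d)
    for (j in seq_along(masks)) m[masks[[j]]] <- regions[i, j] +
        stats::rnorm(sum(masks[[j]]), sd = 0.1)
    vol_map(m, voxel_size_mm = spec$voxel_size_mm)
  })
}

# Smooth gray-matter probability template: high inside a central ellipsoid,
# tapering to 0 at the edge of the grid.
gm_probability_template <- function(spec) {
  d <- spec$grid_dims
  ax <- lapply(d, function(n) (seq_len(n) - (n + 1) / 2) / (n / 2))
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  vol_map(array(pmax(0, pmin(1, 0.9 * (1 - r2))), d),
          voxel_size_mm = spec$voxel_size_mm)
}

#' Generate the imaging arm of a synthetic cohort
#'
#' Builds every subject's 4D series (via [generate_subject_series()]), motion
#' trace, regional DAT-SPECT striatal binding ratios and 3D SBR maps, plus a
#' shared gray-matter probability template, and records the planted truth
#' (coupling amplitudes and population correlations).
#'
#' @param spec a [cohort_spec()].
#' @param clinical the cohort's clinical table from [generate_clinical()].
#' @return An object of class `synthetic_cohort`: a list with `volumes`,
#'   `motion`, `clinical`, `dat_regions` (tibble, PD + controls),
#'   `dat_maps`, `gm_prob`, `spec` and `truth`.
#' @export
generate_imaging <- function(spec, clinical) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (nrow(clinical) != spec$n_subjects) {
    stop("clinical table has ", nrow(clinical), " rows but spec expects ",
         spec$n_subjects, call. = FALSE)
  }
  couplings <- planted_couplings(spec, clinical)
  subj <- lapply(seq_len(spec$n_subjects), function(i)
    generate_subject_series(spec, couplings[i, ], i))
  pd_regions <- generate_dat_regions(spec, spec$n_subjects, "pd", couplings)
  dat_tbl <- tibble::tibble(subject_id = clinical$subject_id, group = "pd",
                            tibble::as_tibble(pd_regions))
  dat_maps <- generate_dat_maps(spec, pd_regions, "pd")
  if (spec$n_controls > 0L) {
    hc_regions <- generate_dat_regions(spec, spec$n_controls, "hc")
    set.seed(subject_seed(spec, 0L, stage = 8L))
    hc_tbl <- tibble::tibble(
      subject_id = sprintf("hc%04d", seq_len(spec$n_controls)), group = "hc",
      tibble::as_tibble(hc_regions))
    hc_tbl$age <- as.integer(pmin(pmax(round(stats::rnorm(spec$n_controls, 61, 10.8)), 38L), 85L))
    hc_tbl$sex <- ifelse(stats::runif(spec$n_controls) < 135 / 198, "male", "female")
    dat_tbl$age <- clinical$age
    dat_tbl$sex <- clinical$sex
    dat_tbl <- dplyr::bind_rows(dat_tbl, hc_tbl)
    dat_maps <- c(dat_maps, generate_dat_maps(spec, hc_regions, "hc"))
  }
  structure(list(
    volumes = lapply(subj, `[[`, "series"),
    motion = lapply(subj, `[[`, "motion"),
    clinical = clinical,
    dat_regions = dat_tbl,
    dat_maps = dat_maps,
    gm_prob = gm_probability_template(spec),
    spec = spec,
    truth = list(couplings = couplings,
                 coupling_effects = spec$coupling_effects,
                 coupling_targets = spec$coupling_targets,
                 updrs_corr = spec$updrs_corr,
                 dat_sfc_corr = spec$dat_sfc_corr)),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d PD subjects (%d series), %d network(s)\n",
              x$spec$n_subjects, length(x$volumes), length(x$spec$network_templates)))
  invisible(x)
}

#' @rdname generate_imaging
#' @export
generate_cohort <- function(spec) {
  generate_imaging(spec, generate_clinical(spec))
}

#' Stream per-subject Fisher-z connectivity maps for a whole cohort
#'
#' Generates each subject's series, runs the standard preprocessing chain
#' (24-parameter motion regression, detrend, bandpass) and the seed
#' correlation map, keeping only the 3D z-map — so cohorts far larger than
#' memory would allow as raw 4D series can be simulated.
#'
#' @param spec a [cohort_spec()].
#' @param clinical clinical table (defines the planted couplings).
#' @param mask optional logical analysis mask.
#' @param smooth_fwhm_mm spatial smoothing applied before connectivity
#'   (default 0 on synthetic grids).
#' @param seed optional [seed_spec()] overriding the spec's planted seed
#'   (e.g. one chosen by [select_seed_peak()]).
#' @return A list: `z` (subjects x in-mask-voxels matrix of Fisher-z values),
#'   `mask`, `vox_idx` (in-mask linear indices), `truth` (planted couplings).
#' @export
cohort_sfc_maps <- function(spec, clinical, mask = NULL, smooth_fwhm_mm = 0,
                            seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  d <- spec$grid_dims
  if (is.null(mask)) mask <- array(TRUE, d)
  if (is.null(seed)) seed <- spec$seed
  vox_idx <- which(as.vector(mask))
  couplings <- planted_couplings(spec, clinical)
  z <- matrix(0, spec$n_subjects, length(vox_idx))
  for (i in seq_len(spec$n_subjects)) {
    subj <- generate_subject_series(spec, couplings[i, ], i)
    pre <- preprocess_series(subj$series, subj$motion,
                             smooth_fwhm_mm = smooth_fwhm_mm)
    zmap <- sfc_map(pre, seed, mask)
    z[i, ] <- as.vector(unclass(zmap))[vox_idx]
  }
  list(z = z, mask = mask, vox_idx = vox_idx,
       truth = list(couplings = couplings,
                    coupling_effects = spec$coupling_effects,
                    coupling_targets = spec$coupling_targets))
}

#' Write a synthetic cohort to disk
#'
#' Volumes as NIfTI-1, motion as 6-column whitespace-delimited text, clinical
#' and DAT tables as TSV with a header.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$volumes)) {
    id <- cohort$clinical$subject_id[i]
    write_volume(cohort$volumes[[i]], file.path(dir, paste0(id, "_rest.nii.gz")))
    utils::write.table(cohort$motion[[i]], file.path(dir, paste0(id, "_motion.txt")),
                       row.names = FALSE, col.names = FALSE)
  }
  for (i in seq_along(cohort$dat_maps)) {
    id <- cohort$dat_regions$subject_id[i]
    write_volume(cohort$dat_maps[[i]], file.path(dir, paste0(id, "_dat.nii.gz")))
  }
  write_volume(cohort$gm_prob, file.path(dir, "gm_prob.nii.gz"))
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$dat_regions, file.path(dir, "dat_regions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Numeric covariate matrix from a clinical table
#'
#' Encodes the standard covariates of no interest: age, sex (male = 1),
#' dominant side (two dummies against the symmetric reference) and the three
#' binary medication flags.
#'
#' @param clinical a clinical tibble (see [generate_clinical()]).
#' @return A numeric matrix with one row per subject.
#' @export
clinical_covariates <- function(clinical) {
  cbind(age = clinical$age,
        sex_male = as.numeric(clinical$sex == "male"),
        side_left = as.numeric(clinical$dominant_side == "left"),
        side_right = as.numeric(clinical$dominant_side == "right"),
        on_ldopa = clinical$on_ldopa,
        on_da = clinical$on_da,
        on_other = clinical$on_other)
}
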