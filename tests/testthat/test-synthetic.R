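test_that("invalid cohort specs are rejected with informative errors", {
  expect_error(small_spec(shared_weight = 1.5), "shared_weight")
  expect_error(small_spec(volume_coupling = -0.1), "volume_coupling")
  expect_error(small_spec(spacing_mm = c(1, -1, 1)), "spacing_mm")
  expect_error(small_spec(grid_shape = c(0, 24, 24)), "grid_shape")
  expect_error(small_spec(correlation_length_mm = 0), "correlation_length")
})

test_that("identical specs (including seed) give bit-identical cohorts", {
  spec <- small_spec(n_patients = 2, seed = 42)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  c3 <- generate_cohort(small_spec(n_patients = 2, seed = 43))
  expect_false(identical(a[[1]]$volumes$CT$values, c3[[1]]$volumes$CT$values))
})

test_that("fully shared noiseless identity cohort has identical modalities", {
  spec <- small_spec(n_patients = 2, seed = 5, shared_weight = 1,
                     modality_params = identity_modalities(noise_sd = 0),
                     n_fiducials = 0)
  coh <- generate_cohort(spec)
  for (pat in coh) {
    expect_equal(pat$volumes$T2w$values, pat$volumes$CT$values)
    expect_equal(pat$volumes$CT$values, pat$volumes$CBCT$values)
  }
})

test_that("cohort structure satisfies its invariants", {
  coh <- generate_cohort(small_spec(n_patients = 3, seed = 9))
  expect_length(coh, 3)
  for (pat in coh) {
    dims <- lapply(pat$volumes, function(v) dim(v$values))
    expect_true(all(vapply(dims, identical, TRUE, dim(pat$mask$inside))))
    expect_gte(sum(pat$mask$inside), 1)
    for (f in seq_len(nrow(pat$fiducials$centers))) {
      ctr <- pat$fiducials$centers[f, ]
      expect_true(pat$mask$inside[ctr[1], ctr[2], ctr[3]])
    }
  }
})

test_that("monotone intensity transforms preserve (or reverse) in-ROI ranks", {
  spec <- small_spec(n_patients = 1, seed = 3, shared_weight = 1,
                     n_fiducials = 0,
                     modality_params = list(
                       T2w = list(transform = "gamma", gamma = 0.7,
                                  gain = 50, offset = 10, noise_sd = 0),
                       CT = list(transform = "negate", gamma = 1,
                                 gain = 20, offset = 5, noise_sd = 0),
                       CBCT = list(transform = "identity", gamma = 1,
                                   gain = 3, offset = -2, noise_sd = 0)))
  pat <- generate_cohort(spec)[[1]]
  inside <- pat$mask$inside
  r_id <- rank(pat$volumes$CBCT$values[inside])
  r_gamma <- rank(pat$volumes$T2w$values[inside])
  r_neg <- rank(pat$volumes$CT$values[inside])
  expect_equal(r_gamma, r_id)
  expect_equal(r_neg, length(r_id) + 1 - r_id)
})

test_that("voxelized ellipsoid volume converges to the analytic volume", {
  radii <- c(8, 6, 7)
  analytic <- 4 * pi / 3 * prod(radii)
  err <- vapply(c(1, 0.5, 0.25), function(sp) {
    n <- ceiling(20 / sp)
    m <- ellipsoid_mask(rep(n, 3), rep(sp, 3), radii)
    abs(roi_volume_mm3(m, rep(sp, 3)) - analytic)
  }, 0)
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], analytic * 0.01)
  # within one voxel volume of analytic, relative to the finest grid
  expect_lt(err[3] / 0.25^3, analytic)
})

test_that("streak injection honours degenerate inputs and slice geometry", {
  vol <- image_volume(array(0, c(20, 20, 20)), 1, "CT")
  msk <- ellipsoid_mask(c(20, 20, 20), c(1, 1, 1), c(8, 8, 8))
  none <- fiducial_annotation(matrix(0L, 0, 3), list())
  sp <- list(n_streaks = 4, length_mm = 6, amplitude = 10, n_slices = 1)

  out0 <- inject_fiducial_streaks(vol, msk, none, sp)
  expect_identical(out0$vol$values, vol$values)
  expect_equal(nrow(out0$truth), 0)

  one <- fiducial_annotation(matrix(c(10L, 10L, 10L), 1), list(10L))
  set.seed(2)
  outa <- inject_fiducial_streaks(vol, msk, one,
                                  modifyList(sp, list(amplitude = 0)))
  expect_identical(outa$vol$values, vol$values)
  expect_equal(nrow(outa$truth), 0)

  set.seed(2)
  out1 <- inject_fiducial_streaks(vol, msk, one, sp)
  expect_gt(nrow(out1$truth), 0)
  expect_true(all(out1$truth[, 3] == 10L))
  expect_setequal(out1$artifact_slices[[1]], 10L)
})

test_that("streak detectability: supra-3-sigma fraction is countable truth", {
  set.seed(7)
  base <- array(rnorm(20^3, 0, 1), c(20, 20, 20))
  vol <- image_volume(base, 1, "CT")
  msk <- ellipsoid_mask(c(20, 20, 20), c(1, 1, 1), c(8, 8, 8))
  one <- fiducial_annotation(matrix(c(10L, 10L, 10L), 1), list(10L))
  sp <- list(n_streaks = 6, length_mm = 8, amplitude = 8, n_slices = 1)
  out <- inject_fiducial_streaks(vol, msk, one, sp)
  clean_mu <- mean(base)
  clean_sd <- sd(base)
  vals <- out$vol$values[out$truth]
  frac <- mean(abs(vals - clean_mu) > 3 * clean_sd)
  # opposite-sign streaks cancel where they cross near the seed, so a
  # small fraction of altered voxels stays sub-threshold
  expect_gt(frac, 0.85)
})

test_that("unshared cohorts show null cross-modality correlation; no
           spurious volume coupling", {
  n_rep <- 200
  n_pat <- 47
  set.seed(99)
  band <- spearman_null_band(n_pat)
  in_band <- logical(n_rep)
  vol_rho <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    coh <- generate_cohort(tiny_spec(
      n_patients = n_pat, seed = 1000 + r, shared_weight = 0,
      volume_coupling = 0,
      modality_params = identity_modalities(noise_sd = 0.05)))
    m <- t(vapply(coh, roi_means, numeric(3)))
    vols <- vapply(coh, function(p) p$truth$volume_mm3, 0)
    rho <- cor(m[, 1], m[, 2], method = "spearman")
    in_band[r] <- rho >= band[1] & rho <= band[2]
    vol_rho[r] <- abs(cor(vols, m[, 1], method = "spearman"))
  }
  expect_gte(mean(in_band), 0.93)
  # with zero coupling the mean |rho| vs volume stays below the null
  # 95% bound
  expect_lt(mean(vol_rho), unname(band[2]))
})
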