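test_that("GLCM on a 1x1x3 line matches the exhaustive pair enumeration", {
  lev <- array(c(1L, 1L, 2L), c(1, 1, 3))
  P <- build_glcm(make_q(lev))
  expect_equal(P, matrix(c(0.5, 0.25, 0.25, 0), 2, 2))
  f <- features_glcm(P)
  v <- setNames(f$value, f$feature)
  expect_equal(v[["GLCM_Energy"]], 0.375)
  expect_equal(v[["GLCM_Entropy"]], 1.5)
  expect_equal(v[["GLCM_Contrast"]], 0.5)
  expect_equal(v[["GLCM_Homogeneity"]], 0.75)
})

test_that("merged GLCM equals the sum of 13 per-direction matrices", {
  set.seed(41)
  for (rep in 1:5) {
    lev <- random_level_roi(4, 2)
    q <- make_q(lev)
    counts <- build_glcm(q) * sum(oracle_glcm(lev, normalize = FALSE))
    expect_equal(counts, oracle_glcm(lev, normalize = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("constant ROI yields the degenerate closed forms", {
  lev <- array(1L, c(3, 3, 3))
  q <- make_q(lev)
  P <- build_glcm(q)
  expect_equal(P, matrix(1, 1, 1))
  f <- setNames(features_glcm(P)$value, features_glcm(P)$feature)
  expect_equal(f[["GLCM_Energy"]], 1)
  expect_equal(f[["GLCM_Entropy"]], 0)
  expect_equal(f[["GLCM_Contrast"]], 0)
  expect_equal(f[["GLCM_Dissimilarity"]], 0)
  expect_equal(f[["GLCM_Homogeneity"]], 1)
  expect_false(features_glcm(P)$defined[2]) # Correlation flagged

  # one zone of size 27; ZP = 1/27
  Z <- build_glszm(q)
  expect_equal(Z, matrix(c(rep(0, 26), 1), 1, 27))
  fz <- setNames(features_glszm(Z, 27)$value, features_glszm(Z, 27)$feature)
  expect_equal(fz[["GLSZM_ZP"]], 1 / 27)

  # NGTDM: zero differences everywhere
  parts <- build_ngtdm(q)
  expect_equal(sum(parts$s), 0)
  fn <- setNames(features_ngtdm(parts)$value, features_ngtdm(parts)$feature)
  expect_equal(fn[["NGTDM_Contrast"]], 0)
  expect_equal(fn[["NGTDM_Coarseness"]], 1e6) # 1/eps sentinel

  # IS on constant raw values: sigma = 0 flags
  fi <- features_intensity(rep(4, 27))
  expect_equal(fi$value[fi$feature == "IS_Variance"], 0)
  expect_false(fi$defined[fi$feature == "IS_Skewness"])
})

test_that("GLCM features error on a single-voxel ROI but extraction
           flags them instead", {
  lev <- array(NA_integer_, c(2, 2, 2))
  lev[1, 1, 1] <- 1L
  q <- make_q(lev)
  expect_error(build_glcm(q), "no in-mask voxel pairs")
  feats <- extract_features(q, image_volume(array(1, c(2, 2, 2)), 1))
  glcm_rows <- feats[feats$family == "GLCM", ]
  expect_true(all(!glcm_rows$defined))
  expect_equal(nrow(feats), 43)
})

test_that("GLRLM handles line ROIs and conserves voxel-direction mass", {
  # single voxel: 13 runs of length 1
  lev1 <- array(NA_integer_, c(3, 3, 3)); lev1[2, 2, 2] <- 1L
  M1 <- build_glrlm(make_q(lev1))
  expect_equal(M1, matrix(13, 1, 1))
  f1 <- setNames(features_glrlm(M1, 1)$value, features_glrlm(M1, 1)$feature)
  expect_equal(f1[["GLRLM_SRE"]], 1)
  expect_equal(f1[["GLRLM_LRE"]], 1)
  expect_equal(f1[["GLRLM_RP"]], 1)

  # 1x1x4 constant line: one run of 4 along the axis, 48 singleton runs
  lev2 <- array(1L, c(1, 1, 4))
  M2 <- build_glrlm(make_q(lev2))
  expect_equal(M2, oracle_glrlm(lev2))
  expect_equal(M2[1, 4], 1)
  expect_equal(M2[1, 1], 48)
  expect_equal(sum(sweep(M2, 2, 1:4, `*`)), 4 * 13)
})

test_that("checkerboard zones follow the component-labeling oracle", {
  lev <- array(NA_integer_, c(3, 3, 1))
  lev[, , 1] <- (outer(1:3, 1:3, `+`) %% 2) + 1L
  M <- build_glszm(make_q(lev))
  expect_equal(M, oracle_glszm(lev))
  # under 26-connectivity the diagonal same-level cells join up
  expect_equal(sum(M), 2)
})

test_that("NGTDM parts on a 1x1x3 line match the neighborhood oracle", {
  lev <- array(c(1L, 2L, 1L), c(1, 1, 3))
  parts <- build_ngtdm(make_q(lev))
  o <- oracle_ngtdm(lev)
  expect_equal(parts$s, o$s)
  expect_equal(parts$N, o$N)
  expect_equal(parts$s[2], 1) # |2 - mean(1,1)|
  expect_equal(parts$s[1], abs(1 - 2) + abs(1 - 2)) # ends see only level 2
})

test_that("matrix conservation laws hold on random ROIs", {
  set.seed(42)
  for (rep in 1:20) {
    lev <- random_level_roi()
    q <- make_q(lev)
    nvox <- sum(!is.na(lev))
    if (nvox < 2) next
    P <- tryCatch(build_glcm(q), error = function(e) NULL)
    if (!is.null(P)) {
      expect_equal(sum(P), 1)
      expect_equal(P, t(P))
      expect_true(all(P >= 0))
    }
    R <- build_glrlm(q)
    expect_equal(sum(sweep(R, 2, seq_len(ncol(R)), `*`)), nvox * 13)
    Z <- build_glszm(q)
    expect_equal(sum(sweep(Z, 2, seq_len(ncol(Z)), `*`)), nvox)
    parts <- build_ngtdm(q)
    expect_equal(sum(parts$p[parts$N > 0]), 1)
    tab <- tabulate(lev[!is.na(lev)], nbins = length(q$codebook))
    expect_true(all(parts$N <= tab)) # isolated voxels may be excluded
  }
})

test_that("intensity statistics match hand-computed moments", {
  f <- features_intensity(c(1, 2, 3))
  v <- setNames(f$value, f$feature)
  expect_equal(v[["IS_Variance"]], 2 / 3)
  expect_equal(v[["IS_Skewness"]], 0)
  sym <- c(-3, -1, 0, 1, 3)
  expect_equal(features_intensity(sym)$value[2], 0) # Skewness row
  set.seed(43)
  g <- rnorm(1e5)
  kurt <- features_intensity(g)$value[1]
  expect_equal(kurt, 3, tolerance = 0.1 / 3)
})

test_that("volume normalization arithmetic and volume-sensitivity", {
  reg <- feature_registry()
  # Type 1 and Type 2 arithmetic on a synthetic feature table
  ft <- tibble::tibble(feature = c("GLRLM_GLN", "NGTDM_Strength"),
                       value = c(10, 10), defined = TRUE)
  parts <- list(s = c(1, 1), N = c(5, 5), p = c(0.5, 0.5), levels = 1:2)
  out <- apply_volume_normalization(ft, parts, V = 5)
  expect_equal(out$value[out$feature == "GLRLM_GLN"], 2)
  expect_equal(out$value[out$feature == "NGTDM_Strength"], 50)
  expect_equal(out$value_raw, c(10, 10))

  # doubling the volume by tiling changes normalized GLN far less than
  # raw GLN
  set.seed(44)
  for (rep in 1:20) {
    lev <- array(sample(1:3, 4 * 4 * 3, replace = TRUE), c(4, 4, 3))
    lev2 <- array(c(lev, lev), c(4, 4, 6)) # 2x tiling along z
    f1 <- extract_features(make_q(lev), image_volume(lev * 1.0, 1))
    f2 <- extract_features(make_q(lev2), image_volume(lev2 * 1.0, 1))
    raw1 <- f1$value_raw[f1$feature == "GLRLM_GLN"]
    raw2 <- f2$value_raw[f2$feature == "GLRLM_GLN"]
    vn1 <- f1$value[f1$feature == "GLRLM_GLN"]
    vn2 <- f2$value[f2$feature == "GLRLM_GLN"]
    rel_raw <- abs(raw2 - raw1) / abs(raw1)
    rel_vn <- abs(vn2 - vn1) / abs(vn1)
    expect_lt(rel_vn, rel_raw)
  }
})

test_that("level shift leaves count-based features unchanged", {
  set.seed(45)
  lev <- random_level_roi(5, 3)
  q1 <- make_q(lev)
  shifted <- lev + 2L
  q2 <- structure(list(levels = shifted, mask = roi_mask(!is.na(lev)),
                       ng = max(shifted, na.rm = TRUE),
                       ng_effective = max(shifted, na.rm = TRUE),
                       codebook = seq_len(max(shifted, na.rm = TRUE)),
                       range = c(1, max(shifted, na.rm = TRUE)),
                       iterations = 0L, mse_trace = numeric(0)),
                  class = "quantized_roi")
  nvox <- sum(!is.na(lev))
  f1 <- features_glrlm(build_glrlm(q1), nvox)
  f2 <- features_glrlm(build_glrlm(q2), nvox)
  for (nm in c("GLRLM_SRE", "GLRLM_LRE", "GLRLM_RP", "GLRLM_GLN",
               "GLRLM_RLN")) {
    expect_equal(f1$value[f1$feature == nm], f2$value[f2$feature == nm])
  }
  z1 <- features_glszm(build_glszm(q1), nvox)
  z2 <- features_glszm(build_glszm(q2), nvox)
  for (nm in c("GLSZM_ZP", "GLSZM_GLN", "GLSZM_ZSN", "GLSZM_SZE")) {
    expect_equal(z1$value[z1$feature == nm], z2$value[z2$feature == nm])
  }
})

test_that("full extraction matches the straight-from-definition oracle", {
  set.seed(46)
  for (rep in 1:10) {
    lev <- random_level_roi()
    if (sum(!is.na(lev)) < 3) next
    raw <- array(rnorm(length(lev), 100, 10), dim(lev))
    feats <- extract_features(make_q(lev), image_volume(raw, 1))
    oracle <- oracle_all_features(lev, raw)
    got <- setNames(feats$value, feats$feature)
    for (nm in names(oracle)) {
      if (!is.finite(oracle[[nm]])) {
        expect_false(feats$defined[feats$feature == nm])
      } else {
        expect_equal(got[[nm]], oracle[[nm]], tolerance = 1e-10)
      }
    }
    expect_equal(got[["volume_mm3"]], sum(!is.na(lev)))
  }
})
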