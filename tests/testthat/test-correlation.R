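test_that("Spearman examples and oracle agreement", {
  expect_equal(spearman_abs(1:10, 1:10)$abs_rho, 1)
  expect_equal(spearman_abs(1:10, 10:1)$abs_rho, 1)
  ex <- spearman_abs(c(1, 2, 3, 4, 5), c(1, 2, 3, 5, 4))
  expect_equal(ex$rho, 0.9) # 1 - 6*2/(5*24)
  # agreement with a from-scratch rank-then-Pearson oracle, with ties
  set.seed(51)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    x <- sample(1:8, n, replace = TRUE)
    y <- x * sample(c(-1, 1), 1) + rnorm(n, 0, 2)
    s <- spearman_abs(x, y)
    if (!s$defined) next
    expect_equal(s$rho, oracle_spearman(x, y), tolerance = 1e-12)
    expect_equal(s$abs_rho, abs(cor(x, y, method = "spearman")),
                 tolerance = 1e-12)
  }
})

test_that("Spearman statistic is exact over all permutations at small n", {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  x <- 1:5
  for (p in perms(1:5)) {
    d2 <- sum((x - p)^2)
    expect_equal(spearman_abs(x, p)$rho, 1 - 6 * d2 / (5 * 24))
  }
})

test_that("degenerate Spearman inputs are flagged undefined", {
  expect_false(spearman_abs(c(1, 2), c(3, 4))$defined)
  expect_false(spearman_abs(rep(1, 10), 1:10)$defined)
  expect_false(spearman_abs(c(1, 2, NA), c(1, NA, 3))$defined)
})

test_that("Benjamini-Hochberg step-up matches the hand computation", {
  adj <- bh_adjust(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(adj$p_adj, rep(0.04, 4))
  expect_equal(bh_adjust(0.123)$p_adj, 0.123)
  expect_equal(nrow(bh_adjust(numeric(0))), 0)
  set.seed(52)
  for (rep in 1:10) {
    p <- runif(sample(2:50, 1))
    got <- bh_adjust(p)$p_adj
    expect_equal(got, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(got >= p))
    o <- order(p)
    expect_true(all(diff(got[o]) >= -1e-12))
  }
})

sim_feature_table <- function(n_pat, features, n_modalities = 3,
                              volume = NULL) {
  mods <- c("T2w", "CT", "CBCT")[seq_len(n_modalities)]
  if (is.null(volume)) volume <- rlnorm(n_pat, 10, 0.3)
  rows <- list()
  for (m in mods) {
    for (f in names(features)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        patient_id = sprintf("P%03d", seq_len(n_pat)), modality = m,
        feature = f, value = features[[f]])
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      patient_id = sprintf("P%03d", seq_len(n_pat)), modality = m,
      feature = "volume_mm3", value = volume)
  }
  dplyr::bind_rows(rows)
}

test_that("volume filter drops volume copies and keeps independent
           features", {
  set.seed(53)
  n <- 47
  vol <- rlnorm(n, 10, 0.3)
  tbl <- sim_feature_table(n, list(copycat = vol + rnorm(n, 0, 1e-6),
                                   indep = rnorm(n)),
                           volume = vol)
  vf <- volume_filter(tbl)
  expect_true(all(vf$dropped$feature == "copycat"))
  expect_equal(nrow(vf$dropped), 3) # one per modality
  expect_true("indep" %in% vf$features$feature)
  expect_false("copycat" %in% vf$features$feature)
  expect_true(all(vf$volume_corr$r_v[vf$volume_corr$feature ==
                                       "copycat"] > 0.99))
})

test_that("report pair counts and classes follow the combinatorics", {
  set.seed(54)
  n <- 20
  F <- 4
  feats <- setNames(lapply(1:F, function(i) rnorm(n)),
                    paste0("f", 1:F))
  tbl <- sim_feature_table(n, feats)
  rep1 <- correlation_report(tbl, volume_threshold = NULL)
  k <- 3 * F
  expect_equal(nrow(rep1$pairs) + nrow(rep1$undefined_pairs),
               k * (k - 1) / 2)
  cls <- table(rep1$pairs$class)
  expect_equal(unname(cls[["intramodality"]]), 3 * F * (F - 1) / 2)
  expect_equal(unname(cls[["intermodality_same_rf"]]), 3 * F)
  expect_true(all(rep1$pairs$p_adj >= rep1$pairs$p_raw - 1e-15))

  # permuting input row order leaves the (pair, value) multiset intact
  tbl2 <- dplyr::arrange(tbl, dplyr::desc(.data$feature), .data$modality)
  rep2 <- correlation_report(tbl2, volume_threshold = NULL)
  key <- function(r) {
    k <- dplyr::mutate(r$pairs,
                       a = pmin(.data$col_a, .data$col_b),
                       b = pmax(.data$col_a, .data$col_b))
    dplyr::arrange(k, .data$a, .data$b)[, c("a", "b", "abs_rho", "p_adj")]
  }
  expect_equal(key(rep1), key(rep2), tolerance = 1e-12)
})

test_that("pairwise-complete path agrees with the dense path", {
  set.seed(55)
  n <- 30
  feats <- list(f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n))
  tbl <- sim_feature_table(n, feats)
  dense <- correlation_report(tbl, volume_threshold = NULL)
  tbl_na <- tbl
  tbl_na$value[5] <- NA # single missing value switches implementation path
  sparse <- correlation_report(tbl_na, volume_threshold = NULL)
  shared <- dplyr::inner_join(
    dense$pairs[, c("col_a", "col_b", "abs_rho", "n")],
    sparse$pairs[, c("col_a", "col_b", "abs_rho", "n")],
    by = c("col_a", "col_b"))
  unaffected <- shared[shared$n.x == shared$n.y, ]
  expect_gt(nrow(unaffected), 0)
  expect_equal(unaffected$abs_rho.x, unaffected$abs_rho.y,
               tolerance = 1e-12)
})

test_that("summaries count thresholds and histogram modes correctly", {
  set.seed(56)
  n <- 15
  feats <- list(f1 = rnorm(n), f2 = rnorm(n))
  tbl <- sim_feature_table(n, feats)
  rep1 <- correlation_report(tbl, volume_threshold = NULL)
  # force a fixture: all pairs significant with |rho| = 1 -> 100% above
  # every threshold
  fix <- rep1
  fix$pairs$abs_rho <- 1
  fix$pairs$significant <- TRUE
  s <- summarize_correlations(fix)
  expect_true(all(s$by_group$pct_significant == 100))
  expect_true(all(s$by_group$`pct_ge_0.75` == 100))
  expect_true(all(s$by_group$`pct_ge_0.95` == 100))
  expect_equal(unique(s$by_group$mode_bin_center), 0.975)
  # hand-counted fixture on one class
  fix2 <- rep1
  fix2$pairs$significant <- TRUE
  intra_ct <- dplyr::filter(fix2$pairs, .data$class == "intramodality",
                            .data$modality_a == "CT")
  s2 <- summarize_correlations(fix2)
  row <- dplyr::filter(s2$by_group, .data$class == "intramodality",
                       .data$group == "CT")
  expect_equal(row$n_significant, nrow(intra_ct))
  expect_equal(row$`pct_ge_0.75`, 100 * mean(intra_ct$abs_rho >= 0.75))
})

test_that("paired t-test flags identical tables and constant shifts", {
  set.seed(57)
  n <- 10
  tbl <- tibble::tibble(
    patient_id = rep(sprintf("P%02d", 1:n), 2),
    feature = rep(c("GLRLM_SRE", "GLSZM_ZP"), each = n),
    value = rnorm(2 * n, 10, 2))
  same <- paired_feature_ttest(tbl, tbl)
  expect_true(all(same$zero_variance))
  expect_equal(same$p, rep(1, 2))
  expect_equal(same$t, rep(0, 2))
  expect_equal(same$spearman_r, rep(1, 2))

  shifted <- dplyr::mutate(tbl, value = .data$value + 5)
  sh <- paired_feature_ttest(shifted, tbl)
  expect_equal(sh$spearman_r, rep(1, 2))
  expect_true(all(sh$p < 1e-6))
  expect_true(all(abs(sh$t) > 50))
})

test_that("shared texture weight drives intermodality same-feature
           correlation and volume coupling is recovered", {
  # mean-intensity feature across patients: w = 0.9 cohorts must show a
  # clearly higher cross-modality correlation than w = 0.1 cohorts
  set.seed(58)
  m_rho <- function(w, seeds) {
    vapply(seeds, function(s) {
      coh <- generate_cohort(tiny_spec(
        n_patients = 30, seed = s, shared_weight = w,
        modality_params = identity_modalities(noise_sd = 0.05)))
      m <- t(vapply(coh, roi_means, numeric(3)))
      mean(c(abs(cor(m[, 1], m[, 2], method = "spearman")),
             abs(cor(m[, 1], m[, 3], method = "spearman")),
             abs(cor(m[, 2], m[, 3], method = "spearman"))))
    }, 0)
  }
  hi <- m_rho(0.9, 101:110)
  lo <- m_rho(0.1, 201:210)
  expect_gt(mean(hi), mean(lo))
  expect_gt(mean(hi), 0.8)

  # volume_coupling = 1: the volume-coupled mean-intensity feature is
  # dropped by the volume filter in nearly all cohorts
  dropped <- vapply(301:320, function(s) {
    coh <- generate_cohort(tiny_spec(
      n_patients = 47, seed = s, shared_weight = 0.5, volume_coupling = 1,
      modality_params = identity_modalities(noise_sd = 0.05)))
    m <- t(vapply(coh, roi_means, numeric(3)))
    vols <- vapply(coh, function(p) p$truth$volume_mm3, 0)
    tbl <- dplyr::bind_rows(
      tibble::tibble(patient_id = seq_len(47), modality = "T2w",
                     feature = "mean_intensity", value = m[, 1]),
      tibble::tibble(patient_id = seq_len(47), modality = "T2w",
                     feature = "volume_mm3", value = vols))
    nrow(volume_filter(tbl)$dropped) == 1
  }, TRUE)
  expect_gte(mean(dropped), 0.95)
})
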