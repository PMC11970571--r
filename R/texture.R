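## Texture matrices and the 42-feature extraction.
##
## All matrices are built in 3D with the 13 unique distance-1 direction
## offsets merged into a single matrix (GLCM symmetric, GLRLM summed over
## directions); zones use 26-connectivity. Gray levels are the 1..Ng
## output of the Lloyd-Max quantizer.

levels_vector <- function(q) {
  v <- q$levels
  v[is.na(v)] <- 0L
  storage.mode(v) <- "integer"
  v
}

n_levels <- function(q) length(q$codebook)

#' Gray-level co-occurrence matrix
#'
#' Counts level pairs over the 13 unique 3D direction offsets at
#' distance 1, in both orderings (so the matrix is symmetric), keeping
#' only pairs with both voxels in the mask, and normalizes to joint
#' probabilities.
#'
#' @param q a `quantized_roi` from [lloyd_quantize()].
#' @return Ng x Ng probability matrix summing to 1.
#' @export
build_glcm <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  M <- cpp_glcm(levels_vector(q), dim(q$levels), n_levels(q))
  tot <- sum(M)
  if (tot == 0)
    stop("GLCM undefined: ROI has no in-mask voxel pairs", call. = FALSE)
  M / tot
}

#' GLCM features
#'
#' The eight co-occurrence features: Contrast, Correlation,
#' Dissimilarity, Energy (angular second moment), Entropy (base-2),
#' Homogeneity (inverse difference), Sum Average and (joint) Variance.
#' Correlation is undefined (flagged) when the marginal variance is 0.
#'
#' @param P normalized symmetric GLCM from [build_glcm()].
#' @return tibble with columns `feature`, `value`, `defined`.
#' @export
features_glcm <- function(P) {
  ng <- nrow(P)
  I <- row(P); J <- col(P)
  px <- rowSums(P)
  g <- seq_len(ng)
  mu <- sum(g * px)
  sig2 <- sum((g - mu)^2 * px)
  pos <- P > 0
  vals <- c(
    Contrast      = sum((I - J)^2 * P),
    Correlation   = if (sig2 > 0) (sum(I * J * P) - mu^2) / sig2 else NA_real_,
    Dissimilarity = sum(abs(I - J) * P),
    Energy        = sum(P^2),
    Entropy       = -sum(P[pos] * log2(P[pos])),
    Homogeneity   = sum(P / (1 + abs(I - J))),
    SumAverage    = sum((I + J) * P),
    Variance      = sum((I - mu)^2 * P)
  )
  tibble::tibble(feature = paste0("GLCM_", names(vals)), value = unname(vals),
                 defined = is.finite(unname(vals)))
}

#' Gray-level run-length matrix
#'
#' Maximal runs of equal level along each of the 13 unique 3D directions,
#' accumulated into one merged Ng x Rmax count matrix (trailing all-zero
#' run-length columns trimmed).
#'
#' @param q a `quantized_roi`.
#' @return count matrix; `sum(r * M[, r])` equals `13 * n_voxels`.
#' @export
build_glrlm <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  M <- cpp_glrlm(levels_vector(q), dim(q$levels), n_levels(q))
  last <- max(which(colSums(M) > 0))
  M[, seq_len(last), drop = FALSE]
}

#' Gray-level size-zone matrix
#'
#' Zones are 26-connected components of constant level; the matrix
#' counts zones by level and size. `sum(z * M[, z])` equals `n_voxels`.
#'
#' @param q a `quantized_roi`.
#' @return Ng x Zmax count matrix.
#' @export
build_glszm <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  Z <- cpp_glszm_zones(levels_vector(q), dim(q$levels))
  ng <- n_levels(q)
  zmax <- max(Z[, 2])
  M <- matrix(0, ng, zmax)
  for (i in seq_len(nrow(Z))) M[Z[i, 1], Z[i, 2]] <- M[Z[i, 1], Z[i, 2]] + 1
  M
}

# Shared run-length / size-zone feature formulas. M: counts; weights on
# level g and size r. `rate_den`: n_voxels * 13 for runs (run
# percentage), n_voxels for zones (zone percentage).
rlsz_features <- function(M, n_voxels, rate_den,
                          prefix_small, prefix_large) {
  Ns <- sum(M)
  p <- M / Ns
  g <- seq_len(nrow(M))
  r <- seq_len(ncol(M))
  pg <- rowSums(p)
  pr <- colSums(p)
  mu_g <- sum(g * pg)
  mu_r <- sum(r * pr)
  vals <- c(
    sum(pr / r^2),                       # short emphasis
    sum(pr * r^2),                       # long/large emphasis
    sum(pg / g^2),                       # low gray-level
    sum(pg * g^2),                       # high gray-level
    sum(p * outer(1 / g^2, 1 / r^2)),    # short + low
    sum(p * outer(g^2, 1 / r^2)),        # short + high
    sum(p * outer(1 / g^2, r^2)),        # long + low
    sum(p * outer(g^2, r^2)),            # long + high
    sum(rowSums(M)^2) / Ns,              # gray-level non-uniformity
    sum(colSums(M)^2) / Ns,              # run/zone non-uniformity
    Ns / rate_den,                       # run/zone percentage
    sum((g - mu_g)^2 * pg),              # gray-level variance
    sum((r - mu_r)^2 * pr)               # run-length/zone-size variance
  )
  names(vals) <- c(prefix_small[1], prefix_large[1], "LG", "HG",
                   "SL", "SH", "LL", "LH", "GLN", "N2", "PCT", "GLV", "SV")
  vals
}

#' GLRLM features
#'
#' The 13 run-length features. Run Percentage uses the merged-direction
#' convention `RP = n_runs / (n_voxels * 13)`.
#'
#' @param M run-length count matrix from [build_glrlm()].
#' @param n_voxels number of in-mask voxels.
#' @return tibble `feature`, `value`, `defined`.
#' @export
features_glrlm <- function(M, n_voxels) {
  v <- rlsz_features(M, n_voxels, n_voxels * 13, "SRE", "LRE")
  vals <- c(GLN = v[["GLN"]], GLV = v[["GLV"]], HGRE = v[["HG"]],
            LRE = v[["LRE"]], LRHGE = v[["LH"]], LRLGE = v[["LL"]],
            LGRE = v[["LG"]], RLV = v[["SV"]], RP = v[["PCT"]],
            RLN = v[["N2"]], SRE = v[["SRE"]], SRHGE = v[["SH"]],
            SRLGE = v[["SL"]])
  tibble::tibble(feature = paste0("GLRLM_", names(vals)),
                 value = unname(vals), defined = is.finite(unname(vals)))
}

#' GLSZM features
#'
#' The 13 size-zone features. Zone Percentage is
#' `ZP = n_zones / n_voxels`.
#'
#' @param M size-zone count matrix from [build_glszm()].
#' @param n_voxels number of in-mask voxels.
#' @return tibble `feature`, `value`, `defined`.
#' @export
features_glszm <- function(M, n_voxels) {
  v <- rlsz_features(M, n_voxels, n_voxels, "SZE", "LZE")
  vals <- c(GLN = v[["GLN"]], GLV = v[["GLV"]], HGZE = v[["HG"]],
            LZE = v[["LZE"]], LZHGE = v[["LH"]], LZLGE = v[["LL"]],
            LGZE = v[["LG"]], SZE = v[["SZE"]], SZHGE = v[["SH"]],
            SZLGE = v[["SL"]], ZP = v[["PCT"]], ZSN = v[["N2"]],
            ZSV = v[["SV"]])
  tibble::tibble(feature = paste0("GLSZM_", names(vals)),
                 value = unname(vals), defined = is.finite(unname(vals)))
}

#' Neighborhood gray-tone difference parts
#'
#' For every in-mask voxel with at least one in-mask 26-neighbor,
#' accumulates the absolute difference between its level and the mean
#' level of its in-mask neighborhood. Voxels with no in-mask neighbor
#' are excluded from the counts.
#'
#' @param q a `quantized_roi`.
#' @return list with `s` (per-level summed absolute difference), `N`
#'   (per-level voxel count), `p` (`N / sum(N)`), and `levels`.
#' @export
build_ngtdm <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  parts <- cpp_ngtdm(levels_vector(q), dim(q$levels), n_levels(q))
  n <- sum(parts$N)
  list(s = parts$s, N = parts$N, p = parts$N / n,
       levels = seq_len(n_levels(q)))
}

#' NGTDM features
#'
#' Busyness, Coarseness, Complexity, Contrast and Strength following
#' Amadasun and King, with a stabilizer `eps` in the Coarseness and
#' Strength denominators. A flat ROI yields Contrast 0 and Coarseness
#' `1/eps` (capped sentinel).
#'
#' @param parts output of [build_ngtdm()].
#' @param eps stabilizer (default 1e-6).
#' @return tibble `feature`, `value`, `defined`.
#' @export
features_ngtdm <- function(parts, eps = 1e-6) {
  occ <- parts$N > 0
  i <- parts$levels[occ]
  p <- parts$p[occ]
  s <- parts$s[occ]
  n <- sum(parts$N)
  ngp <- sum(occ)
  ps <- sum(p * s)
  coarseness <- 1 / (eps + ps)
  if (ngp >= 2) {
    D2 <- outer(i, i, `-`)^2
    PP <- outer(p, p)
    contrast <- sum(PP * D2) / (ngp * (ngp - 1)) * sum(s) / n
    busy_den <- sum(abs(outer(i * p, i * p, `-`)))
    busyness <- if (busy_den > 0) ps / busy_den else 0
    Psum <- outer(p, p, `+`)
    PSsum <- outer(p * s, p * s, `+`)
    complexity <- sum(abs(outer(i, i, `-`)) * PSsum / Psum) / n
    strength <- sum(Psum * D2) / (eps + sum(s))
  } else {
    contrast <- 0
    busyness <- 0
    complexity <- 0
    strength <- 0
  }
  vals <- c(Busyness = busyness, Coarseness = coarseness,
            Complexity = complexity, Contrast = contrast,
            Strength = strength)
  tibble::tibble(feature = paste0("NGTDM_", names(vals)),
                 value = unname(vals), defined = is.finite(unname(vals)))
}

#' First-order intensity statistics
#'
#' Population moments of the raw (unquantized, re-segmented) in-ROI
#' intensities: Variance, Skewness and raw (non-excess) Kurtosis.
#' Skewness and Kurtosis are flagged undefined when the variance is 0.
#'
#' @param x numeric vector of in-ROI intensities (length >= 2).
#' @return tibble `feature`, `value`, `defined`.
#' @export
features_intensity <- function(x) {
  if (length(x) < 2) stop("need at least 2 voxels", call. = FALSE)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 > 0) {
    skew <- mean((x - mu)^3) / m2^1.5
    kurt <- mean((x - mu)^4) / m2^2
  } else {
    skew <- NA_real_
    kurt <- NA_real_
  }
  vals <- c(Kurtosis = kurt, Skewness = skew, Variance = m2)
  tibble::tibble(feature = paste0("IS_", names(vals)), value = unname(vals),
                 defined = is.finite(unname(vals)))
}

#' Volume normalization of volume-dependent features
#'
#' Applies the four normalization types to the seven volume-dependent
#' features: Type 1 divides by the ROI volume (GLRLM GLN and RLN, GLSZM
#' GLN and ZSN), Type 2 multiplies by it (NGTDM Strength), and Types 3
#' and 4 recompute Busyness and Coarseness from the gray-tone difference
#' parts with the per-level normalizer `p_i * s(i) / N(i) = s(i) / n`:
#' \deqn{Busyness_{VN} = \frac{\sum_i p_i s(i)/N(i)}
#'   {\sum_i \sum_j |i p_i - j p_j|}, \quad
#'   Coarseness_{VN} = \left[\epsilon + \sum_i p_i s(i)/N(i)\right]^{-1}.}
#'
#' @param features tibble from the `features_*` functions (must contain
#'   the seven volume-normalized features).
#' @param ngtdm_parts output of [build_ngtdm()].
#' @param V ROI volume (mm^3; equal to the voxel count on the package's
#'   default 1 mm isotropic grid).
#' @param eps stabilizer for Type 4 (default 1e-6).
#' @return the input tibble with a `value_raw` column added and `value`
#'   replaced by the normalized value for the seven features; a zero
#'   Type-3 denominator flags Busyness undefined.
#' @export
apply_volume_normalization <- function(features, ngtdm_parts, V,
                                       eps = 1e-6) {
  if (!is.numeric(V) || V <= 0) stop("`V` must be positive", call. = FALSE)
  reg <- feature_registry()
  features <- dplyr::left_join(features,
                               dplyr::select(reg, "feature", "vn_type"),
                               by = "feature")
  features$vn_type[is.na(features$vn_type)] <- "none"
  features$value_raw <- features$value

  occ <- ngtdm_parts$N > 0
  i <- ngtdm_parts$levels[occ]
  p <- ngtdm_parts$p[occ]
  s <- ngtdm_parts$s[occ]
  Ni <- ngtdm_parts$N[occ]
  num <- sum(p * s / Ni)
  den3 <- sum(abs(outer(i * p, i * p, `-`)))

  out <- features
  for (k in seq_len(nrow(out))) {
    vt <- out$vn_type[k]
    if (vt == "none") next
    raw <- out$value_raw[k]
    out$value[k] <- switch(vt,
      "1" = raw / V,
      "2" = raw * V,
      "3" = if (den3 > 0) num / den3 else NA_real_,
      "4" = 1 / (eps + num)
    )
  }
  out$defined <- is.finite(out$value)
  dplyr::select(out, -"vn_type")
}

#' Extract the full 42-feature vector from a quantized ROI
#'
#' Computes all five feature families on the quantized levels, the
#' first-order statistics on the raw re-segmented intensities, the ROI
#' volume, and applies volume normalization to the seven
#' volume-dependent features. Family-level failures (e.g. a single-voxel
#' ROI, where no co-occurrence pairs exist) propagate as flagged
#' undefined values for that family only.
#'
#' @param q a `quantized_roi` from [lloyd_quantize()].
#' @param raw_vol the [image_volume()] holding raw intensities on the
#'   same grid as `q` (used for the IS features).
#' @param eps NGTDM stabilizer (default 1e-6).
#' @return tibble with one row per registry feature plus `volume_mm3`
#'   (43 rows): columns `feature`, `family`, `ibsi_code`, `vn_type`,
#'   `value`, `value_raw`, `defined`.
#' @export
extract_features <- function(q, raw_vol, eps = 1e-6) {
  stopifnot(inherits(q, "quantized_roi"), inherits(raw_vol, "image_volume"))
  if (!identical(dim(q$levels), dim(raw_vol$values)))
    stop("quantized ROI and raw volume grids differ", call. = FALSE)
  n_vox <- sum(q$mask$inside)
  spacing <- raw_vol$spacing_mm
  vol_mm3 <- n_vox * prod(spacing)

  na_family <- function(fam) {
    reg <- feature_registry()
    nm <- reg$feature[reg$family == fam]
    tibble::tibble(feature = nm, value = NA_real_, defined = FALSE)
  }
  glcm <- tryCatch(features_glcm(build_glcm(q)),
                   error = function(e) na_family("GLCM"))
  glrlm <- features_glrlm(build_glrlm(q), n_vox)
  glszm <- features_glszm(build_glszm(q), n_vox)
  parts <- build_ngtdm(q)
  ngtdm <- features_ngtdm(parts, eps = eps)
  is_feat <- tryCatch(features_intensity(raw_vol$values[q$mask$inside]),
                      error = function(e) na_family("IS"))

  feats <- dplyr::bind_rows(glcm, glrlm, is_feat, ngtdm, glszm)
  feats <- apply_volume_normalization(feats, parts, vol_mm3, eps = eps)
  reg <- feature_registry()
  feats <- dplyr::left_join(
    feats, dplyr::select(reg, "feature", "family", "ibsi_code", "vn_type"),
    by = "feature")
  feats <- dplyr::bind_rows(
    feats,
    tibble::tibble(feature = "volume_mm3", family = "Geometry",
                   ibsi_code = NA_character_, vn_type = "none",
                   value = vol_mm3, value_raw = vol_mm3, defined = TRUE))
  dplyr::select(feats, "feature", "family", "ibsi_code", "vn_type",
                "value", "value_raw", "defined")
}
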