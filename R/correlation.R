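## Cross-modality correlation analysis of radiomic features.
##
## Every (modality, feature) column is treated as one variable measured
## across patients; the analysis reports absolute Spearman correlations
## over the upper triangle of the full pairwise matrix, adjusts p-values
## once with Benjamini-Hochberg over that pooled family, and labels each
## pair as intramodality, intermodality/same-feature or
## intermodality/cross-feature. Features too strongly tied to ROI volume
## (|rho| with same-modality volume above a threshold) are removed first
## so volume does not masquerade as texture agreement.

#' Absolute Spearman correlation with t-approximation p-value
#'
#' Average-rank Spearman correlation on pairwise-complete observations,
#' with the two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of
#' freedom (computed on the signed coefficient); the absolute value of
#' the coefficient is returned, since strong negative association is as
#' meaningful as positive here.
#'
#' @param x,y numeric vectors of equal length; `NA`s are dropped
#'   pairwise.
#' @return one-row tibble: `abs_rho`, `rho`, `p`, `n` (complete pairs),
#'   `defined` (`FALSE` when fewer than 3 complete pairs or a vector has
#'   zero rank variance).
#' @examples
#' spearman_abs(1:5, c(1, 2, 3, 5, 4))
#' @export
spearman_abs <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  undef <- tibble::tibble(abs_rho = NA_real_, rho = NA_real_, p = NA_real_,
                          n = n, defined = FALSE)
  if (n < 3) return(undef)
  rx <- rank(x[ok])
  ry <- rank(y[ok])
  if (var(rx) == 0 || var(ry) == 0) return(undef)
  rho <- cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tval), df = n - 2)
  }
  tibble::tibble(abs_rho = abs(rho), rho = rho, p = p, n = n, defined = TRUE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1) with significance
#' flags at `alpha`.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @param alpha significance level for the flags (default 0.05).
#' @return tibble with `p_raw`, `p_adj`, `significant`.
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  if (length(p) == 0)
    return(tibble::tibble(p_raw = numeric(0), p_adj = numeric(0),
                          significant = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p_adj <- p.adjust(p, method = "BH")
  tibble::tibble(p_raw = p, p_adj = p_adj,
                 significant = !is.na(p_adj) & p_adj < alpha)
}

#' Wide patient-by-column feature matrix
#'
#' Pivot of a tidy feature table to one row per patient and one column
#' per `(modality, feature)` pair, named `modality.feature`.
#'
#' @param features tidy tibble with columns `patient_id`, `modality`,
#'   `feature`, `value`.
#' @return tibble with `patient_id` plus one column per pair.
#' @export
feature_matrix <- function(features) {
  features |>
    dplyr::mutate(column = paste(.data$modality, .data$feature, sep = ".")) |>
    dplyr::select("patient_id", "column", "value") |>
    tidyr::pivot_wider(names_from = "column", values_from = "value") |>
    dplyr::arrange(.data$patient_id)
}

#' Filter features confounded by ROI volume
#'
#' Computes `R_V`, the absolute Spearman correlation across patients
#' between each `(modality, feature)` column and the same modality's ROI
#' volume, and removes columns with `R_V` above the threshold. The
#' volume feature itself is kept for reporting but never enters the
#' pairwise analysis.
#'
#' @param features tidy feature table (`patient_id`, `modality`,
#'   `feature`, `value`) including a `volume_mm3` feature per modality.
#' @param threshold drop threshold on `R_V` (default 0.75).
#' @param volume_feature name of the volume feature (default
#'   `"volume_mm3"`).
#' @return list with `features` (filtered tidy table), `volume_corr`
#'   (tibble `modality`, `feature`, `r_v`, `p`, `dropped`) and `dropped`
#'   (tibble of removed columns).
#' @export
volume_filter <- function(features, threshold = 0.75,
                          volume_feature = "volume_mm3") {
  vols <- features |>
    dplyr::filter(.data$feature == volume_feature) |>
    dplyr::select("patient_id", "modality", volume = "value")
  if (nrow(vols) == 0)
    stop("no `", volume_feature, "` rows found", call. = FALSE)
  feat <- dplyr::filter(features, .data$feature != volume_feature)
  volume_corr <- feat |>
    dplyr::inner_join(vols, by = c("patient_id", "modality")) |>
    dplyr::group_by(.data$modality, .data$feature) |>
    dplyr::summarise(res = list(spearman_abs(.data$value, .data$volume)),
                     .groups = "drop") |>
    tidyr::unnest("res") |>
    dplyr::transmute(.data$modality, .data$feature, r_v = .data$abs_rho,
                     p = .data$p,
                     dropped = .data$defined & .data$abs_rho > threshold)
  dropped <- dplyr::filter(volume_corr, .data$dropped)
  kept <- dplyr::anti_join(feat, dropped, by = c("modality", "feature"))
  list(features = dplyr::bind_rows(kept,
                                   dplyr::filter(features,
                                                 .data$feature ==
                                                   volume_feature)),
       volume_corr = volume_corr,
       dropped = dropped)
}

#' Build the cross-modality correlation report
#'
#' Applies the volume filter, forms the wide patient-by-column matrix,
#' computes the absolute Spearman correlation and raw p for every
#' unordered column pair (upper triangle, diagonal excluded), adjusts
#' the pooled p-vector once with Benjamini-Hochberg, and labels each
#' pair: same modality -> `"intramodality"`; different modality, same
#' feature -> `"intermodality_same_rf"`; otherwise
#' `"intermodality_cross_rf"`. Pairs undefined after pairwise-complete
#' handling (fewer than 3 complete pairs or zero rank variance) are
#' excluded from the BH family and reported separately.
#'
#' @param features tidy feature table (`patient_id`, `modality`,
#'   `feature`, `value`), including per-modality `volume_mm3` rows.
#' @param alpha significance level on adjusted p (default 0.05).
#' @param volume_threshold volume-filter threshold on `R_V` (default
#'   0.75); `NULL` skips the filter.
#' @return object of class `radcorr_report`: list with `pairs` (tibble
#'   `col_a`, `col_b`, `modality_a`, `modality_b`, `feature_a`,
#'   `feature_b`, `class`, `abs_rho`, `rho`, `p_raw`, `p_adj`,
#'   `significant`, `n`), `undefined_pairs`, `volume_corr`, `dropped`,
#'   `alpha`, `n_patients`, `n_columns`.
#' @export
correlation_report <- function(features, alpha = 0.05,
                               volume_threshold = 0.75) {
  if (!is.null(volume_threshold)) {
    vf <- volume_filter(features, threshold = volume_threshold)
    features_kept <- vf$features
    volume_corr <- vf$volume_corr
    dropped <- vf$dropped
  } else {
    features_kept <- features
    volume_corr <- tibble::tibble()
    dropped <- tibble::tibble()
  }
  feat <- dplyr::filter(features_kept, .data$feature != "volume_mm3")
  wide <- feature_matrix(feat)
  cols <- setdiff(names(wide), "patient_id")
  k <- length(cols)
  if (k < 2) stop("need at least two feature columns", call. = FALSE)
  meta <- tibble::tibble(
    column = cols,
    modality = sub("\\..*$", "", cols),
    feature = sub("^[^.]*\\.", "", cols)
  )
  X <- as.matrix(wide[cols])
  n_pat <- nrow(X)

  ia <- rep(seq_len(k - 1), times = (k - 1):1)
  ib <- unlist(lapply(2:k, function(j) j:k))
  # fast path: no missing values -> rank once, one correlation matrix
  if (!anyNA(X)) {
    R <- apply(X, 2, rank)
    sds <- apply(R, 2, sd)
    C <- suppressWarnings(cor(R))
    rho <- C[cbind(ia, ib)]
    rho[sds[ia] == 0 | sds[ib] == 0] <- NA_real_
    nn <- rep(n_pat, length(rho))
  } else {
    res <- mapply(function(a, b) {
      s <- spearman_abs(X[, a], X[, b])
      c(if (s$defined) s$rho else NA_real_, s$n)
    }, ia, ib)
    rho <- res[1, ]
    nn <- res[2, ]
  }
  defined <- is.finite(rho) & nn >= 3
  praw <- rep(NA_real_, length(rho))
  idx <- which(defined)
  if (length(idx)) {
    r <- rho[idx]
    nv <- nn[idx]
    p <- ifelse(abs(r) >= 1, 0,
                2 * pt(-abs(r * sqrt((nv - 2) / pmax(1 - r^2, 1e-300))),
                       df = nv - 2))
    praw[idx] <- p
  }
  pairs <- tibble::tibble(
    col_a = cols[ia], col_b = cols[ib],
    modality_a = meta$modality[ia], modality_b = meta$modality[ib],
    feature_a = meta$feature[ia], feature_b = meta$feature[ib],
    abs_rho = abs(rho), rho = rho, p_raw = praw, n = as.integer(nn)
  ) |>
    dplyr::mutate(class = dplyr::case_when(
      .data$modality_a == .data$modality_b ~ "intramodality",
      .data$feature_a == .data$feature_b ~ "intermodality_same_rf",
      TRUE ~ "intermodality_cross_rf"
    ))
  undefined_pairs <- dplyr::filter(pairs, !is.finite(.data$abs_rho))
  pairs <- dplyr::filter(pairs, is.finite(.data$abs_rho))
  adj <- bh_adjust(pairs$p_raw, alpha = alpha)
  pairs$p_adj <- adj$p_adj
  pairs$significant <- adj$significant
  structure(list(pairs = pairs, undefined_pairs = undefined_pairs,
                 volume_corr = volume_corr, dropped = dropped,
                 alpha = alpha, n_patients = n_pat, n_columns = k),
            class = "radcorr_report")
}

#' @export
print.radcorr_report <- function(x, ...) {
  cat(sprintf(paste0("<radcorr_report> %d patients, %d columns, %d pairs",
                     " (%d significant at adjusted p < %g)\n"),
              x$n_patients, x$n_columns, nrow(x$pairs),
              sum(x$pairs$significant), x$alpha))
  invisible(x)
}

#' Summarize a correlation report by comparison class
#'
#' For each comparison class and modality (or modality pair), tabulates
#' the significant pairs (adjusted p below the report's alpha): the
#' percentage of pairs significant, the percentage of significant pairs
#' with `|rho|` at or above each threshold, a fixed-width histogram of
#' significant `|rho|`, and the histogram mode bin centre.
#'
#' @param report a `radcorr_report`.
#' @param thresholds high-correlation thresholds (default
#'   `c(0.75, 0.85, 0.95)`).
#' @param bin_width histogram bin width on `[0, 1]` (default 0.05).
#' @return object of class `radcorr_summary`: list with `by_group`
#'   (tibble: `class`, `group`, `n_pairs`, `n_significant`,
#'   `pct_significant`, `pct_ge_<thr>` columns, `mode_bin_center`) and
#'   `histogram` (tibble: `class`, `group`, `bin_center`, `count`).
#' @export
summarize_correlations <- function(report, thresholds = c(0.75, 0.85, 0.95),
                                   bin_width = 0.05) {
  stopifnot(inherits(report, "radcorr_report"))
  pairs <- report$pairs |>
    dplyr::mutate(group = ifelse(
      .data$class == "intramodality", .data$modality_a,
      paste(pmin(.data$modality_a, .data$modality_b),
            pmax(.data$modality_a, .data$modality_b), sep = "-")))
  breaks <- seq(0, 1, by = bin_width)
  centers <- utils::head(breaks, -1) + bin_width / 2
  groups <- dplyr::distinct(pairs, .data$class, .data$group)
  by_group <- vector("list", nrow(groups))
  hists <- vector("list", nrow(groups))
  for (g in seq_len(nrow(groups))) {
    sub <- dplyr::filter(pairs, .data$class == groups$class[g],
                         .data$group == groups$group[g])
    sig <- dplyr::filter(sub, .data$significant)
    cnt <- if (nrow(sig)) {
      as.vector(table(cut(pmin(sig$abs_rho, 1), breaks = breaks,
                          include.lowest = TRUE)))
    } else rep(0L, length(centers))
    row <- tibble::tibble(
      class = groups$class[g], group = groups$group[g],
      n_pairs = nrow(sub), n_significant = nrow(sig),
      pct_significant = 100 * nrow(sig) / max(nrow(sub), 1))
    for (thr in thresholds) {
      row[[sprintf("pct_ge_%g", thr)]] <-
        if (nrow(sig)) 100 * mean(sig$abs_rho >= thr) else NA_real_
    }
    row$mode_bin_center <- if (nrow(sig)) centers[which.max(cnt)] else NA_real_
    by_group[[g]] <- row
    hists[[g]] <- tibble::tibble(class = groups$class[g],
                                 group = groups$group[g],
                                 bin_center = centers, count = cnt)
  }
  structure(list(by_group = dplyr::bind_rows(by_group),
                 histogram = dplyr::bind_rows(hists),
                 alpha = report$alpha, thresholds = thresholds,
                 bin_width = bin_width),
            class = "radcorr_summary")
}

#' @export
print.radcorr_summary <- function(x, ...) {
  cat("<radcorr_summary>\n")
  print(x$by_group)
  invisible(x)
}

#' Paired comparison of features with and without artifact masking
#'
#' For each feature, a two-sided paired t-test across patients between
#' the masked and unmasked extraction, plus the Spearman correlation
#' between the two conditions. Zero-variance differences are flagged:
#' an all-zero difference reports `t = 0`, `p = 1`; a constant non-zero
#' shift reports `t = +/-Inf`, `p = 0`.
#'
#' @param fv_masked,fv_unmasked tidy feature tables (`patient_id`,
#'   `feature`, `value`) over the same patients and features.
#' @return tibble with `feature`, `family`, `spearman_r`, `t`, `p`,
#'   `n`, `zero_variance`.
#' @export
paired_feature_ttest <- function(fv_masked, fv_unmasked) {
  joined <- dplyr::inner_join(
    dplyr::select(fv_masked, "patient_id", "feature", masked = "value"),
    dplyr::select(fv_unmasked, "patient_id", "feature",
                  unmasked = "value"),
    by = c("patient_id", "feature"))
  if (nrow(joined) == 0) stop("tables share no (patient, feature) rows",
                              call. = FALSE)
  reg <- feature_registry()
  joined |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(res = list({
      ok <- is.finite(.data$masked) & is.finite(.data$unmasked)
      a <- .data$masked[ok]; b <- .data$unmasked[ok]
      d <- a - b
      r <- spearman_abs(a, b)$rho
      tol <- 1e-12 * max(1, abs(a), abs(b))
      if (length(d) < 2 || sd(d) <= tol) {
        md <- if (length(d)) mean(d) else 0
        tibble::tibble(spearman_r = r,
                       t = if (abs(md) > tol) sign(md) * Inf else 0,
                       p = if (abs(md) > tol) 0 else 1,
                       n = length(d), zero_variance = TRUE)
      } else {
        tt <- t.test(a, b, paired = TRUE)
        tibble::tibble(spearman_r = r, t = unname(tt$statistic),
                       p = tt$p.value, n = length(d),
                       zero_variance = FALSE)
      }
    }), .groups = "drop") |>
    tidyr::unnest("res") |>
    dplyr::left_join(dplyr::select(reg, "feature", "family"),
                     by = "feature") |>
    dplyr::mutate(family = ifelse(.data$feature == "volume_mm3", "Geometry",
                                  .data$family)) |>
    dplyr::select("feature", "family", "spearman_r", "t", "p", "n",
                  "zero_variance")
}
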