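## End-to-end driver: simulate -> preprocess -> artifact mask ->
## extract -> correlate -> power, with file-based stage outputs so each
## stage is independently inspectable and a rerun with the same config
## reproduces every CSV bit-identically.

#' Pipeline configuration
#'
#' Bundles the cohort spec and the analysis settings. Defaults are the
#' package's standard analysis settings: 64 gray levels, 1 mm isotropic
#' analysis grid, 5 mm artifact radius, alpha 0.05 on adjusted p-values
#' and a 0.75 volume-correlation filter.
#'
#' @param cohort a [cohort_spec()].
#' @param bins gray levels for quantization (default 64).
#' @param target_mm isotropic analysis spacing in mm (default 1).
#' @param artifact_radius_mm fiducial-mask disk radius (default 5).
#' @param alpha significance level on adjusted p (default 0.05).
#' @param volume_threshold volume-filter threshold (default 0.75).
#' @param seed overrides `cohort$seed` when non-`NULL`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), bins = 64,
                            target_mm = 1, artifact_radius_mm = 5,
                            alpha = 0.05, volume_threshold = 0.75,
                            seed = NULL) {
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, bins = bins, target_mm = target_mm,
                 artifact_radius_mm = artifact_radius_mm, alpha = alpha,
                 volume_threshold = volume_threshold),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the
#' `cohort` key mirrors [cohort_spec()].
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  ca <- raw$cohort %||% list()
  cohort <- do.call(cohort_spec, ca)
  pipeline_config(cohort = cohort,
                  bins = raw$bins %||% 64,
                  target_mm = raw$target_mm %||% 1,
                  artifact_radius_mm = raw$artifact_radius_mm %||% 5,
                  alpha = raw$alpha %||% 0.05,
                  volume_threshold = raw$volume_threshold %||% 0.75,
                  seed = raw$seed)
}

#' Run the full analysis pipeline
#'
#' Generates the cohort, writes per-patient NIfTI volumes/masks and
#' fiducial JSON plus a manifest, extracts features (with artifact
#' masking on the X-ray-like modalities), builds the correlation report
#' and class summaries, computes the correlation power at the cohort
#' size, and writes every stage output under `out_dir` together with a
#' provenance record. Re-running with an identical config reproduces
#' all CSV outputs bit-identically.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param write_volumes write per-patient NIfTI files (default TRUE;
#'   disable to keep runs lightweight when only tables are needed).
#' @return (invisibly) list with `features`, `log`, `report`, `summary`,
#'   `power`, and `paths` of the written files.
#' @export
run_pipeline <- function(config, out_dir, write_volumes = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  cohort <- generate_cohort(config$cohort)

  if (write_volumes) {
    img_dir <- file.path(out_dir, "cohort")
    dir.create(img_dir, showWarnings = FALSE)
    manifest <- list()
    for (pat in cohort) {
      for (m in names(pat$volumes)) {
        f <- file.path(img_dir, sprintf("%s_%s.nii.gz", pat$id, m))
        write_volume_nifti(pat$volumes[[m]], f)
        manifest[[length(manifest) + 1]] <-
          tibble::tibble(patient_id = pat$id, modality = m, path = f)
      }
      write_volume_nifti(pat$mask,
                         file.path(img_dir, sprintf("%s_mask.nii.gz",
                                                    pat$id)),
                         spacing_mm = config$cohort$spacing_mm)
      write_fiducials_json(pat$fiducials,
                           file.path(img_dir,
                                     sprintf("%s_fiducials.json", pat$id)))
    }
    paths$manifest <- file.path(out_dir, "manifest.csv")
    readr::write_csv(dplyr::bind_rows(manifest), paths$manifest)
  }

  ext <- extract_cohort_features(cohort, bins = config$bins,
                                 target_mm = config$target_mm,
                                 artifact_radius_mm =
                                   config$artifact_radius_mm)
  paths$features <- file.path(out_dir, "features.csv")
  readr::write_csv(ext$features, paths$features)
  paths$preprocess_log <- file.path(out_dir, "preprocess_log.csv")
  readr::write_csv(ext$log, paths$preprocess_log)

  report <- correlation_report(ext$features, alpha = config$alpha,
                               volume_threshold = config$volume_threshold)
  paths$pairs <- file.path(out_dir, "pairs.csv")
  readr::write_csv(report$pairs, paths$pairs)
  paths$volume_corr <- file.path(out_dir, "volume_corr.csv")
  readr::write_csv(report$volume_corr, paths$volume_corr)

  summ <- summarize_correlations(report)
  paths$summary <- file.path(out_dir, "summary.json")
  jsonlite::write_json(list(by_group = summ$by_group,
                            histogram = summ$histogram,
                            alpha = summ$alpha),
                       paths$summary, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  n_pairs <- nrow(report$pairs)
  pow <- list(
    n = config$cohort$n_patients,
    alpha_bonferroni = bonferroni_alpha(config$alpha, max(n_pairs, 1)),
    power_large_effect = power_correlation(config$cohort$n_patients, 0.75,
                                           bonferroni_alpha(config$alpha,
                                                            max(n_pairs, 1)),
                                           tails = 2),
    power_small_effect = power_correlation(config$cohort$n_patients, 0.3,
                                           bonferroni_alpha(config$alpha,
                                                            max(n_pairs, 1)),
                                           tails = 2))
  paths$power <- file.path(out_dir, "power.json")
  jsonlite::write_json(pow, paths$power, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  cfg_json <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE,
                               digits = NA, pretty = TRUE)
  cfg_file <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_file)
  prov <- list(package = "radcorr",
               version = as.character(utils::packageVersion("radcorr")),
               seed = config$cohort$seed,
               config_md5 = unname(tools::md5sum(cfg_file)))
  paths$provenance <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(features = ext$features, log = ext$log, report = report,
                 summary = summ, power = pow, paths = paths))
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}
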