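## Synthetic phantom cohorts.
##
## Each patient owns a smooth latent Gaussian field S shared by all
## modalities plus an independent field H_m per modality; the modality
## image is transform_m(sqrt(w) S + sqrt(1 - w) H_m) + noise, so the
## `shared_weight` w is the fraction of latent texture variance the
## modalities have in common. The ROI is a patient-specific ellipsoid
## with lognormal semi-axes; CT-like and CBCT-like volumes additionally
## carry in-plane streak artifacts radiating from implanted fiducial
## seeds.

#' Specification of a synthetic phantom cohort
#'
#' Collects every knob of the generator. Defaults describe a cohort of
#' 47 patients on a 64 mm cube at 1 mm isotropic spacing, prostate-like
#' ellipsoidal ROIs of roughly 17 mL median volume, three imaging
#' modalities (a T2-weighted-MRI-like, a CT-like and a CBCT-like
#' channel) sharing half of their latent texture variance, and three
#' gold-fiducial seeds whose streaks contaminate the two X-ray-like
#' channels.
#'
#' @param n_patients cohort size (default 47).
#' @param grid_shape voxel grid triple (default `c(64, 64, 64)`).
#' @param spacing_mm voxel spacing triple in mm (default 1 mm isotropic;
#'   `c(0.7, 0.7, 2.8)` reproduces a typical anisotropic T2w grid).
#' @param correlation_length_mm Gaussian smoothing length of the latent
#'   fields, in mm (default 4).
#' @param shared_weight fraction of latent texture variance shared across
#'   modalities, in `[0, 1]` (default 0.5).
#' @param modality_params named list (one entry per modality) of lists
#'   with `transform` (`"identity"`, `"negate"` or `"gamma"`), `gamma`
#'   (exponent for the gamma curve), `gain`, `offset` and `noise_sd`.
#' @param roi_radii_mm list with `meanlog` (length-3) and `sdlog`
#'   (scalar) of the lognormal semi-axis distribution, in mm.
#' @param volume_coupling strength in `[0, 1]` of the coupling between
#'   ROI volume and the patient's mean-intensity texture parameter
#'   (default 0, no coupling).
#' @param n_fiducials fiducial seeds per patient (default 3).
#' @param streak_params list with `n_streaks` per fiducial, `length_mm`,
#'   `amplitude` (in units of the unit-variance latent field) and
#'   `n_slices` (axial extent of each fiducial's artifact).
#' @param seed integer RNG seed; identical specs (including seed) give
#'   bit-identical cohorts.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 47,
                        grid_shape = c(64, 64, 64),
                        spacing_mm = c(1, 1, 1),
                        correlation_length_mm = 4,
                        shared_weight = 0.5,
                        modality_params = list(
                          T2w = list(transform = "gamma", gamma = 0.8,
                                     gain = 100, offset = 300,
                                     noise_sd = 0.05),
                          CT = list(transform = "negate", gamma = 1,
                                    gain = 30, offset = 40,
                                    noise_sd = 0.05),
                          CBCT = list(transform = "negate", gamma = 1,
                                      gain = 30, offset = 35,
                                      noise_sd = 0.1)
                        ),
                        roi_radii_mm = list(meanlog = log(c(18, 14, 16)),
                                            sdlog = 0.15),
                        volume_coupling = 0,
                        n_fiducials = 3,
                        streak_params = list(n_streaks = 6, length_mm = 12,
                                             amplitude = 8, n_slices = 3),
                        seed = 1L) {
  spec <- list(n_patients = as.integer(n_patients),
               grid_shape = as.integer(grid_shape),
               spacing_mm = as.numeric(spacing_mm),
               correlation_length_mm = correlation_length_mm,
               shared_weight = shared_weight,
               modality_params = modality_params,
               roi_radii_mm = roi_radii_mm,
               volume_coupling = volume_coupling,
               n_fiducials = as.integer(n_fiducials),
               streak_params = streak_params,
               seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  if (spec$n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (length(spec$grid_shape) != 3 || any(spec$grid_shape < 2))
    stop("grid_shape must be a triple of at least 2", call. = FALSE)
  if (length(spec$spacing_mm) != 3 || any(spec$spacing_mm <= 0))
    stop("spacing_mm must be a positive triple", call. = FALSE)
  if (spec$correlation_length_mm <= 0)
    stop("correlation_length_mm must be positive", call. = FALSE)
  if (spec$shared_weight < 0 || spec$shared_weight > 1)
    stop("shared_weight must lie in [0, 1]", call. = FALSE)
  if (spec$volume_coupling < 0 || spec$volume_coupling > 1)
    stop("volume_coupling must lie in [0, 1]", call. = FALSE)
  if (any(vapply(spec$modality_params, function(m) m$noise_sd < 0, TRUE)))
    stop("noise_sd must be non-negative", call. = FALSE)
  if (spec$roi_radii_mm$sdlog < 0)
    stop("roi sdlog must be non-negative", call. = FALSE)
  invisible(spec)
}

# Smooth white noise with a separable Gaussian kernel (sd in voxels per
# axis) and standardize to approximately unit variance.
gaussian_band_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  half <- max(1L, as.integer(ceiling(3 * sigma_vox)))
  offs <- -half:half
  k <- exp(-offs^2 / (2 * sigma_vox^2))
  W <- matrix(0, n, n)
  for (o in offs) {
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1 & j <= n
    W[cbind(i[ok], j[ok])] <- W[cbind(i[ok], j[ok])] +
      k[o + half + 1]
  }
  W / rowSums(W)
}

latent_field <- function(grid_shape, spacing_mm, correlation_length_mm) {
  a <- array(rnorm(prod(grid_shape)), grid_shape)
  for (d in 1:3) {
    sigma_vox <- correlation_length_mm / spacing_mm[d] / 2
    a <- apply_along(a, gaussian_band_matrix(grid_shape[d], sigma_vox), d)
  }
  sdev <- sd(as.vector(a))
  if (sdev > 0) a <- a / sdev
  a
}

apply_modality_transform <- function(x, params) {
  y <- switch(params$transform,
              identity = x,
              negate = -x,
              # gamma curve on a linear window of the unit-variance
              # field: x in [-4, 4] mapped to [0, 1], then ^gamma
              gamma = pmin(pmax((x + 4) / 8, 0), 1)^params$gamma,
              stop("unknown transform: ", params$transform, call. = FALSE))
  y * params$gain + params$offset
}

#' Inject in-plane streak artifacts around fiducial seeds
#'
#' Adds radial high/low-intensity line segments ("streaks") on the axial
#' slices around each fiducial centre, emulating the metal artifact of
#' implanted gold seeds on X-ray-based images. Streak directions are
#' drawn from the current RNG state; successive streaks alternate in
#' sign. The exact set of altered voxels is returned as ground truth.
#'
#' @param vol an [image_volume()].
#' @param mask an [roi_mask()] (streaks are drawn irrespective of the
#'   mask, as clinical streaks are; recall is assessed in-mask).
#' @param fiducials a [fiducial_annotation()] (only `centers` is used;
#'   artifact slices are derived from `n_slices`).
#' @param streak_params list with `n_streaks`, `length_mm`, `amplitude`
#'   and `n_slices` (see [cohort_spec()]). Zero amplitude (or zero
#'   fiducials) returns the input unchanged with an empty truth set.
#' @return list with `vol` (modified volume), `truth` (integer matrix of
#'   altered voxel coordinates, one row per voxel) and `artifact_slices`
#'   (per-fiducial slice index vectors).
#' @export
inject_fiducial_streaks <- function(vol, mask, fiducials, streak_params) {
  stopifnot(inherits(vol, "image_volume"),
            inherits(fiducials, "fiducial_annotation"))
  nf <- nrow(fiducials$centers)
  amp <- streak_params$amplitude
  if (nf == 0 || amp == 0) {
    return(list(vol = vol, truth = matrix(0L, 0, 3),
                artifact_slices = rep(list(integer(0)), nf)))
  }
  dm <- dim(vol$values)
  v <- vol$values
  spx <- vol$spacing_mm[1]; spy <- vol$spacing_mm[2]
  n_slices <- streak_params$n_slices %||% 3
  half <- (n_slices - 1) %/% 2
  altered <- array(FALSE, dm)
  art_slices <- vector("list", nf)
  for (f in seq_len(nf)) {
    ci <- fiducials$centers[f, 1]
    cj <- fiducials$centers[f, 2]
    ck <- fiducials$centers[f, 3]
    slices <- (ck - half):(ck + half)
    slices <- slices[slices >= 1 & slices <= dm[3]]
    art_slices[[f]] <- slices
    angles <- runif(streak_params$n_streaks, 0, 2 * pi)
    for (s in slices) {
      for (a in seq_along(angles)) {
        ei <- ci + round(streak_params$length_mm * cos(angles[a]) / spx)
        ej <- cj + round(streak_params$length_mm * sin(angles[a]) / spy)
        pts <- bresenham2d(ci, cj, ei, ej)
        ok <- pts[, 1] >= 1 & pts[, 1] <= dm[1] &
          pts[, 2] >= 1 & pts[, 2] <= dm[2]
        pts <- pts[ok, , drop = FALSE]
        if (!nrow(pts)) next
        sgn <- if (a %% 2 == 0) -1 else 1
        idx <- cbind(pts, s)
        v[idx] <- v[idx] + sgn * amp
        altered[idx] <- TRUE
      }
    }
  }
  truth <- which(altered, arr.ind = TRUE)
  colnames(truth) <- NULL
  list(vol = image_volume(v, vol$spacing_mm, vol$modality),
       truth = unname(truth), artifact_slices = art_slices)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic phantom cohort
#'
#' Draws `n_patients` phantoms per the spec. For each patient: lognormal
#' ellipsoid semi-axes define the ROI; a shared latent field plus
#' per-modality fields are mixed with weight `shared_weight`, passed
#' through the per-modality monotone intensity transform, shifted by the
#' volume-coupled intensity parameter, and degraded with Gaussian noise;
#' streaks are injected on the CT-like and CBCT-like channels only. A
#' per-patient seed sequence derived from `spec$seed` makes each patient
#' independently reproducible.
#'
#' @param spec a [cohort_spec()].
#' @return list of patients, each a list with `id`, `volumes` (named
#'   list of [image_volume()]), `mask`, `fiducials`
#'   ([fiducial_annotation()]), `streak_truth` (named per-modality list
#'   of altered-voxel matrices) and `truth` (latent parameters actually
#'   drawn: `volume_mm3`, `radii_mm`, `volume_z`, `coupled_shift`,
#'   per-modality `gain`).
#' @examples
#' coh <- generate_cohort(cohort_spec(n_patients = 2,
#'                                    grid_shape = c(24, 24, 24),
#'                                    roi_radii_mm = list(
#'                                      meanlog = log(c(8, 7, 7)),
#'                                      sdlog = 0.1)))
#' names(coh[[1]]$volumes)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  patient_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_patients)
  w <- spec$shared_weight
  modalities <- names(spec$modality_params)
  xray_like <- intersect(modalities, c("CT", "CBCT"))
  # analytic moments of log(ellipsoid volume) for the coupling z-score
  lv_mean <- log(4 * pi / 3) + sum(spec$roi_radii_mm$meanlog)
  lv_sd <- sqrt(3) * spec$roi_radii_mm$sdlog
  lapply(seq_len(spec$n_patients), function(p) {
    set.seed(patient_seeds[p])
    radii <- exp(rnorm(3, spec$roi_radii_mm$meanlog, spec$roi_radii_mm$sdlog))
    mask <- ellipsoid_mask(spec$grid_shape, spec$spacing_mm, radii)
    vol_mm3 <- 4 * pi / 3 * prod(radii)
    vz <- if (lv_sd > 0) (log(vol_mm3) - lv_mean) / lv_sd else 0
    shift <- spec$volume_coupling * vz
    S <- latent_field(spec$grid_shape, spec$spacing_mm,
                      spec$correlation_length_mm)
    fid <- draw_fiducials(spec, radii)
    volumes <- list()
    streak_truth <- list()
    art_slices <- rep(list(integer(0)), nrow(fid))
    for (m in modalities) {
      mp <- spec$modality_params[[m]]
      H <- latent_field(spec$grid_shape, spec$spacing_mm,
                        spec$correlation_length_mm)
      L <- sqrt(w) * S + sqrt(1 - w) * H + shift
      img <- apply_modality_transform(L, mp)
      if (mp$noise_sd > 0) {
        noise <- array(rnorm(length(img), 0, mp$noise_sd * abs(mp$gain)),
                       spec$grid_shape)
        img <- img + noise
      }
      vol <- image_volume(img, spec$spacing_mm, m)
      if (m %in% xray_like && nrow(fid) > 0) {
        sp <- spec$streak_params
        sp$amplitude <- sp$amplitude * abs(mp$gain)
        inj <- inject_fiducial_streaks(vol, mask,
                                       fiducial_annotation(fid,
                                         rep(list(1L), nrow(fid))),
                                       sp)
        vol <- inj$vol
        streak_truth[[m]] <- inj$truth
        art_slices <- mapply(function(a, b) sort(unique(c(a, b))),
                             art_slices, inj$artifact_slices,
                             SIMPLIFY = FALSE)
      } else {
        streak_truth[[m]] <- matrix(0L, 0, 3)
      }
      volumes[[m]] <- vol
    }
    if (nrow(fid) > 0 && all(lengths(art_slices) == 0))
      art_slices <- lapply(seq_len(nrow(fid)),
                           function(f) fid[f, 3, drop = TRUE])
    list(id = sprintf("P%03d", p),
         volumes = volumes,
         mask = mask,
         fiducials = fiducial_annotation(fid, art_slices),
         streak_truth = streak_truth,
         truth = list(volume_mm3 = vol_mm3, radii_mm = radii,
                      volume_z = vz, coupled_shift = shift,
                      gains = vapply(spec$modality_params,
                                     function(m) m$gain, 0)))
  })
}

# Fiducial centres drawn uniformly inside the middle half of the
# ellipsoid so they always fall well inside the mask.
draw_fiducials <- function(spec, radii) {
  nf <- spec$n_fiducials
  if (nf == 0) return(matrix(0L, 0, 3))
  center_vox <- (spec$grid_shape - 1) / 2 + 1
  out <- matrix(0L, nf, 3)
  for (f in seq_len(nf)) {
    u <- runif(3, -0.5, 0.5)
    out[f, ] <- as.integer(round(center_vox + u * radii / spec$spacing_mm))
  }
  out
}
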