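## Metal-fiducial streak-artifact masking.
##
## Streaks from implanted gold seeds radiate in-plane from the seed
## centre on X-ray-based images. The removal algorithm works per axial
## slice ("layer"): intensities on artifact-free layers define a
## mu +/- 3 sigma artifact threshold; on artifact layers the mask is the
## union of a 5 mm disk around the seed, every in-ROI pixel outside the
## threshold, and the discrete line from each such pixel back to the
## seed centre.

#' Fiducial annotation
#'
#' @param centers integer matrix with one row per fiducial and columns
#'   `(i, j, k)` giving 1-based voxel coordinates of the seed centre.
#' @param artifact_slices list (one element per fiducial) of integer
#'   vectors of axial slice indices (third array index) carrying that
#'   fiducial's artifact.
#' @return object of class `fiducial_annotation`.
#' @export
fiducial_annotation <- function(centers, artifact_slices) {
  centers <- matrix(as.integer(centers), ncol = 3)
  if (nrow(centers) > 0) {
    if (!is.list(artifact_slices) || length(artifact_slices) != nrow(centers))
      stop("`artifact_slices` must be a list with one element per fiducial",
           call. = FALSE)
    if (any(lengths(artifact_slices) == 0))
      stop("each fiducial needs at least one artifact slice", call. = FALSE)
  }
  structure(list(centers = centers,
                 artifact_slices = lapply(artifact_slices, as.integer)),
            class = "fiducial_annotation")
}

#' Artifact intensity threshold from artifact-free layers
#'
#' Computes the mean and (population) standard deviation of in-ROI voxel
#' intensities on axial slices that carry no fiducial artifact, and
#' returns the band `(mu - n_sigma * sigma, mu + n_sigma * sigma)`.
#' Pixels outside this band on artifact layers are treated as streak
#' artifact.
#'
#' @param vol an [image_volume()].
#' @param mask an [roi_mask()] on the same grid.
#' @param ann a [fiducial_annotation()].
#' @param n_sigma band half-width in standard deviations (default 3).
#' @return numeric `(low, high)`.
#' @export
artifact_threshold <- function(vol, mask, ann, n_sigma = 3) {
  stopifnot(inherits(ann, "fiducial_annotation"))
  check_same_grid(vol, mask)
  roi_slices <- which(apply(mask$inside, 3, any))
  art <- unique(unlist(ann$artifact_slices))
  clean <- setdiff(roi_slices, art)
  if (length(clean) == 0)
    stop("no artifact-free ROI slice available; supply a manual threshold",
         call. = FALSE)
  sel <- mask$inside
  sel[, , setdiff(seq_len(dim(sel)[3]), clean)] <- FALSE
  x <- vol$values[sel]
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  c(mu - n_sigma * sigma, mu + n_sigma * sigma)
}

# Discrete 2D line between pixel centres (Bresenham); returns matrix of
# (i, j) including both endpoints.
bresenham2d <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- -abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx + dy
  pts <- matrix(0L, dx - dy + 1L, 2)
  n <- 0L
  repeat {
    n <- n + 1L
    pts[n, ] <- c(x0, y0)
    if (x0 == x1 && y0 == y1) break
    e2 <- 2L * err
    if (e2 >= dy) { err <- err + dy; x0 <- x0 + sx }
    if (e2 <= dx) { err <- err + dx; y0 <- y0 + sy }
  }
  pts[seq_len(n), , drop = FALSE]
}

#' Build the streak-artifact removal mask
#'
#' For each fiducial and each of its artifact slices the masked set is
#' the union of (a) all in-ROI pixels whose centre lies within
#' `radius_mm` of the fiducial centre (in-plane Euclidean distance using
#' the in-plane spacing), (b) all in-ROI pixels on that slice whose value
#' falls outside `threshold`, and (c) for every pixel in (b), the in-ROI
#' pixels on the discrete (Bresenham) line segment from it to the
#' fiducial centre. The union over fiducials is returned.
#'
#' @param vol an [image_volume()].
#' @param mask an [roi_mask()].
#' @param ann a [fiducial_annotation()].
#' @param threshold numeric `(low, high)` from [artifact_threshold()].
#' @param radius_mm disk radius around the seed centre (default 5 mm).
#' @return object of class `artifact_mask`: list with `masked` (logical
#'   array, subset of the ROI), `components` (per-fiducial logical
#'   arrays), and `threshold`.
#' @export
build_artifact_mask <- function(vol, mask, ann, threshold, radius_mm = 5) {
  stopifnot(inherits(ann, "fiducial_annotation"))
  check_same_grid(vol, mask)
  if (length(threshold) != 2 || threshold[1] > threshold[2])
    stop("`threshold` must be (low, high)", call. = FALSE)
  dm <- dim(vol$values)
  spx <- vol$spacing_mm[1]; spy <- vol$spacing_mm[2]
  if (radius_mm < min(spx, spy))
    warning("radius smaller than one pixel; disk degenerates to the centre pixel")
  components <- vector("list", nrow(ann$centers))
  masked <- array(FALSE, dm)
  for (f in seq_len(nrow(ann$centers))) {
    comp <- array(FALSE, dm)
    ci <- ann$centers[f, 1]; cj <- ann$centers[f, 2]
    for (s in ann$artifact_slices[[f]]) {
      if (s < 1 || s > dm[3]) next
      roi2d <- mask$inside[, , s]
      if (!any(roi2d)) next
      # (a) disk around the centre
      di <- (seq_len(dm[1]) - ci) * spx
      dj <- (seq_len(dm[2]) - cj) * spy
      disk <- outer(di^2, dj^2, `+`) <= radius_mm^2
      sl <- disk & roi2d
      # (b) supra-threshold pixels
      v2d <- vol$values[, , s]
      out <- roi2d & (v2d < threshold[1] | v2d > threshold[2])
      sl <- sl | out
      # (c) lines from each distal artifact pixel to the centre
      if (any(out)) {
        idx <- which(out, arr.ind = TRUE)
        for (r in seq_len(nrow(idx))) {
          pts <- bresenham2d(idx[r, 1], idx[r, 2], ci, cj)
          keep <- pts[, 1] >= 1 & pts[, 1] <= dm[1] &
            pts[, 2] >= 1 & pts[, 2] <= dm[2]
          pts <- pts[keep, , drop = FALSE]
          on_roi <- roi2d[pts]
          pts <- pts[on_roi, , drop = FALSE]
          if (nrow(pts)) sl[pts] <- TRUE
        }
      }
      comp[, , s] <- comp[, , s] | sl
    }
    components[[f]] <- comp
    masked <- masked | comp
  }
  structure(list(masked = masked, components = components,
                 threshold = threshold),
            class = "artifact_mask")
}

#' Remove an artifact mask from the ROI
#'
#' @param mask an [roi_mask()].
#' @param am an `artifact_mask` from [build_artifact_mask()].
#' @return list with `mask` (reduced [roi_mask()]) and
#'   `reduction_fraction` (removed voxels / original voxels).
#' @export
apply_artifact_mask <- function(mask, am) {
  stopifnot(inherits(mask, "roi_mask"), inherits(am, "artifact_mask"))
  if (!identical(dim(mask$inside), dim(am$masked)))
    stop("mask shapes disagree", call. = FALSE)
  keep <- mask$inside & !am$masked
  n0 <- sum(mask$inside)
  if (!any(keep))
    stop("artifact mask removes the entire ROI", call. = FALSE)
  list(mask = roi_mask(keep), reduction_fraction = (n0 - sum(keep)) / n0)
}
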