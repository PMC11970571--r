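#' 3D image volume
#'
#' A minimal container for a scalar 3D image: a numeric array of voxel
#' values, the physical voxel spacing in millimetres, and a modality
#' label. Voxel centres sit on a regular grid; voxel `(i, j, k)` (1-based)
#' has physical coordinate `(i - 1, j - 1, k - 1) * spacing_mm`.
#'
#' @param values numeric 3D array of finite voxel values.
#' @param spacing_mm positive numeric of length 1 or 3; voxel spacing in mm.
#' @param modality character label (e.g. `"T2w"`, `"CT"`, `"CBCT"`).
#' @return An object of class `image_volume`: a list with elements
#'   `values`, `spacing_mm` and `modality`.
#' @examples
#' vol <- image_volume(array(rnorm(8 * 8 * 8), c(8, 8, 8)), 1)
#' dim(vol$values)
#' @export
image_volume <- function(values, spacing_mm, modality = "generic") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (any(!is.finite(values)))
    stop("voxel values must all be finite", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("`spacing_mm` must be a positive triple", call. = FALSE)
  structure(
    list(values = values, spacing_mm = spacing_mm,
         modality = as.character(modality)[1L]),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s, %s voxels @ %s mm\n", x$modality,
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing_mm, 3), collapse = "x")))
  invisible(x)
}

#' Binary region-of-interest mask
#'
#' @param inside logical (or 0/1) 3D array marking in-ROI voxels. Must
#'   contain at least one `TRUE` voxel.
#' @return An object of class `roi_mask` with element `inside` (logical
#'   array).
#' @examples
#' m <- array(FALSE, c(4, 4, 4)); m[2:3, 2:3, 2:3] <- TRUE
#' roi_mask(m)
#' @export
roi_mask <- function(inside) {
  if (!is.array(inside) || length(dim(inside)) != 3L)
    stop("`inside` must be a 3D array", call. = FALSE)
  inside <- array(as.logical(inside), dim(inside))
  if (any(is.na(inside))) stop("mask values must be TRUE/FALSE", call. = FALSE)
  if (!any(inside)) stop("mask must contain at least one voxel", call. = FALSE)
  structure(list(inside = inside), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s grid, %d voxels inside\n",
              paste(dim(x$inside), collapse = "x"), sum(x$inside)))
  invisible(x)
}

check_same_grid <- function(vol, mask) {
  if (!identical(dim(vol$values), dim(mask$inside)))
    stop("volume and mask grids differ: ",
         paste(dim(vol$values), collapse = "x"), " vs ",
         paste(dim(mask$inside), collapse = "x"), call. = FALSE)
  invisible(TRUE)
}

#' ROI volume in cubic millimetres
#'
#' Voxel count times voxel volume.
#'
#' @param mask an [roi_mask()].
#' @param spacing_mm voxel spacing triple in mm.
#' @return scalar volume in mm^3.
#' @export
roi_volume_mm3 <- function(mask, spacing_mm) {
  sum(mask$inside) * prod(spacing_mm)
}

#' Ellipsoidal ROI mask
#'
#' Builds a binary mask of the axis-aligned ellipsoid with the given
#' semi-axes, centred in the grid (or at `center_mm`). Membership is
#' decided at voxel centres.
#'
#' @param grid_shape integer triple of grid dimensions.
#' @param spacing_mm voxel spacing triple (mm).
#' @param radii_mm positive triple of semi-axes (mm).
#' @param center_mm optional physical centre; defaults to the grid centre.
#' @return an [roi_mask()].
#' @export
ellipsoid_mask <- function(grid_shape, spacing_mm, radii_mm,
                           center_mm = NULL) {
  grid_shape <- as.integer(grid_shape)
  spacing_mm <- rep(as.numeric(spacing_mm), length.out = 3L)
  radii_mm <- rep(as.numeric(radii_mm), length.out = 3L)
  if (any(radii_mm <= 0)) stop("radii must be positive", call. = FALSE)
  if (is.null(center_mm)) center_mm <- (grid_shape - 1) * spacing_mm / 2
  ax <- lapply(1:3, function(d) {
    ((seq_len(grid_shape[d]) - 1) * spacing_mm[d] - center_mm[d]) / radii_mm[d]
  })
  # squared normalized distance, separable outer sum
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  roi_mask(d2 <= 1)
}
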