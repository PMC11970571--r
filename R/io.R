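## NIfTI / JSON interchange for volumes, masks and fiducials.

#' Write a volume or mask to NIfTI
#'
#' @param x an [image_volume()] or [roi_mask()] (masks are written as
#'   0/1 integers; supply `spacing_mm` for masks).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing_mm voxel spacing for masks (ignored for volumes).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(x, path, spacing_mm = c(1, 1, 1)) {
  if (inherits(x, "image_volume")) {
    arr <- x$values
    sp <- x$spacing_mm
  } else if (inherits(x, "roi_mask")) {
    arr <- array(as.integer(x$inside), dim(x$inside))
    sp <- rep(as.numeric(spacing_mm), length.out = 3)
  } else {
    stop("`x` must be an image_volume or roi_mask", call. = FALSE)
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file as an image volume or ROI mask
#'
#' @param path NIfTI file path.
#' @param modality modality label for volumes.
#' @param as_mask read as a binary [roi_mask()] (values > 0.5).
#' @return an [image_volume()] or [roi_mask()].
#' @export
read_volume_nifti <- function(path, modality = "generic", as_mask = FALSE) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img)[1:3])
  if (as_mask) return(roi_mask(arr > 0.5))
  image_volume(arr, RNifti::pixdim(img)[1:3], modality)
}

#' Write fiducial annotations to JSON
#'
#' @param ann a [fiducial_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fiducials_json <- function(ann, path) {
  stopifnot(inherits(ann, "fiducial_annotation"))
  obj <- list(
    centers = unname(apply(ann$centers, 1, as.integer, simplify = FALSE)),
    artifact_slices = lapply(ann$artifact_slices, as.integer))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Read fiducial annotations from JSON
#'
#' @param path JSON path written by [write_fiducials_json()].
#' @return a [fiducial_annotation()].
#' @export
read_fiducials_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  centers <- obj$centers
  if (is.list(centers)) centers <- do.call(rbind, centers)
  if (is.null(centers) || length(centers) == 0) centers <- matrix(0L, 0, 3)
  slices <- obj$artifact_slices
  if (!is.list(slices)) slices <- as.list(slices)
  fiducial_annotation(matrix(as.integer(centers), ncol = 3),
                      lapply(slices, as.integer))
}
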