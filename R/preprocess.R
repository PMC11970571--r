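## Separable grid resampling and gray-level preparation.

# Keys cubic-convolution kernel, a = -0.5; reproduces linear (and
# quadratic) signals exactly, interpolating (weight 1 at the node).
keys_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  w <- numeric(length(t))
  i1 <- t <= 1
  w[i1] <- (a + 2) * t[i1]^3 - (a + 3) * t[i1]^2 + 1
  i2 <- t > 1 & t < 2
  w[i2] <- a * t[i2]^3 - 5 * a * t[i2]^2 + 8 * a * t[i2] - 4 * a
  w
}

# n_out x n_in weight matrix mapping samples on an input grid with
# spacing sp_in to output positions (0:(n_out-1)) * sp_out. Out-of-range
# kernel support uses linear extension of the two edge samples, which
# keeps affine signals exact up to the border.
resample_weights <- function(n_in, sp_in, n_out, sp_out,
                             kernel = c("cubic", "linear")) {
  kernel <- match.arg(kernel)
  if (n_in == 1L) return(matrix(1, n_out, 1))
  x <- (seq_len(n_out) - 1) * sp_out / sp_in # in 0-based input index units
  W <- matrix(0, n_out, n_in)
  base <- floor(x)
  offs <- if (kernel == "cubic") -1:2 else 0:1
  add <- function(rows, cols0, w) {
    # cols0 are 0-based input indices; virtual samples beyond the grid
    # are f(-e) = (1+e) f(0) - e f(1), f(n-1+e) = (1+e) f(n-1) - e f(n-2)
    sel <- w != 0
    rows <- rows[sel]; cols0 <- cols0[sel]; w <- w[sel]
    if (!length(w)) return(invisible())
    lo <- cols0 < 0
    hi <- cols0 > n_in - 1
    mid <- !lo & !hi
    if (any(mid))
      W[cbind(rows[mid], cols0[mid] + 1)] <<-
        W[cbind(rows[mid], cols0[mid] + 1)] + w[mid]
    if (any(lo)) {
      e <- -cols0[lo]
      W[cbind(rows[lo], 1)] <<- W[cbind(rows[lo], 1)] + (1 + e) * w[lo]
      W[cbind(rows[lo], 2)] <<- W[cbind(rows[lo], 2)] - e * w[lo]
    }
    if (any(hi)) {
      e <- cols0[hi] - (n_in - 1)
      W[cbind(rows[hi], n_in)] <<- W[cbind(rows[hi], n_in)] +
        (1 + e) * w[hi]
      W[cbind(rows[hi], n_in - 1)] <<- W[cbind(rows[hi], n_in - 1)] -
        e * w[hi]
    }
    invisible()
  }
  for (o in offs) {
    idx <- base + o
    w <- if (kernel == "cubic") keys_kernel(x - idx) else {
      t <- abs(x - idx)
      ifelse(t < 1, 1 - t, 0)
    }
    add(seq_len(n_out), idx, w)
  }
  W
}

# Apply matrix W along dimension d of 3D array a.
apply_along <- function(a, W, d) {
  dm <- dim(a)
  if (d == 1L) {
    array(W %*% matrix(a, dm[1], dm[2] * dm[3]), c(nrow(W), dm[2], dm[3]))
  } else if (d == 2L) {
    b <- aperm(a, c(2, 1, 3))
    b <- array(W %*% matrix(b, dm[2], dm[1] * dm[3]), c(nrow(W), dm[1], dm[3]))
    aperm(b, c(2, 1, 3))
  } else {
    b <- aperm(a, c(3, 1, 2))
    b <- array(W %*% matrix(b, dm[3], dm[1] * dm[2]), c(nrow(W), dm[1], dm[2]))
    aperm(b, c(2, 3, 1))
  }
}

#' Resample a volume and its mask to an isotropic grid
#'
#' The image is interpolated with separable cubic convolution (Keys
#' kernel, third order); the mask is interpolated linearly and
#' re-binarized at 0.5. Output voxel `(i, j, k)` sits at physical
#' position `(i - 1, j - 1, k - 1) * target_mm`, so the input origin is
#' preserved and the output grid covers the input extent without
#' extrapolation.
#'
#' @param vol an [image_volume()].
#' @param mask an [roi_mask()] on the same grid.
#' @param target_mm target isotropic spacing in mm (default 1).
#' @return list with elements `vol` (resampled [image_volume()]) and
#'   `mask` (resampled [roi_mask()]).
#' @export
resample_isotropic <- function(vol, mask, target_mm = 1) {
  stopifnot(inherits(vol, "image_volume"), inherits(mask, "roi_mask"))
  check_same_grid(vol, mask)
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0)
    stop("`target_mm` must be a positive scalar", call. = FALSE)
  dm <- dim(vol$values)
  sp <- vol$spacing_mm
  n_out <- pmax(1L, as.integer(floor((dm - 1) * sp / target_mm + 1e-9)) + 1L)
  Wc <- lapply(1:3, function(d)
    resample_weights(dm[d], sp[d], n_out[d], target_mm, "cubic"))
  Wl <- lapply(1:3, function(d)
    resample_weights(dm[d], sp[d], n_out[d], target_mm, "linear"))
  v <- vol$values
  m <- array(as.numeric(mask$inside), dm)
  for (d in 1:3) {
    v <- apply_along(v, Wc[[d]], d)
    m <- apply_along(m, Wl[[d]], d)
  }
  inside <- m >= 0.5
  if (!any(inside))
    stop(sprintf("resampling emptied the ROI mask (modality %s)",
                 vol$modality), call. = FALSE)
  list(vol = image_volume(v, target_mm, vol$modality),
       mask = roi_mask(inside))
}

#' 3-sigma intensity re-segmentation
#'
#' Computes the mean and (population) standard deviation of the in-mask
#' intensities and removes from the mask every voxel whose value falls
#' outside `[mu - 3 sigma, mu + 3 sigma]`. This is the IBSI-style
#' re-segmentation applied before gray-level quantization; outlying
#' voxels are excluded, not clamped.
#'
#' @param vol an [image_volume()].
#' @param mask an [roi_mask()] on the same grid.
#' @param n_sigma half-width of the retained band in standard deviations
#'   (default 3).
#' @return list with `mask` (re-segmented [roi_mask()]), `range`
#'   (`c(mu - 3*sigma, mu + 3*sigma)`), `mu`, `sigma`, `n_removed`, and
#'   `degenerate` (`TRUE` when sigma is zero, in which case the mask is
#'   unchanged and the range collapses to `(mu, mu)`).
#' @export
collewet_resegment <- function(vol, mask, n_sigma = 3) {
  stopifnot(inherits(vol, "image_volume"), inherits(mask, "roi_mask"))
  check_same_grid(vol, mask)
  x <- vol$values[mask$inside]
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2)) # population SD
  if (sigma == 0) {
    return(list(mask = mask, range = c(mu, mu), mu = mu, sigma = 0,
                n_removed = 0L, degenerate = TRUE))
  }
  rng <- c(mu - n_sigma * sigma, mu + n_sigma * sigma)
  keep <- mask$inside & vol$values >= rng[1] & vol$values <= rng[2]
  if (!any(keep))
    stop("re-segmentation removed every voxel", call. = FALSE)
  list(mask = roi_mask(keep), range = rng, mu = mu, sigma = sigma,
       n_removed = sum(mask$inside) - sum(keep), degenerate = FALSE)
}

#' Lloyd-Max gray-level quantization
#'
#' Quantizes the in-mask intensities to `ng` gray levels with the
#' Lloyd-Max fixed point: the codebook is initialized at the centres of
#' `ng` equal-width bins over `range`, then nearest-code assignment and
#' per-code centroid update alternate until the largest codebook movement
#' falls below `tol` times the range width (or `max_iter` iterations).
#' Empty codes keep their previous value. A value equidistant from two
#' codes is assigned to the lower level, so results are bit-stable.
#'
#' If the ROI holds `k <= ng` distinct values they are mapped directly to
#' levels `1..k` in increasing order and the effective level count is
#' recorded.
#'
#' @param vol an [image_volume()].
#' @param mask an [roi_mask()] (typically after [collewet_resegment()]).
#' @param range numeric `(low, high)` quantization range; defaults to the
#'   in-mask value range.
#' @param ng number of gray levels (default 64).
#' @param tol relative convergence tolerance on codebook movement
#'   (default 1e-8 of the range width).
#' @param max_iter iteration cap (default 500).
#' @return An object of class `quantized_roi`: list with `levels`
#'   (integer array, `NA` outside the mask), `mask`, `ng` (nominal),
#'   `ng_effective`, `codebook`, `range`, `iterations` and `mse_trace`
#'   (within-bin mean squared error after each iteration).
#' @export
lloyd_quantize <- function(vol, mask, range = NULL, ng = 64,
                           tol = 1e-8, max_iter = 500) {
  stopifnot(inherits(vol, "image_volume"), inherits(mask, "roi_mask"))
  check_same_grid(vol, mask)
  ng <- as.integer(ng)
  if (ng < 2L) stop("`ng` must be at least 2", call. = FALSE)
  x <- vol$values[mask$inside]
  if (is.null(range)) range <- base::range(x)
  lo <- range[1]; hi <- range[2]
  distinct <- sort(unique(x))

  finish <- function(lev_in_mask, codebook, iterations, mse_trace) {
    levels <- array(NA_integer_, dim(vol$values))
    levels[mask$inside] <- lev_in_mask
    structure(list(levels = levels, mask = mask, ng = ng,
                   ng_effective = length(codebook), codebook = codebook,
                   range = c(lo, hi), iterations = iterations,
                   mse_trace = mse_trace),
              class = "quantized_roi")
  }

  if (length(distinct) == 1L)
    return(finish(rep(1L, length(x)), distinct, 0L, 0))
  if (length(distinct) <= ng) {
    lev <- match(x, distinct)
    return(finish(lev, distinct, 0L,
                  0)) # codes sit on the distinct values: zero error
  }

  width <- hi - lo
  code <- lo + width * (seq_len(ng) - 0.5) / ng
  assign_levels <- function(code) {
    mids <- (code[-1] + code[-length(code)]) / 2
    findInterval(x, mids, left.open = TRUE) + 1L # tie -> lower level
  }
  mse_trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    lev <- assign_levels(code)
    sums <- tapply(x, factor(lev, levels = seq_len(ng)), sum)
    cnts <- tabulate(lev, nbins = ng)
    newcode <- code
    occ <- cnts > 0L
    newcode[occ] <- as.numeric(sums[occ]) / cnts[occ]
    lev <- assign_levels(newcode)
    mse_trace <- c(mse_trace, mean((x - newcode[lev])^2))
    moved <- max(abs(newcode - code))
    code <- newcode
    if (moved < tol * width || iter >= max_iter) break
  }
  lev <- assign_levels(code)
  # collapse any non-increasing (duplicated) codes so the codebook is
  # strictly increasing and levels stay consecutive
  if (any(diff(code) <= 0)) {
    keepcode <- unique(code)
    lev <- match(code, keepcode)[lev]
    code <- keepcode
  }
  # drop empty trailing/interior codes: relabel occupied codes 1..k
  occ <- sort(unique(lev))
  if (length(occ) < length(code)) {
    code <- code[occ]
    lev <- match(lev, occ)
  }
  finish(lev, code, iter, mse_trace)
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat(sprintf("<quantized_roi> %d levels (%d effective), %d voxels\n",
              x$ng, x$ng_effective, sum(x$mask$inside)))
  invisible(x)
}
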