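#' Marker threshold windows
#'
#' Staining is isolated from background by keeping pixels whose 8-bit red
#' channel value lies inside a per-marker window determined experimentally
#' on the study's stains. `default_threshold_windows()` returns the twelve
#' published windows.
#'
#' @param marker marker label.
#' @param lo,hi window bounds on the 8-bit (0-255) scale, `lo <= hi`.
#' @return `threshold_window` returns a classed list; the default table is
#'   a data frame with columns `marker`, `lo`, `hi`.
#' @examples
#' default_threshold_windows()
#' @export
threshold_window <- function(marker, lo, hi) {
  if (!is.finite(lo) || !is.finite(hi) || lo < 0 || hi > 255 || lo > hi) {
    stop("threshold window must satisfy 0 <= lo <= hi <= 255", call. = FALSE)
  }
  structure(list(marker = as.character(marker), lo = lo, hi = hi),
            class = "threshold_window")
}

#' @rdname threshold_window
#' @export
default_threshold_windows <- function() {
  data.frame(
    marker = c("CALR", "FER", "GABRA3", "GAD6567", "MBP", "PARV",
               "SERT", "SMI32", "SYN", "TH", "TRANSF", "VGLUT1"),
    lo = c(0, 0, 0, 51, 0, 41, 0, 0, 0, 0, 0, 0),
    hi = c(95, 127, 134, 112, 130, 133, 165, 156, 162, 155, 110, 140))
}

#' Apply a threshold window to an intensity channel
#'
#' Marks a pixel as stained iff `lo <= value <= hi` (stained structures are
#' darker, i.e. lower, on the red channel than background).
#'
#' @param image numeric matrix/array of single-channel values on the 0-255
#'   scale.
#' @param window a [threshold_window()].
#' @return Binary array of the same shape (1 = stained).
#' @export
apply_threshold_window <- function(image, window) {
  stopifnot(inherits(window, "threshold_window"))
  if (any(!is.finite(image))) stop("image has non-finite values", call. = FALSE)
  if (min(image) < 0 || max(image) > 255) {
    stop("image values outside the window's 0-255 scale", call. = FALSE)
  }
  out <- (image >= window$lo & image <= window$hi) * 1
  if (!is.null(dim(image))) dim(out) <- dim(image)
  out
}

# separable 1-D convolution of a 3D array along one axis, zero-padded
conv_axis <- function(arr, kernel, axis) {
  r <- (length(kernel) - 1L) / 2L
  perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
  a <- aperm(arr, perm)
  d <- dim(a)
  m <- matrix(a, nrow = d[1])
  padded <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
  f <- stats::filter(padded, kernel, sides = 2)
  out <- array(as.numeric(f[(r + 1):(r + d[1]), , drop = FALSE]), dim = d)
  aperm(out, order(perm))
}

gaussian_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-0.5 * ((-r:r) / sigma_vox)^2)
  k / sum(k)
}

#' Mask-normalized Gaussian smoothing
#'
#' Smooths a staining volume with an anisotropic Gaussian kernel of the
#' given full width at half maximum (in mm, converted per axis by the voxel
#' spacing; `sigma = FWHM / (2 sqrt(2 ln 2))`), truncated outside the
#' nucleus mask and renormalized: each output voxel is the kernel-weighted
#' mean of *mask* voxels only, with weights re-scaled to sum to one
#' (normalized convolution, `smooth(data * mask) / smooth(mask)`). The
#' kernel support is cut at four sigma. Output is defined only inside the
#' mask (`NA` outside); a constant field stays exactly constant.
#'
#' @param vol an [intensity_volume()].
#' @param fwhm_mm kernel full width at half maximum in mm (default 0.3).
#' @return An `intensity_volume` with smoothed data.
#' @export
smooth_in_mask <- function(vol, fwhm_mm = 0.3) {
  stopifnot(inherits(vol, "intensity_volume"))
  if (!is.finite(fwhm_mm) || fwhm_mm <= 0) {
    stop("fwhm_mm must be positive", call. = FALSE)
  }
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  m <- vol$mask * 1
  dat <- vol$data
  dat[!vol$mask] <- 0
  num <- dat
  den <- m
  for (axis in 1:3) {
    k <- gaussian_kernel(sigma_mm / vol$spacing[axis])
    num <- conv_axis(num, k, axis)
    den <- conv_axis(den, k, axis)
  }
  out <- array(NA_real_, dim = dim(dat))
  out[vol$mask] <- num[vol$mask] / den[vol$mask]
  res <- vol
  res$data <- out
  res
}

#' Flag extreme-intensity sectors
#'
#' Marks a sector as excluded when its log-transformed intensity exceeds
#' the grid's median by more than five interquartile ranges:
#' `log(y + 1) > median + 5 * IQR` over the currently included sectors
#' (log1p admits zeros; quantiles use linear interpolation). The rule is
#' applied once per grid, protecting the maximum-likelihood fits from
#' outlying sectors.
#'
#' @param grid a [sector_grid()].
#' @return The grid with updated `included` flags.
#' @export
exclude_outliers <- function(grid) {
  stopifnot(inherits(grid, "sector_grid"))
  inc <- grid$included
  ly <- log1p(grid$y[inc])
  cut <- stats::median(ly) + 5 * stats::IQR(ly)
  flag <- rep(FALSE, nrow(grid))
  flag[inc] <- ly > cut
  grid$included <- inc & !flag
  if (!any(grid$included)) {
    stop("outlier exclusion removed every sector (degenerate grid)",
         call. = FALSE)
  }
  grid
}
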