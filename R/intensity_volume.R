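#' Intensity volumes
#'
#' Container for one specimen/marker 3D staining reconstruction: a
#' nonnegative stained-pixel count (or density) array, a binary nucleus mask
#' of the same shape, and the anisotropic voxel spacing. The first two array
#' dimensions are in-plane (cutting plane), the third runs across slices
#' (rostrocaudal axis). Typical histology spacing is 0.014 mm in-plane and
#' 0.3 mm between slices.
#'
#' @param data 3D nonnegative numeric array.
#' @param mask 3D binary (logical or 0/1) array, same shape as `data`.
#' @param spacing numeric triple of voxel sizes in mm
#'   (in-plane, in-plane, inter-slice), all positive.
#' @param specimen_id,marker labels.
#' @return An object of class `intensity_volume`.
#' @export
intensity_volume <- function(data, mask, spacing = c(0.014, 0.014, 0.3),
                             specimen_id = "specimen", marker = "marker") {
  data <- as.array(data)
  mask <- as.array(mask)
  if (length(dim(data)) != 3L) stop("data must be a 3D array", call. = FALSE)
  if (!identical(dim(data), dim(mask))) {
    stop("mask shape must match data shape", call. = FALSE)
  }
  mask <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(mask)) stop("mask must be binary with no NA", call. = FALSE)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three positive numbers (mm)", call. = FALSE)
  }
  if (any(!is.finite(data[mask])) || any(data[mask] < 0)) {
    stop("data must be finite and nonnegative inside the mask", call. = FALSE)
  }
  structure(list(data = data, mask = mask, spacing = spacing,
                 specimen_id = as.character(specimen_id),
                 marker = as.character(marker)),
            class = "intensity_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat(sprintf("Intensity volume: specimen %s, marker %s\n", x$specimen_id, x$marker))
  cat(sprintf("  shape %s, spacing %s mm, %d mask voxels\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = " x "),
              sum(x$mask)))
  invisible(x)
}

#' Write / read intensity volumes as NIfTI
#'
#' Stores the data and mask arrays as two NIfTI-1 images with the voxel
#' spacing in the header, the standard neuroimaging container for 3D
#' reconstructions.
#'
#' @param vol an [intensity_volume()].
#' @param data_path,mask_path output `.nii`/`.nii.gz` paths.
#' @return For the writer, `data_path` invisibly; for the reader, an
#'   `intensity_volume`.
#' @export
write_volume_nifti <- function(vol, data_path, mask_path) {
  stopifnot(inherits(vol, "intensity_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, data_path)
  msk <- RNifti::asNifti(array(as.numeric(vol$mask), dim = dim(vol$mask)))
  RNifti::pixdim(msk) <- vol$spacing
  RNifti::writeNifti(msk, mask_path)
  invisible(data_path)
}

#' @rdname write_volume_nifti
#' @param specimen_id,marker labels attached to the volume read back.
#' @export
read_volume_nifti <- function(data_path, mask_path,
                              specimen_id = "specimen", marker = "marker") {
  img <- RNifti::readNifti(data_path)
  msk <- RNifti::readNifti(mask_path)
  spacing <- RNifti::pixdim(img)[1:3]
  intensity_volume(array(as.numeric(img), dim = dim(img)[1:3]),
                   array(as.numeric(msk) > 0.5, dim = dim(msk)[1:3]),
                   spacing = spacing,
                   specimen_id = specimen_id, marker = marker)
}

#' Import a TIFF stack as an intensity volume
#'
#' Reads one single-channel TIFF image per section (in rostrocaudal order)
#' and stacks them into a 3D array with the given in-plane and inter-slice
#' spacing. Multi-channel images are reduced to their first channel.
#'
#' @param paths character vector of per-section TIFF paths, in slice order.
#' @param mask optional 3D binary array; defaults to all voxels.
#' @param spacing voxel spacing in mm (in-plane, in-plane, inter-slice).
#' @param specimen_id,marker labels.
#' @return An [intensity_volume()].
#' @export
read_tiff_stack <- function(paths, mask = NULL,
                            spacing = c(0.014, 0.014, 0.3),
                            specimen_id = "specimen", marker = "marker") {
  slices <- lapply(paths, function(p) {
    s <- tiff::readTIFF(p)
    if (length(dim(s)) == 3L) s <- s[, , 1]
    s
  })
  d <- dim(slices[[1]])
  if (!all(vapply(slices, function(s) identical(dim(s), d), logical(1)))) {
    stop("all TIFF sections must have identical dimensions", call. = FALSE)
  }
  arr <- array(unlist(slices), dim = c(d, length(slices)))
  if (is.null(mask)) mask <- array(TRUE, dim = dim(arr))
  intensity_volume(arr, mask, spacing = spacing,
                   specimen_id = specimen_id, marker = marker)
}
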