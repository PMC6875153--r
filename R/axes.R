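#' Anatomical axis frame of a nucleus mask
#'
#' The three analysis axes of a reconstructed nucleus: the rostrocaudal
#' axis is the slice (cutting-plane) direction; the two in-plane axes come
#' from a principal component analysis of the in-plane mm coordinates of
#' all mask voxels pooled over slices (in the study these align with the
#' dorsolateral-ventromedial direction and its orthogonal). Components are
#' given a deterministic sign: each is flipped so its largest-magnitude
#' loading is positive.
#'
#' @param vol an [intensity_volume()] whose mask spans at least two slices.
#' @return An object of class `axis_frame`: list with `pca_axes` (2x2
#'   orthonormal columns in in-plane mm space), `origin` (in-plane
#'   centroid, mm), `sdev` (component SDs) and axis labels.
#' @export
compute_axes <- function(vol) {
  stopifnot(inherits(vol, "intensity_volume"))
  idx <- which(vol$mask, arr.ind = TRUE)
  if (length(unique(idx[, 3])) < 2L) {
    stop("mask must span at least two slices", call. = FALSE)
  }
  xy <- cbind(idx[, 1] * vol$spacing[1], idx[, 2] * vol$spacing[2])
  pc <- stats::prcomp(xy, center = TRUE, scale. = FALSE)
  if (pc$sdev[2] <= 1e-10 * pc$sdev[1]) {
    stop("degenerate mask: in-plane coordinates are collinear", call. = FALSE)
  }
  rot <- pc$rotation
  for (c_ in 1:2) {
    lead <- which.max(abs(rot[, c_]))
    if (rot[lead, c_] < 0) rot[, c_] <- -rot[, c_]
  }
  structure(list(pca_axes = rot,
                 origin = pc$center,
                 sdev = pc$sdev,
                 axis_labels = c("rostrocaudal", "in-plane PC1",
                                 "in-plane PC2")),
            class = "axis_frame")
}

#' @export
print.axis_frame <- function(x, ...) {
  cat("Axis frame: rostrocaudal (slice axis) + in-plane PCA axes\n")
  print(round(x$pca_axes, 4))
  invisible(x)
}

#' Normalized anatomical coordinates of mask voxels
#'
#' Maps every mask voxel to `(x1, x2, x3)` in \[0, 1\]: `x1` is the
#' min-max-scaled slice position (rostrocaudal), `x2`/`x3` the
#' min-max-scaled scores on the two in-plane principal axes. Extreme voxels
#' map to exactly 0 and 1 on each axis; the scaling makes the coordinates
#' invariant to translating the whole mask.
#'
#' @param vol an [intensity_volume()].
#' @param frame an [compute_axes()] frame for the same mask.
#' @return List with `x` (n x 3 matrix), `voxel_index` (n x 3 array
#'   indices), and `values` (the data values at those voxels).
#' @export
normalize_coordinates <- function(vol, frame) {
  stopifnot(inherits(vol, "intensity_volume"), inherits(frame, "axis_frame"))
  idx <- which(vol$mask, arr.ind = TRUE)
  if (length(unique(idx[, 3])) < 2L) {
    stop("single-slice mask: rostrocaudal coordinate undefined",
         call. = FALSE)
  }
  xy <- cbind(idx[, 1] * vol$spacing[1], idx[, 2] * vol$spacing[2])
  scores <- sweep(xy, 2, frame$origin) %*% frame$pca_axes
  raw <- cbind(idx[, 3] * vol$spacing[3], scores)
  x <- apply(raw, 2, function(v) {
    r <- range(v)
    if (r[2] - r[1] <= 0) rep(0.5, length(v)) else (v - r[1]) / (r[2] - r[1])
  })
  colnames(x) <- c("x1", "x2", "x3")
  list(x = x, voxel_index = idx, values = vol$data[idx])
}

#' Rasterize a masked volume into equal-volume sectors
#'
#' Divides the mask voxels into `k^3` sectors of equal voxel count by
#' nested quantile splitting: voxels are split into `k` equal-count bins
#' along the rostrocaudal coordinate; each bin is split into `k`
#' equal-count bins along the second axis; each of those along the third
#' (bin sizes differ by at most one voxel at every level). Nested
#' splitting is the equal-volume reading that keeps every sector occupied
#' on an irregular (e.g. lens-shaped) mask — independent marginal binning
#' would leave the "corner" intersections of a convex nucleus empty —
#' so a 10-division rasterization always yields 1000 analyzable sectors.
#' The sector intensity is the voxel sum by default (count-like, matching
#' the NB error model); sector coordinates are the bin centers
#' `(b - 0.5) / k`. Total intensity over sectors equals the total over
#' mask voxels.
#'
#' @param vol an [intensity_volume()] (typically after [smooth_in_mask()]).
#' @param frame an [compute_axes()] frame; computed from the mask if `NULL`.
#' @param k divisions per axis (3 for the consistency stage, 10 for model
#'   fitting).
#' @param stat `"sum"` (default) or `"mean"` voxel aggregation.
#' @return A [sector_grid()] with shape `c(k, k, k)`.
#' @export
rasterize <- function(vol, frame = NULL, k = 10L, stat = c("sum", "mean")) {
  stopifnot(inherits(vol, "intensity_volume"))
  stat <- match.arg(stat)
  k <- as.integer(k)
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  if (is.null(frame)) frame <- compute_axes(vol)
  co <- normalize_coordinates(vol, frame)
  n <- nrow(co$x)
  if (n < k^3) {
    stop("mask has ", n, " voxels, fewer than ", k^3, " sectors",
         call. = FALSE)
  }
  b1 <- equal_count_bins(co$x[, 1], k)
  b2 <- integer(n)
  b3 <- integer(n)
  for (u in seq_len(k)) {
    s1 <- which(b1 == u)
    b2[s1] <- equal_count_bins(co$x[s1, 2], k)
    for (v in seq_len(k)) {
      s2 <- s1[b2[s1] == v]
      b3[s2] <- equal_count_bins(co$x[s2, 3], k)
    }
  }
  key <- (b1 - 1L) * k * k + (b2 - 1L) * k + b3
  vals <- co$values
  if (anyNA(vals)) stop("volume has NA intensities inside the mask", call. = FALSE)
  agg <- if (stat == "sum") {
    tapply(vals, key, sum)
  } else {
    tapply(vals, key, mean)
  }
  keys <- as.integer(names(agg))
  b1 <- (keys - 1L) %/% (k * k)
  b2 <- ((keys - 1L) %/% k) %% k
  b3 <- (keys - 1L) %% k
  rec <- data.frame(i = b1, j = b2, k = b3,
                    x1 = (b1 + 0.5) / k, x2 = (b2 + 0.5) / k,
                    x3 = (b3 + 0.5) / k,
                    y = as.numeric(agg))
  sector_grid(rec, specimen_id = vol$specimen_id, marker = vol$marker,
              shape = c(k, k, k))
}

# rank-based equal-count binning; ties broken by stable original order
equal_count_bins <- function(v, k) {
  n <- length(v)
  bins <- integer(n)
  bins[order(v, seq_len(n))] <- ceiling(seq_len(n) * k / n)
  bins
}

#' Aggregate a fine sector grid to a coarser resolution
#'
#' Re-bins a fine sector grid (e.g. 10x10x10) into `k` near-equal groups of
#' whole index slices per axis and aggregates the intensities within each
#' coarse cell — the same field rasterized at a coarser resolution, as used
#' by the across-specimen consistency stage (3x3x3 = 27 sectors). The
#' default aggregate is the *mean* fine-sector intensity: the consistency
#' analysis tests mean staining per sector, and the mean is insensitive to
#' the slightly unequal group sizes when `k` does not divide the fine
#' shape. Averaging many fine sectors also brings the coarse values close
#' to normality, which the per-sector t tests rely on.
#'
#' @param grid a [sector_grid()].
#' @param k coarse divisions per axis (must not exceed the fine shape).
#' @param stat `"mean"` (default) or `"sum"`.
#' @return A [sector_grid()] with shape `c(k, k, k)`.
#' @export
coarsen_grid <- function(grid, k = 3L, stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  stopifnot(inherits(grid, "sector_grid"))
  k <- as.integer(k)
  shape <- attr(grid, "shape")
  if (any(k > shape)) stop("k exceeds the fine grid shape", call. = FALSE)
  bin <- function(idx, kf) ceiling((idx + 1L) * k / kf)
  b1 <- bin(grid$i, shape[1]); b2 <- bin(grid$j, shape[2]); b3 <- bin(grid$k, shape[3])
  key <- (b1 - 1L) * k * k + (b2 - 1L) * k + b3
  agg <- tapply(grid$y, key, if (stat == "mean") mean else sum)
  keys <- as.integer(names(agg))
  c1 <- (keys - 1L) %/% (k * k)
  c2 <- ((keys - 1L) %/% k) %% k
  c3 <- (keys - 1L) %% k
  rec <- data.frame(i = c1, j = c2, k = c3,
                    x1 = (c1 + 0.5) / k, x2 = (c2 + 0.5) / k,
                    x3 = (c3 + 0.5) / k, y = as.numeric(agg))
  sector_grid(rec, specimen_id = attr(grid, "specimen_id"),
              marker = attr(grid, "marker"), shape = c(k, k, k))
}
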