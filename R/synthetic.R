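#' Synthetic STN-like masks
#'
#' Builds a binary nucleus mask on an anisotropic voxel grid: either an
#' ellipsoid or a biconvex lens (intersection of two spheres), optionally
#' rotated, standing in for a delineated subthalamic nucleus. The bounding
#' grid is sized to hold the shape with at least a two-voxel margin; a
#' voxel belongs to the mask when its continuous center lies inside the
#' rotated shape.
#'
#' @param semi_axes positive mm triple: ellipsoid semi-axes, or for
#'   `kind = "lens"` the equatorial radius (first two entries) and the
#'   half-thickness (third).
#' @param spacing positive mm triple of voxel sizes; the third entry is the
#'   inter-slice distance.
#' @param kind `"ellipsoid"` or `"lens"`.
#' @param orientation rotation angles in radians (about the third, second
#'   and first grid axes, applied in that order).
#' @param specimen_id label for the resulting volume.
#' @return An [intensity_volume()] whose `data` is zero and whose `mask`
#'   is the shape.
#' @examples
#' m <- make_lens_mask(c(1, 1, 1), spacing = c(0.1, 0.1, 0.3))
#' sum(m$mask)
#' @export
make_lens_mask <- function(semi_axes = c(5, 3, 1.5),
                           spacing = c(0.1, 0.1, 0.3),
                           kind = c("ellipsoid", "lens"),
                           orientation = c(0, 0, 0),
                           specimen_id = "synthetic") {
  kind <- match.arg(kind)
  semi_axes <- as.numeric(semi_axes)
  spacing <- as.numeric(spacing)
  if (any(semi_axes <= 0) || any(spacing <= 0)) {
    stop("semi-axes and spacing must be positive", call. = FALSE)
  }
  R <- rotation_matrix(orientation)
  # bounding radius of the rotated shape along each grid axis
  extent <- sqrt(colSums((R * semi_axes)^2))
  n <- 2L * (ceiling(extent / spacing) + 2L) + 1L
  centers <- lapply(1:3, function(a) (seq_len(n[a]) - (n[a] + 1) / 2) * spacing[a])
  g <- as.matrix(expand.grid(centers[[1]], centers[[2]], centers[[3]]))
  local <- g %*% R   # grid-space -> shape-space coordinates
  inside <- if (kind == "ellipsoid") {
    rowSums(sweep(local, 2, semi_axes, "/")^2) <= 1
  } else {
    a <- mean(semi_axes[1:2])
    cthick <- semi_axes[3]
    if (cthick >= a) stop("lens half-thickness must be below its radius", call. = FALSE)
    Rs <- (a^2 + cthick^2) / (2 * cthick)
    off <- Rs - cthick
    r2 <- local[, 1]^2 + local[, 2]^2
    (r2 + (local[, 3] + off)^2 <= Rs^2) & (r2 + (local[, 3] - off)^2 <= Rs^2)
  }
  mask <- array(inside, dim = n)
  if (!any(mask)) {
    stop("mask parameters produced an empty mask (shape below voxel size)",
         call. = FALSE)
  }
  intensity_volume(array(0, dim = n), mask, spacing = spacing,
                   specimen_id = specimen_id, marker = "mask")
}

rotation_matrix <- function(angles) {
  cz <- cos(angles[1]); sz <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cx <- cos(angles[3]); sx <- sin(angles[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Rz %*% Ry %*% Rx
}

sector_coords <- function(grid_shape) {
  grid_shape <- as.integer(grid_shape)
  idx <- expand.grid(i = seq_len(grid_shape[1]) - 1L,
                     j = seq_len(grid_shape[2]) - 1L,
                     k = seq_len(grid_shape[3]) - 1L)
  data.frame(idx,
             x1 = (idx$i + 0.5) / grid_shape[1],
             x2 = (idx$j + 0.5) / grid_shape[2],
             x3 = (idx$k + 0.5) / grid_shape[3])
}

#' Simulate negative-binomial immunoreactivity
#'
#' Draws independent NB counts whose mean follows one of the four spatial
#' models (see [stn_models]) evaluated at sector or voxel locations, with
#' shape dispersion `alpha` (`Var = mu + mu^2/alpha`; `alpha -> Inf` is the
#' Poisson limit). Supply either a `grid_shape` (draws on the sector-center
#' lattice and returns a [sector_grid()]) or a mask `volume` (draws at every
#' mask voxel at its normalized anatomical coordinates and returns an
#' [intensity_volume()]).
#'
#' @param params a [model_params()] truth.
#' @param grid_shape integer triple of sector divisions per axis.
#' @param volume an [intensity_volume()] whose mask defines the voxels.
#' @param seed integer seed; the same seed reproduces the same draws.
#' @param specimen_id,marker labels for the output.
#' @return A `sector_grid` or an `intensity_volume` of counts.
#' @export
simulate_intensities <- function(params, grid_shape = NULL, volume = NULL,
                                 seed = NULL, specimen_id = "synthetic",
                                 marker = "marker") {
  stopifnot(inherits(params, "model_params"))
  if (params$alpha <= 0) stop("alpha must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(volume)) {
    if (is.null(grid_shape)) stop("supply grid_shape or volume", call. = FALSE)
    sc <- sector_coords(grid_shape)
    mu <- predict_mean(params, as.matrix(sc[, c("x1", "x2", "x3")]))
    sc$y <- stats::rnbinom(nrow(sc), size = params$alpha, mu = mu)
    sector_grid(sc, specimen_id = specimen_id, marker = marker,
                shape = as.integer(grid_shape))
  } else {
    frame <- compute_axes(volume)
    coords <- normalize_coordinates(volume, frame)
    mu <- predict_mean(params, coords$x)
    y <- stats::rnbinom(nrow(coords$x), size = params$alpha, mu = mu)
    data <- array(0, dim = dim(volume$mask))
    data[coords$voxel_index] <- y
    intensity_volume(data, volume$mask, spacing = volume$spacing,
                     specimen_id = specimen_id, marker = marker)
  }
}

#' Study design for the synthetic generator
#'
#' Describes a synthetic study emulating the seven-specimen, twelve-marker
#' immunohistochemistry design: which spatial model generates each marker,
#' with what parameters, on what sector lattice, and how much the
#' log-intercept varies across specimens (inter-individual staining
#' intensity variability).
#'
#' The default marker-to-model assignment follows the across-specimen
#' consensus of the published study (linear gradients for nine markers;
#' sigmoidal gradients for MBP, PARV and SYN), with moderate effect sizes,
#' dispersion `alpha = 10` and a log-intercept jitter of 0.25 SD.
#'
#' @param n_specimens number of specimens (default 7).
#' @param markers marker labels (default the twelve study markers).
#' @param grid_shape sector divisions per axis (default `c(10, 10, 10)`).
#' @param model_assignment named character vector marker -> model id;
#'   defaults as above.
#' @param params named list marker -> [model_params()]; defaults derived
#'   from the assignment.
#' @param specimen_intercept_sd SD of the per-specimen `lambda0` jitter.
#' @param seed study seed; expanded deterministically into
#'   per-(specimen, marker) substreams.
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_specimens = 7L,
                         markers = stn_markers(),
                         grid_shape = c(10L, 10L, 10L),
                         model_assignment = NULL,
                         params = NULL,
                         specimen_intercept_sd = 0.25,
                         seed = 1L) {
  if (n_specimens < 1L) stop("need at least one specimen", call. = FALSE)
  if (is.null(model_assignment)) {
    model_assignment <- stats::setNames(rep("B", length(markers)), markers)
    model_assignment[markers %in% c("MBP", "PARV", "SYN")] <- "D"
  }
  if (is.null(names(model_assignment)) ||
      !all(markers %in% names(model_assignment))) {
    stop("model_assignment must be named by marker", call. = FALSE)
  }
  if (is.null(params)) {
    params <- lapply(model_assignment[markers], default_truth)
    names(params) <- markers
  }
  for (mk in markers) {
    if (!inherits(params[[mk]], "model_params")) {
      stop("params for marker ", mk, " must be model_params", call. = FALSE)
    }
    if (params[[mk]]$model_id != model_assignment[[mk]]) {
      stop("params/model_assignment mismatch for marker ", mk, call. = FALSE)
    }
  }
  structure(list(n_specimens = as.integer(n_specimens), markers = markers,
                 grid_shape = as.integer(grid_shape),
                 model_assignment = model_assignment[markers],
                 params = params,
                 specimen_intercept_sd = specimen_intercept_sd,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' The twelve study protein markers
#' @return Character vector of marker labels.
#' @export
stn_markers <- function() {
  c("CALR", "FER", "GABRA3", "GAD6567", "MBP", "PARV",
    "SERT", "SMI32", "SYN", "TH", "TRANSF", "VGLUT1")
}

# per-model generating truths at realistic effect sizes (mean counts ~30,
# overdispersion alpha = 10, gradients of about one log unit)
default_truth <- function(model_id) {
  l0 <- log(30)
  switch(model_id,
         A = model_params("A", lambda0 = l0, alpha = 10),
         B = model_params("B", lambda0 = l0, lambda1 = 1, lambda2 = -1,
                          lambda3 = 0.5, alpha = 10),
         C = model_params("C", lambda0 = l0, lambda1 = 1, lambda2 = -1,
                          beta1 = 0.4, beta2 = 0.5, tau1 = 0.3, tau2 = 0.7,
                          alpha = 10),
         D = model_params("D", lambda0 = l0, lambda1 = 1, lambda2 = -1,
                          beta1 = 0.4, beta2 = 0.5, tau1 = 0.35, tau2 = 0.65,
                          kappa = 10, alpha = 10))
}

#' Generate a synthetic study
#'
#' Simulates one sector grid per (specimen, marker) combination of a
#' [study_design()]: each specimen draws a `lambda0` offset from
#' `N(0, specimen_intercept_sd)` (shared across its markers), then each
#' grid draws NB counts from the marker's generating model. All randomness
#' derives deterministically from the study seed.
#'
#' @param design a [study_design()].
#' @return List with `grids` (named `"specimen|marker"`) and `truth` (the
#'   design plus the realized per-specimen intercept offsets), the latter
#'   serializable with [write_truth()].
#' @examples
#' st <- generate_study(study_design(n_specimens = 2, markers = c("CALR", "MBP"),
#'                                   grid_shape = c(4, 4, 4), seed = 7))
#' length(st$grids)
#' @export
generate_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  specimens <- sprintf("S%02d", seq_len(design$n_specimens))
  set.seed(derive_seed(design$seed, 0L))
  offsets <- stats::rnorm(design$n_specimens, 0, design$specimen_intercept_sd)
  names(offsets) <- specimens
  grids <- list()
  idx <- 0L
  for (s in seq_along(specimens)) {
    for (mk in design$markers) {
      idx <- idx + 1L
      truth <- design$params[[mk]]
      truth$lambda0 <- truth$lambda0 + offsets[s]
      g <- simulate_intensities(truth, grid_shape = design$grid_shape,
                                seed = derive_seed(design$seed, idx),
                                specimen_id = specimens[s], marker = mk)
      grids[[grid_id(g)]] <- g
    }
  }
  truth <- list(design = design, specimen_offsets = offsets)
  list(grids = grids, truth = truth)
}

#' Serialize / reload a study truth record
#'
#' Writes the generating parameters of a synthetic study (design, per-marker
#' truths, realized specimen offsets) as JSON, and reads them back into the
#' same structure, so fitted estimates can always be compared with the truth
#' that produced the data.
#'
#' @param truth the `truth` component of [generate_study()].
#' @param path JSON file path.
#' @return The reloaded truth list (for `read_truth`); `path` invisibly for
#'   `write_truth`.
#' @export
write_truth <- function(truth, path) {
  d <- truth$design
  obj <- list(
    n_specimens = d$n_specimens,
    markers = d$markers,
    grid_shape = d$grid_shape,
    model_assignment = as.list(d$model_assignment),
    params = lapply(d$params, function(p) p[model_param_names(p$model_id)]),
    specimen_intercept_sd = d$specimen_intercept_sd,
    seed = d$seed,
    specimen_offsets = as.list(truth$specimen_offsets))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  assignment <- unlist(obj$model_assignment)
  params <- lapply(obj$markers, function(mk) {
    p <- obj$params[[mk]]
    do.call(model_params, c(list(model_id = assignment[[mk]]), p))
  })
  names(params) <- obj$markers
  design <- study_design(n_specimens = obj$n_specimens,
                         markers = obj$markers,
                         grid_shape = obj$grid_shape,
                         model_assignment = assignment,
                         params = params,
                         specimen_intercept_sd = obj$specimen_intercept_sd,
                         seed = obj$seed)
  list(design = design,
       specimen_offsets = unlist(obj$specimen_offsets))
}
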