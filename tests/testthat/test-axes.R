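angle_deg <- function(u, v) {
  c_ <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, c_)) * 180 / pi
}

test_that("PCA axes recover the in-plane axes of an anisotropic ellipsoid", {
  theta <- 0.5
  m <- make_lens_mask(c(2, 0.8, 0.6), spacing = c(0.05, 0.05, 0.2),
                      orientation = c(theta, 0, 0))
  fr <- compute_axes(m)
  expect_lt(angle_deg(fr$pca_axes[, 1], c(cos(theta), sin(theta))), 5)
  expect_lt(angle_deg(fr$pca_axes[, 2], c(-sin(theta), cos(theta))), 5)
  expect_equal(crossprod(fr$pca_axes), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("recovered axes are equivariant under in-plane rotation", {
  base <- 0.2
  extra <- 0.3
  f1 <- compute_axes(make_lens_mask(c(2, 0.8, 0.6),
                                    spacing = c(0.05, 0.05, 0.2),
                                    orientation = c(base, 0, 0)))
  f2 <- compute_axes(make_lens_mask(c(2, 0.8, 0.6),
                                    spacing = c(0.05, 0.05, 0.2),
                                    orientation = c(base + extra, 0, 0)))
  R <- matrix(c(cos(extra), sin(extra), -sin(extra), cos(extra)), 2)
  expect_lt(angle_deg(f2$pca_axes[, 1], R %*% f1$pca_axes[, 1]), 5)
})

test_that("the sign convention is deterministic even for a sphere", {
  m <- make_lens_mask(c(1, 1, 1), spacing = c(0.1, 0.1, 0.1))
  f1 <- compute_axes(m)
  f2 <- compute_axes(m)
  expect_identical(f1$pca_axes, f2$pca_axes)
  lead <- apply(abs(f1$pca_axes), 2, which.max)
  expect_true(all(f1$pca_axes[cbind(lead, 1:2)] > 0))
})

test_that("degenerate masks are rejected", {
  arr <- array(FALSE, c(8, 8, 4))
  arr[4, 3:6, 2:3] <- TRUE   # collinear in-plane
  vol <- intensity_volume(array(0, dim(arr)), arr, c(0.1, 0.1, 0.3))
  expect_error(compute_axes(vol), "collinear")
  single <- array(FALSE, c(8, 8, 4))
  single[3:6, 3:6, 2] <- TRUE
  vol1 <- intensity_volume(array(0, dim(single)), single, c(0.1, 0.1, 0.3))
  expect_error(compute_axes(vol1), "two slices")
})

test_that("normalized coordinates hit 0 and 1 and ignore translations", {
  m <- make_lens_mask(c(1, 0.7, 0.5), spacing = c(0.1, 0.1, 0.1))
  fr <- compute_axes(m)
  co <- normalize_coordinates(m, fr)
  expect_equal(apply(co$x, 2, min), c(x1 = 0, x2 = 0, x3 = 0))
  expect_equal(apply(co$x, 2, max), c(x1 = 1, x2 = 1, x3 = 1))

  # translate the mask within a larger array: coordinates unchanged
  big <- array(FALSE, dim(m$mask) + c(6, 4, 2))
  big[(1:dim(m$mask)[1]) + 3, (1:dim(m$mask)[2]) + 4,
      (1:dim(m$mask)[3]) + 2] <- m$mask
  volb <- intensity_volume(array(0, dim(big)), big, m$spacing)
  cob <- normalize_coordinates(volb, compute_axes(volb))
  expect_equal(cob$x, co$x, tolerance = 1e-8)
})

test_that("the mid slice of a 21-slice mask sits at x1 = 0.5", {
  m <- make_lens_mask(c(1, 1, 1), spacing = c(0.1, 0.1, 0.1))
  co <- normalize_coordinates(m, compute_axes(m))
  slices <- sort(unique(co$voxel_index[, 3]))
  expect_length(slices, 21)
  mid <- co$voxel_index[, 3] == slices[11]
  expect_equal(unique(co$x[mid, 1]), 0.5)
})

test_that("a full 30-cube at k = 3 gives 27 sectors of 1000 voxels", {
  cube <- array(TRUE, c(30, 30, 30))
  vol <- intensity_volume(array(1, dim(cube)), cube, c(0.1, 0.1, 0.1))
  g <- rasterize(vol, k = 3, stat = "sum")
  expect_equal(nrow(g), 27)
  expect_true(all(g$y == 1000))  # each sector counted 1000 unit voxels
})

test_that("rasterization conserves total intensity and splits counts evenly", {
  m <- make_lens_mask(c(1.2, 0.9, 0.7), spacing = c(0.08, 0.08, 0.15))
  sim <- simulate_intensities(model_params("B", lambda0 = log(5), lambda1 = 1),
                              volume = m, seed = 6)
  fr <- compute_axes(sim)
  for (k in c(3L, 10L)) {
    g <- rasterize(sim, fr, k = k)
    expect_equal(sum(g$y), sum(sim$data[sim$mask]))
    expect_equal(nrow(g), k^3)
    expect_s3_class(validate_sector_grid(g), "sector_grid")
    # equal-volume property, via a unit-intensity rasterization: every
    # sector holds n/k^3 voxels up to the nested-splitting rounding
    ones <- sim
    ones$data[ones$mask] <- 1
    cnt <- rasterize(ones, fr, k = k)
    n_vox <- sum(sim$mask)
    expect_lte(diff(range(cnt$y)), 3)          # sizes near-equal
    expect_lte(max(abs(cnt$y - n_vox / k^3)), 3)
    marg <- tapply(cnt$y, cnt$i, sum)          # first axis split exactly
    expect_lte(diff(range(marg)), 1)
  }
})

test_that("rasterization demands enough voxels and positive k", {
  m <- make_lens_mask(c(0.3, 0.3, 0.3), spacing = c(0.1, 0.1, 0.1))
  expect_error(rasterize(m, k = 10), "fewer than")
  expect_error(rasterize(m, k = 0), "at least 1")
})

test_that("coarsening averages whole slices into near-equal groups", {
  g <- toy_grid(10, seed = 31)
  cg <- coarsen_grid(g, 3)
  expect_equal(nrow(cg), 27)
  expect_identical(attr(cg, "shape"), c(3L, 3L, 3L))
  # oracle: direct mean over the 4/3/3 slice grouping per axis
  grp <- function(idx) ceiling((idx + 1) * 3 / 10)
  man <- aggregate(y ~ gi + gj + gk,
                   data = data.frame(gi = grp(g$i), gj = grp(g$j),
                                     gk = grp(g$k), y = g$y),
                   FUN = mean)
  man <- man[order(man$gi, man$gj, man$gk), ]
  cg <- cg[order(cg$i, cg$j, cg$k), ]
  expect_equal(cg$y, man$y)
  expect_equal(sum(coarsen_grid(g, 5, stat = "sum")$y), sum(g$y))
})
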