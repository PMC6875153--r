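test_that("threshold windows keep in-window pixels and drop the rest", {
  w <- threshold_window("CALR", 0, 95)
  img <- matrix(c(50, 200, 0, 95, 96, 255), 2, 3)
  out <- apply_threshold_window(img, w)
  expect_equal(out, matrix(c(1, 0, 1, 1, 0, 0), 2, 3))
  expect_true(all(apply_threshold_window(img, threshold_window("x", 0, 255)) == 1))
  uniform <- matrix(96, 4, 4)
  expect_true(all(apply_threshold_window(uniform, w) == 0))
})

test_that("threshold windows validate their scale", {
  expect_error(threshold_window("x", -1, 10), "0 <= lo")
  expect_error(threshold_window("x", 10, 5), "lo <= hi")
  expect_error(threshold_window("x", 0, 300), "<= 255")
  expect_error(apply_threshold_window(matrix(300, 2, 2),
                                      threshold_window("x", 0, 95)),
               "0-255")
})

test_that("the default windows cover the twelve study markers", {
  tw <- default_threshold_windows()
  expect_setequal(tw$marker, stn_markers())
  expect_equal(tw$hi[tw$marker == "CALR"], 95)
  expect_equal(tw$lo[tw$marker == "GAD6567"], 51)
  expect_true(all(tw$lo >= 0 & tw$hi <= 255 & tw$lo <= tw$hi))
})

test_that("masked smoothing leaves a constant field exactly constant", {
  vol <- make_lens_mask(c(0.8, 0.6, 0.5), spacing = c(0.1, 0.1, 0.2))
  vol$data[vol$mask] <- 7.5
  sm <- smooth_in_mask(vol, fwhm_mm = 0.3)
  expect_equal(sm$data[sm$mask], rep(7.5, sum(sm$mask)), tolerance = 1e-12)
  expect_true(all(is.na(sm$data[!sm$mask])))
})

test_that("masked smoothing matches a dense normalized-convolution oracle", {
  # small box mask with an off-center spike; oracle: brute-force truncated
  # Gaussian weights over mask voxels, renormalized per target voxel
  dims <- c(9, 8, 7)
  mask <- array(FALSE, dims)
  mask[2:8, 2:7, 2:6] <- TRUE
  data <- array(0, dims)
  data[5, 4, 4] <- 3
  data[3, 6, 3] <- 1.5
  spacing <- c(0.1, 0.1, 0.15)
  vol <- intensity_volume(data, mask, spacing)
  fwhm <- 0.3
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  sig_vox <- sigma / spacing
  rad <- pmax(1, ceiling(4 * sig_vox))
  idx <- which(mask, arr.ind = TRUE)
  oracle <- array(NA_real_, dims)
  for (r in seq_len(nrow(idx))) {
    ctr <- idx[r, ]
    d1 <- idx[, 1] - ctr[1]; d2 <- idx[, 2] - ctr[2]; d3 <- idx[, 3] - ctr[3]
    wt <- exp(-0.5 * ((d1 / sig_vox[1])^2 + (d2 / sig_vox[2])^2 +
                        (d3 / sig_vox[3])^2))
    wt[abs(d1) > rad[1] | abs(d2) > rad[2] | abs(d3) > rad[3]] <- 0
    oracle[ctr[1], ctr[2], ctr[3]] <- sum(wt * data[idx]) / sum(wt)
  }
  sm <- smooth_in_mask(vol, fwhm_mm = fwhm)
  expect_equal(sm$data[mask], oracle[mask], tolerance = 1e-10)
})

test_that("a deep spike's smoothed mass sums back to its value", {
  # mask wide enough that every voxel receiving mass has a fully interior
  # kernel (otherwise edge renormalization inflates the total)
  dims <- c(25, 25, 9)
  mask <- array(TRUE, dims)
  data <- array(0, dims)
  data[13, 13, 5] <- 4.2
  vol <- intensity_volume(data, mask, spacing = c(0.1, 0.1, 0.3))
  sm <- smooth_in_mask(vol, fwhm_mm = 0.3)
  expect_equal(sum(sm$data), 4.2, tolerance = 1e-9)
  expect_true(all(sm$data >= 0))
})

test_that("smoothing rejects invalid kernels", {
  vol <- make_lens_mask(c(0.5, 0.5, 0.5), spacing = c(0.1, 0.1, 0.1))
  expect_error(smooth_in_mask(vol, fwhm_mm = 0), "positive")
})

test_that("outlier rule flags only extreme sectors (direct quantile oracle)", {
  y <- c(1:9, 1000)
  rec <- data.frame(i = 0:9, j = 0, k = 0, x1 = (0:9 + 0.5) / 10,
                    x2 = 0.5, x3 = 0.5, y = y)
  g <- sector_grid(rec, "s", "m", shape = c(10, 1, 1))
  out <- exclude_outliers(g)
  ly <- log1p(y)
  cut <- median(ly) + 5 * IQR(ly)   # linear-interpolation quantiles
  expect_identical(out$included, !(ly > cut))
  expect_identical(which(!out$included), 10L)
})

test_that("outlier rule is idempotent on the surviving flags and handles ties/zeros", {
  set.seed(21)
  y <- c(rpois(98, 15), 0, 5000)
  rec <- expand.grid(i = 0:9, j = 0:9, k = 0)
  rec$x1 <- (rec$i + 0.5) / 10; rec$x2 <- (rec$j + 0.5) / 10; rec$x3 <- 0.5
  rec$y <- y
  g <- sector_grid(rec, "s", "m", shape = c(10, 10, 1))
  once <- exclude_outliers(g)
  again <- exclude_outliers(g)
  expect_identical(again$included, once$included)
  # a second pass never resurrects an excluded sector
  twice <- exclude_outliers(once)
  expect_true(all(once$included | !twice$included))

  allsame <- g
  allsame$y <- rep(4, nrow(g))
  expect_identical(exclude_outliers(allsame)$included, rep(TRUE, nrow(g)))

  withzero <- g
  withzero$y[1] <- 0
  expect_silent(exclude_outliers(withzero))
})
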