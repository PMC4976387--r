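test_that("distance map matches exhaustive nearest-background search", {
  set.seed(91)
  # random 2-D masks up to 12x12, plus degenerate shapes
  for (i in 1:25) {
    nr <- sample(2:12, 1); nc <- sample(2:12, 1)
    mask <- matrix(runif(nr * nc) > runif(1, 0.2, 0.8), nr, nc)
    if (!any(!mask)) mask[1, 1] <- FALSE
    expect_equal(exterior_distance_map(mask), brute_edt(mask))
  }
  # random small 3-D masks with anisotropic spacing
  for (i in 1:10) {
    dims <- c(sample(2:8, 1), sample(2:8, 1), sample(2:5, 1))
    mask <- array(runif(prod(dims)) > 0.4, dims)
    if (!any(!mask)) mask[1, 1, 1] <- FALSE
    sp <- c(1, 1.5, 3)
    expect_equal(exterior_distance_map(mask, spacing = sp),
                 brute_edt(mask, spacing = sp))
  }
})

test_that("hand-computable distance cases come out exact", {
  # 5x5 all-true except the border: center is 2 away
  m <- matrix(FALSE, 5, 5); m[2:4, 2:4] <- TRUE
  d <- exterior_distance_map(m)
  expect_equal(d[3, 3], 2.0)
  expect_equal(d[2, 2], 1.0) # nearest background is the orthogonal neighbor
  # single in-mask pixel: distance 1 to adjacent background
  m1 <- matrix(FALSE, 3, 3); m1[2, 2] <- TRUE
  expect_equal(exterior_distance_map(m1)[2, 2], 1.0)
  # anisotropic slab: background only below, spacing 3 on the z axis
  slab <- array(TRUE, c(4, 4, 3)); slab[, , 1] <- FALSE
  d3 <- exterior_distance_map(slab, spacing = c(1, 1, 3))
  expect_true(all(d3[, , 2] == 3))
  expect_true(all(d3[, , 3] == 6))
  expect_error(exterior_distance_map(array(TRUE, c(3, 3))), "exterior")
  expect_error(
    exterior_distance_map(rbind(c(FALSE, TRUE), c(TRUE, TRUE)),
                          spacing = c(1, -1)),
    "spacing")
})

test_that("distance map agrees with an independent 2-D implementation", {
  set.seed(92)
  mask <- matrix(runif(40 * 40) > 0.3, 40, 40)
  mask[1, ] <- FALSE
  d_pkg <- exterior_distance_map(mask)
  d_ebi <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1)))
  expect_equal(d_pkg, d_ebi, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("constant intensity yields a flat profile", {
  m <- matrix(FALSE, 20, 20); m[3:18, 3:18] <- TRUE
  d <- exterior_distance_map(m)
  prof <- profile_by_depth(matrix(7, 20, 20), d)
  means <- prof$profile$mean_intensity
  expect_true(all(abs(means[!is.na(means)] - 7) < 1e-12))
  expect_equal(prof$n_voxels, sum(m))
  expect_equal(sum(prof$profile$pixel_count), sum(m))
})

test_that("a distance ramp profiles onto its own bin centers", {
  m <- matrix(FALSE, 30, 30); m[2:29, 2:29] <- TRUE
  d <- exterior_distance_map(m)
  prof <- profile_by_depth(d, d, bin_width = 1)
  ok <- prof$profile$pixel_count > 0
  expect_true(all(abs(prof$profile$mean_intensity[ok] -
                        prof$profile$bin_center[ok]) <= 0.5))
  # per-bin averaging oracle
  idx <- ceiling(d[d > 0] / 1)
  for (b in which(ok)) {
    expect_equal(prof$profile$mean_intensity[b],
                 mean(d[d > 0][idx == b]))
  }
})

test_that("exclusion masks remove a bright blob from the profile", {
  m <- matrix(FALSE, 30, 30); m[2:29, 2:29] <- TRUE
  d <- exterior_distance_map(m)
  ramp <- d
  blob <- matrix(FALSE, 30, 30); blob[12:16, 12:16] <- TRUE
  bright <- ramp; bright[blob] <- 1e6
  with_blob <- profile_by_depth(bright, d)
  without <- profile_by_depth(bright, d, exclusion = blob)
  blob_bins <- unique(ceiling(d[blob & d > 0]))
  expect_gt(max(with_blob$profile$mean_intensity[blob_bins]), 1e5)
  ok <- without$profile$pixel_count > 0
  expect_true(all(abs(without$profile$mean_intensity[ok] -
                        without$profile$bin_center[ok]) <= 0.5))
  # profile is unchanged by the intensity of excluded voxels
  bright2 <- ramp; bright2[blob] <- -42
  expect_equal(profile_by_depth(bright2, d, exclusion = blob)$profile,
               without$profile)
  expect_equal(without$n_voxels, sum(d > 0) - sum(blob & d > 0))
  expect_error(profile_by_depth(ramp, d, bin_width = 0), "bin_width")
})

test_that("automatic cell masking isolates the dominant component", {
  img <- matrix(0, 64, 64)
  img[20:50, 20:50] <- 500   # the cell
  img[5:7, 5:7] <- 400       # small debris
  set.seed(93)
  img <- img + matrix(abs(rnorm(64^2, 0, 5)), 64)
  mask <- make_cell_mask(img, smooth_sigma = 1)
  expect_true(all(mask[25:45, 25:45]))
  expect_false(any(mask[1:10, 1:10]))
})
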