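test_that("otsu separates a perfectly bimodal image", {
  img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  t <- otsu_threshold(img)
  expect_gt(t, 10); expect_lt(t, 200)
  expect_error(otsu_threshold(matrix(5, 4, 4)), "distinct")
})

test_that("otsu equals exhaustive intra-class-variance minimization", {
  set.seed(71)
  for (i in 1:10) {
    vals <- c(rnorm(400, 100, 25), rnorm(200, 400, 60), runif(100, 0, 600))
    img <- matrix(vals, 35, 20)
    expect_equal(otsu_threshold(img), brute_otsu(vals), tolerance = 1e-12)
  }
})

test_that("otsu lands near the midpoint of a symmetric mixture", {
  set.seed(72)
  vals <- c(rnorm(1e5, 50, 25), rnorm(1e5, 200, 25))
  t <- otsu_threshold(matrix(vals, 500))
  bin_width <- diff(range(vals)) / 256
  expect_lt(abs(t - 125), 3 * bin_width)
})

test_that("otsu agrees with an independent implementation", {
  # EBImage computes the same criterion on [0,1]-scaled data
  set.seed(73)
  img <- matrix(runif(64^2)^2, 64)
  t_pkg <- otsu_threshold(img, n_bins = 256)
  t_ebi <- EBImage::otsu(EBImage::Image(img), range = range(img), levels = 256)
  expect_lt(abs(t_pkg - t_ebi), diff(range(img)) / 256)
})

test_that("percentile threshold follows the fraction-below convention", {
  vals <- matrix(1:100, 10, 10)
  expect_equal(percentile_threshold(vals, 0.5), 51)
  expect_equal(percentile_threshold(vals, 0.01), 2)
  expect_equal(percentile_threshold(vals, 0.95), 96)
  expect_error(percentile_threshold(vals, 0), "percentile")
  expect_error(percentile_threshold(vals, 1), "percentile")
})

test_that("percentile threshold resolves ties toward more pixels below", {
  set.seed(74)
  vals <- c(rep(0, 80), runif(20, 5, 10))
  img <- matrix(vals, 10, 10)
  t <- percentile_threshold(img, 0.5)
  expect_gt(t, 0)
  expect_equal(t, min(vals[vals > 0])) # just above the zero plateau
  expect_gte(mean(vals < t), 0.5)
  # attainable fraction is the smallest one >= the request
  expect_equal(mean(vals < t), 0.8)
  # request unattainable below the max: occupancy becomes empty
  expect_equal(percentile_threshold(matrix(c(0, 0, 0, 1), 2), 0.9), Inf)
})

test_that("occupancy tables count pixels into pattern cells", {
  m1 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  m2 <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  tab <- build_occupancy_table(list(m1, m2))
  expect_equal(tab$n_pixels, 4)
  expect_equal(unname(tab$counts[c("11", "10", "01", "00")]), c(1, 0, 1, 2))
  # all-false masks put all mass in the all-zero pattern
  tab0 <- build_occupancy_table(list(m1 & FALSE, m2 & FALSE))
  expect_equal(unname(tab0$counts["00"]), 4)
  expect_error(build_occupancy_table(list(m1)), "at least 2")
})

test_that("random occupancy tables match a per-pixel tally oracle", {
  set.seed(75)
  for (k in 2:4) {
    masks <- lapply(seq_len(k), function(i) matrix(runif(15 * 11) > 0.4, 15, 11))
    valid <- matrix(runif(15 * 11) > 0.1, 15, 11)
    tab <- build_occupancy_table(masks, valid = valid)
    # oracle: loop every pixel, build its pattern string, count
    tallies <- table(apply(
      do.call(cbind, lapply(masks, function(m) as.integer(m[valid]))),
      1, paste, collapse = ""))
    for (pat in names(tallies)) {
      expect_equal(unname(tab$counts[pat]), unname(as.integer(tallies[pat])))
    }
    expect_equal(tab$n_pixels, sum(valid))
    expect_equal(sum(tab$counts), sum(valid))
    # marginals recovered from pattern sums
    for (c_i in seq_len(k)) {
      expect_equal(marginal_occupied(tab, c_i), sum(masks[[c_i]][valid]))
    }
  }
})

test_that("degrees of freedom follow 2^k - 1 - k", {
  set.seed(76)
  for (k in 2:6) {
    masks <- lapply(seq_len(k), function(i) matrix(runif(40 * 40) > 0.5, 40, 40))
    res <- chi2_mutual_independence(build_occupancy_table(masks))
    expect_equal(res$df, 2^k - 1 - k)
  }
})

test_that("a table built from exact products gives statistic 0 and p 1", {
  # 2 channels, marginals 1/2 each, joint exactly the product
  pattern <- rep(c("11", "10", "01", "00"), each = 100)
  m1 <- matrix(substr(pattern, 1, 1) == "1", 20, 20)
  m2 <- matrix(substr(pattern, 2, 2) == "1", 20, 20)
  res <- chi2_mutual_independence(build_occupancy_table(list(m1, m2)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("the 2x2 case matches hand computation and stats::chisq.test", {
  counts <- c("11" = 30, "10" = 20, "01" = 20, "00" = 30)
  pattern <- rep(names(counts), counts)
  m1 <- matrix(substr(pattern, 1, 1) == "1", 10, 10)
  m2 <- matrix(substr(pattern, 2, 2) == "1", 10, 10)
  res <- chi2_mutual_independence(build_occupancy_table(list(m1, m2)))
  expect_equal(res$statistic, 4.0)
  expect_equal(res$df, 1)
  ref <- suppressWarnings(
    chisq.test(matrix(c(30, 20, 20, 30), 2), correct = FALSE))
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
})

test_that("degenerate marginals are refused and sparse cells flagged", {
  m1 <- matrix(TRUE, 5, 5)
  m2 <- matrix(runif(25) > 0.5, 5, 5)
  expect_error(chi2_mutual_independence(build_occupancy_table(list(m1, m2))),
               "marginal")
  set.seed(77)
  masks <- lapply(1:3, function(i) matrix(runif(36) > 0.9, 6, 6))
  masks[[1]][1:4] <- TRUE; masks[[2]][2:5] <- TRUE; masks[[3]][3:6] <- TRUE
  tab <- build_occupancy_table(masks)
  res <- chi2_mutual_independence(tab)
  expect_gt(res$low_expected_cells, 0)
  expect_equal(res$min_expected, min(res$expected))
})

test_that("engineered parity-independent channels give ratio exactly 1", {
  n <- 40
  rowpar <- matrix(rep(seq_len(n) %% 2, n), n, n) * 100
  colpar <- t(matrix(rep(seq_len(n) %% 2, n), n, n)) * 100
  sweep <- exceedance_sweep(list(rowpar, colpar),
                            percentiles = c(0.05, 0.2, 0.35, 0.5))
  expect_true(all(sweep$curve$ratio == 1))
})

test_that("identical channels give ratio 1/P(occupied)^(k-1)", {
  img <- structured_image(48, seed = 78)
  for (k in 2:3) {
    sweep <- exceedance_sweep(rep(list(img), k),
                              percentiles = c(0.3, 0.6, 0.9),
                              subsets = list(seq_len(k)))
    for (i in seq_len(nrow(sweep$curve))) {
      p <- sweep$curve$percentile[i]
      t <- percentile_threshold(img, p)
      p_occ <- mean(img >= t)
      expect_equal(sweep$curve$ratio[i], 1 / p_occ^(k - 1))
      expect_gte(sweep$curve$ratio[i], 1)
    }
  }
})

test_that("the default sweep spans 1% to 95%", {
  img1 <- structured_image(24, seed = 79)
  img2 <- structured_image(24, seed = 80)
  sweep <- exceedance_sweep(list(img1, img2))
  expect_equal(min(sweep$percentiles), 0.01)
  expect_equal(max(sweep$percentiles), 0.95)
  expect_error(exceedance_sweep(list(img1, img2), subsets = list()), "subset")
  expect_error(exceedance_sweep(list(img1, img2), percentiles = c(0, 0.5)),
               "percentiles")
})

test_that("zero-marginal percentiles are recorded missing, never 0 or Inf", {
  # 90% zero plateau: sweeping below 0.9 leaves occupancy, above empties it
  img <- matrix(0, 20, 20); img[1:40] <- 15
  sweep <- exceedance_sweep(list(img, img), percentiles = c(0.5, 0.93))
  r_low <- sweep$curve$ratio[sweep$curve$percentile == 0.5]
  r_high <- sweep$curve$ratio[sweep$curve$percentile == 0.93]
  expect_true(is.finite(r_low))
  expect_true(is.na(r_high))
})
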