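test_that("invalid configurations are rejected", {
  expect_error(scene_config(label_prob = 1.2), "label_prob")
  expect_error(scene_config(residual_fraction = 1), "residual_fraction")
  expect_error(scene_config(psf_sigma = 0), "psf_sigma")
  expect_error(scene_config(image_shape = c(0, 10)), "image_shape")
  expect_error(scene_config(channel_affinities = c(0.5, -0.1)),
               "channel_affinities")
})

test_that("without domains every site belongs to exactly one channel", {
  cfg <- small_scene_config(seed = 4, n_domains = 0L, background_site_rate = 40L)
  sc <- generate_scene(cfg)
  expect_true(all(rowSums(sc$membership) == 1))
  # joint membership across any channel pair is impossible by construction
  for (a in 1:2) for (b in (a + 1):3) {
    expect_equal(sum(sc$membership[, a] & sc$membership[, b]), 0)
  }
  expect_true(all(is.na(sc$domain)))
})

test_that("certain affinities make every domain site a member of every channel", {
  cfg <- small_scene_config(seed = 5, channel_affinities = c(1, 1, 1),
                            n_domains = 5L, background_site_rate = 0L)
  sc <- generate_scene(cfg)
  expect_true(all(sc$membership))
})

test_that("triple-membership fraction matches the product of affinities", {
  cfg <- scene_config(image_shape = c(256L, 256L), n_sites = 1000L,
                      n_domains = 30L, channel_affinities = c(0.8, 0.8, 0.8),
                      background_site_rate = 0L, seed = 42)
  sc <- generate_scene(cfg)
  frac <- mean(rowSums(sc$membership) == 3)
  p <- 0.8^3
  tol <- 3 * sqrt(p * (1 - p) / 1000)
  expect_lt(abs(frac - p), tol)
})

test_that("scene and renders are bit-identical under a fixed seed", {
  cfg <- small_scene_config(seed = 9)
  sc1 <- generate_scene(cfg); sc2 <- generate_scene(cfg)
  expect_identical(sc1, sc2)
  r1 <- render_round(sc1, cfg, 2); r2 <- render_round(sc2, cfg, 2)
  expect_identical(r1, r2)
  p1 <- render_round(sc1, cfg, 1, post_elution = TRUE)
  p2 <- render_round(sc1, cfg, 1, post_elution = TRUE)
  expect_identical(p1, p2)
})

test_that("nothing labeled, no background, no noise gives a zero image", {
  cfg <- small_scene_config(seed = 2, label_prob = 0, noise_sigma = 0,
                            background_amplitude = 0)
  sc <- generate_scene(cfg)
  imgs <- render_round(sc, cfg, 1)
  expect_true(all(vapply(imgs, function(im) all(im == 0), TRUE)))
  expect_error(render_round(sc, cfg, 0), "round_index")
})

test_that("post-elution residual matches residual_fraction in expectation", {
  ratios <- vapply(1:40, function(s) {
    cfg <- small_scene_config(seed = 100 + s, noise_sigma = 0,
                              background_amplitude = 0,
                              residual_fraction = 0.055)
    sc <- generate_scene(cfg)
    pre <- render_round(sc, cfg, 1)$ch1
    post <- render_round(sc, cfg, 1, post_elution = TRUE)$ch1
    sum(post) / sum(pre)
  }, 0)
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 0.055), 3 * se + 1e-3)
})

test_that("per-round labeled-site counts are calibrated to label_prob", {
  # over 100 seeds the pooled labeled count is Binomial(total_avail, q)
  q <- 0.7
  total_avail <- 0
  total_labeled <- 0
  for (s in 1:100) {
    cfg <- small_scene_config(seed = 1000 + s, label_prob = q)
    sc <- generate_scene(cfg)
    avail <- sum(sc$membership[, 1])
    lab <- length(cycloc:::labeled_sites(sc, cfg, 1, 1))
    total_avail <- total_avail + avail
    total_labeled <- total_labeled + lab
  }
  expect_lt(abs(total_labeled - q * total_avail),
            3 * sqrt(total_avail * q * (1 - q)))
})

test_that("round gain and cumulative drift shape successive rounds", {
  cfg <- small_scene_config(seed = 6, noise_sigma = 0,
                            background_amplitude = 0, label_prob = 1,
                            spot_amplitude = 2000, # keep overlaps clear of 16-bit clipping
                            round_gain = 1.2, drift_per_round = c(3, -2))
  sc <- generate_scene(cfg)
  r1 <- render_round(sc, cfg, 1)$ch1
  r2 <- render_round(sc, cfg, 2)$ch1
  # with certain labeling, round 2 is the gain-scaled translate of round 1
  r1_shifted <- translate_int(r1, 3, -2) * 1.2
  interior <- matrix(FALSE, 96, 96); interior[12:85, 12:85] <- TRUE
  expect_lt(max(abs((r2 - r1_shifted)[interior])), 1e-6 * max(r1))
})
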