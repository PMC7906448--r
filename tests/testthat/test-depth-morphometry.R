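test_that("depth_to_hue handles colorized and raw inputs", {
  red <- array(0L, c(3, 4, 3))
  red[, , 1] <- 255L
  expect_true(all(depth_to_hue(red) == 0L))
  green <- array(0L, c(3, 4, 3))
  green[, , 2] <- 255L
  expect_true(all(depth_to_hue(green) == round(255 / 3)))

  # raw metric map: floor vs body separate cleanly under Otsu
  d <- matrix(2250L, 100, 120)
  d[40:60, 50:90] <- 1750L
  hue <- depth_to_hue(d)
  expect_true(all(hue %in% 0:255))
  seg <- segment_largest(hue, opening_diameter = 1)
  expect_equal(seg$area_px, 21 * 41)

  # degenerate constant map normalizes to zero
  expect_true(all(depth_to_hue(matrix(5L, 3, 3)) == 0L))
})

test_that("mask centroid uses first moments with half-up rounding", {
  m <- matrix(FALSE, 20, 20)
  m[1:10, 1:10] <- TRUE  # pixels 0..9 in both axes, centroid (4.5, 4.5)
  expect_equal(centroid_of_mask(m), c(x = 5L, y = 5L))
  one <- matrix(FALSE, 10, 10)
  one[4, 8] <- TRUE  # 0-based (x = 7, y = 3)
  expect_equal(centroid_of_mask(one), c(x = 7L, y = 3L))
  expect_error(centroid_of_mask(matrix(FALSE, 3, 3)),
               class = "pigmorph_no_object")

  # centred synthetic ellipse: centroid within 1 px of the true centre
  cfg <- scene_config(depth_noise_sd = 0, tail_length_px = 0.01,
                      tail_width_px = 0)
  tr <- frame_truth(center = c(424, 240), orientation = 0)
  seg <- segment_largest(to_grayscale(render_frame(cfg, tr)$rgb))
  ctr <- centroid_of_mask(seg$mask)
  expect_lte(max(abs(ctr - c(424, 240))), 1)
})

test_that("centroid depth sampling ignores invalid pixels", {
  d <- matrix(1750L, 20, 20)
  expect_equal(sample_centroid_depth(d, c(x = 10, y = 10)), 1.750)
  d[10, 10] <- 0L  # dead pixel inside the 5x5 window
  expect_equal(sample_centroid_depth(d, c(x = 10, y = 10)), 1.750)
  dz <- matrix(0L, 20, 20)
  expect_error(sample_centroid_depth(dz, c(x = 10, y = 10)),
               class = "pigmorph_invalid_depth")
  expect_error(sample_centroid_depth(d, c(x = 100, y = 10)), "outside")
})

test_that("height is the camera height minus the centroid depth", {
  expect_equal(height_from_depth(1.75, 2.25), 0.5)
  expect_equal(height_from_depth(2.00, 2.25), 0.25)
  expect_error(height_from_depth(2.25, 2.25),
               class = "pigmorph_invalid_depth")
})

test_that("noiseless frames recover the true height to the millimeter", {
  cfg <- scene_config(depth_noise_sd = 0, pig_height = 0.5)
  tr <- frame_truth(center = c(424, 240), orientation = 65,
                    true_height = 0.5)
  fp <- render_frame(cfg, tr)
  hm <- measure_height_frame(fp$depth_mm)
  expect_equal(hm$qc, "OK")
  expect_lt(abs(hm$centroid_depth_m - (2.25 - 0.5)), 0.001)
  expect_lt(abs(hm$height_m - 0.5), 0.001)
})

test_that("2-means posture clustering matches the exhaustive oracle", {
  h <- c(0.50, 0.51, 0.49, 0.30, 0.29)
  cl <- cluster_postures(h)
  expect_false(cl$merged)
  expect_equal(which(cl$labels == 1L), 1:3)
  expect_equal(cl$standing_median, 0.50)

  # degenerate inputs merge
  flat <- cluster_postures(rep(0.40, 6))
  expect_true(flat$merged)
  expect_equal(flat$standing_median, 0.40)
  single <- cluster_postures(0.37)
  expect_true(single$merged)

  # two points: singleton clusters, standing is the higher
  two <- cluster_postures(c(0.50, 0.30))
  expect_false(two$merged)
  expect_equal(two$standing_median, 0.50)

  # against the exhaustive two-segment partition for n <= 12
  set.seed(99)
  for (i in 1:40) {
    n <- sample(3:12, 1)
    x <- round(runif(n, 0.2, 0.6), 3)
    if (length(unique(x)) < 2) next
    cl <- cluster_postures(x, seed = i)
    if (cl$merged) next
    oracle <- best_split_1d(x)
    # identical partitions up to label swap
    expect_true(all(cl$labels == oracle$labels) ||
                  all(cl$labels == 3L - oracle$labels))
  }
})

test_that("video height tracks the standing cluster", {
  # 60% standing at 0.5 m, 40% sitting, 5 mm depth noise
  cfg <- scene_config(standing_fraction = 0.6, border_fraction = 0,
                      blur_fraction = 0, depth_noise_sd = 5,
                      pig_height = 0.5)
  v <- simulate_video(cfg, 80, seed = 12)
  hv <- video_height(v, seed = 5)
  expect_lt(abs(hv$height_m - 0.5), 0.01)
  expect_false(hv$merged)
  expect_equal(hv$n_used, 80)

  # all-standing noiseless video: exact
  cfg0 <- scene_config(standing_fraction = 1, border_fraction = 0,
                       blur_fraction = 0, depth_noise_sd = 0,
                       pig_height = 0.45)
  v0 <- simulate_video(cfg0, 12, seed = 2)
  hv0 <- video_height(v0, seed = 1)
  expect_equal(hv0$height_m, 0.45, tolerance = 1e-6)

  # empty pen: no valid frames
  empty <- replicate(4, matrix(2250L, 120, 160), simplify = FALSE)
  expect_error(video_height(empty), class = "pigmorph_no_valid_frames")
})

test_that("height estimate is position-invariant and monotone", {
  cfg <- scene_config(depth_noise_sd = 0, pig_height = 0.5)
  hs <- sapply(list(c(300, 200), c(500, 300), c(424, 150)), function(ctr) {
    tr <- frame_truth(center = ctr, orientation = 10)
    measure_height_frame(render_frame(cfg, tr)$depth_mm)$height_m
  })
  expect_lt(diff(range(hs)), 0.001)

  delta <- 0.07
  cfg2 <- scene_config(depth_noise_sd = 0, pig_height = 0.5 + delta)
  tr <- frame_truth(center = c(424, 240), true_height = 0.5 + delta)
  h2 <- measure_height_frame(render_frame(cfg2, tr)$depth_mm)$height_m
  expect_lt(abs(h2 - (0.5 + delta)), 0.002)
})
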