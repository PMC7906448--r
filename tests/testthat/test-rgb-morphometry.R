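test_that("grayscale conversion is luminance-weighted and validated", {
  black <- array(0L, c(4, 5, 3))
  expect_true(all(to_grayscale(black) == 0L))
  white <- array(255L, c(4, 5, 3))
  expect_true(all(to_grayscale(white) == 255L))
  flat <- array(100L, c(4, 5, 3))
  expect_true(all(to_grayscale(flat) == 100L))
  colored <- array(0L, c(1, 1, 3))
  colored[1, 1, ] <- c(255L, 0L, 0L)
  expect_equal(to_grayscale(colored)[1, 1], as.integer(round(0.299 * 255)))
  expect_error(to_grayscale(matrix(0, 3, 3)), "H x W x 3")
})

test_that("segmentation keeps the largest object and removes the tail", {
  cfg <- scene_config(depth_noise_sd = 0, tail_length_px = 30,
                      tail_width_px = 5)
  tr <- frame_truth(center = c(400, 240), orientation = 0,
                    true_length = 200, true_width = 80)
  fp <- render_frame(cfg, tr)
  seg <- segment_largest(to_grayscale(fp$rgb))
  oracle <- oracle_ellipse_area(100, 40, 400, 240, 0, 848, 480)
  expect_lt(abs(seg$area_px - oracle) / oracle, 0.05)
  # tail tip (beyond the +x pole of the ellipse) must be gone after opening
  expect_false(seg$mask[241, 400 + 100 + 20])
  # ... although it was rendered
  expect_equal(fp$rgb[241, 400 + 100 + 20, 1], cfg$pig_gray)

  # uniform image: nothing to segment
  expect_error(segment_largest(matrix(128L, 50, 60)),
               class = "pigmorph_no_object")

  # two blobs: only the larger is retained
  g <- gray_with_blobs(200, 300, list(c(50, 149, 40, 89),    # 100x50 = 5000
                                      c(20, 39, 200, 224)))  # 20x25 = 500
  seg2 <- segment_largest(g, opening_diameter = 1)
  expect_equal(seg2$area_px, 5000)
  expect_true(seg2$mask[100, 60])
  expect_false(seg2$mask[30, 210])
})

test_that("segmentation agrees with EBImage on threshold and components", {
  g <- gray_with_blobs(120, 160, list(c(30, 89, 40, 119), c(5, 14, 5, 14)),
                       fg = 180L, bg = 60L)
  seg <- segment_largest(g, opening_diameter = 1)
  img <- EBImage::Image(t(g) / 255)
  thr <- EBImage::otsu(img, range = c(0, 1), levels = 256)
  expect_lte(abs(seg$threshold / 255 - thr), 2 / 255)
  # both thresholds induce the same foreground
  expect_equal(sum(g > seg$threshold), sum(img > thr))
  lab <- EBImage::bwlabel(img > thr)
  areas <- table(lab[lab > 0])
  expect_equal(seg$area_px, max(areas))
})

test_that("opening matches EBImage's disc opening on a thin-tailed blob", {
  cfg <- scene_config(depth_noise_sd = 0)
  tr <- frame_truth(center = c(400, 240), orientation = 25,
                    true_length = 180, true_width = 76)
  g <- to_grayscale(render_frame(cfg, tr)$rgb)
  seg <- segment_largest(g, opening_diameter = 15)
  img <- EBImage::Image(t(g) / 255)
  bin <- img > EBImage::otsu(img, range = c(0, 1), levels = 256)
  op <- EBImage::opening(bin, EBImage::makeBrush(15, "disc"))
  # the two disc discretizations differ slightly at the rim
  expect_lt(abs(seg$area_px - sum(op)) / sum(op), 0.02)
})

test_that("minimum-area rectangle matches examples and the grid oracle", {
  box <- rotated_box(rect_contour(100, 40, 0, 200, 120))
  lw <- canonical_length_width(box)
  expect_equal(unname(lw), c(100, 40))
  expect_true(min(box$angle %% 90, 90 - box$angle %% 90) < 1e-6)

  box30 <- rotated_box(rect_contour(100, 40, 30, 200, 120))
  lw30 <- canonical_length_width(box30)
  expect_lt(max(abs(lw30 - c(100, 40))), 1)

  for (ang in c(0, 30, 77, 151)) {
    be <- rotated_box(ellipse_contour(100, 40, ang, 300, 200))
    lwe <- canonical_length_width(be)
    expect_lt(max(abs(lwe - c(200, 80))), 2)
  }

  # agreement with the 0.1-degree rotating-calipers brute force
  set.seed(42)
  for (i in 1:25) {
    pts <- matrix(runif(2 * sample(5:50, 1), 0, 100), ncol = 2)
    lw_fast <- canonical_length_width(rotated_box(pts))
    expect_true(min_rect_agrees(lw_fast, oracle_min_rect(pts)))
  }

  expect_error(rotated_box(cbind(1:5, 2 * (1:5))), "collinear")
  expect_error(rotated_box(cbind(1, 2)), "3 points")
})

test_that("canonical length/width orders the sides", {
  b <- rotated_box(rect_contour(30, 80))
  expect_equal(unname(canonical_length_width(b)), c(80, 30))
  b2 <- rotated_box(rect_contour(50, 50))
  expect_equal(unname(canonical_length_width(b2)), c(50, 50))
})

test_that("border attachment uses corners against a margin", {
  mk <- function(x0, y0, w, h) {
    rotated_box(cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h)))
  }
  dims <- c(480, 848)
  expect_false(border_attached(mk(10, 10, 100, 50), dims, 2))
  b0 <- mk(0.5, 10, 100, 50)   # corner at x = 0 after footprint padding
  expect_true(border_attached(b0, dims, 2))
  b1 <- mk(1.5, 10, 100, 50)   # corner at x = 1, margin 2
  expect_true(border_attached(b1, dims, 2))
  b3 <- mk(3.5, 10, 100, 50)   # corner at x = 3, outside the margin
  expect_false(border_attached(b3, dims, 2))
})

test_that("area range check is a fraction of the frame", {
  dims <- c(480, 848)
  expect_true(area_in_range(8000, 0.01, 0.40, dims))
  expect_false(area_in_range(100, 0.01, 0.40, dims))
  expect_false(area_in_range(prod(dims), 0.01, 0.40, dims))
  expect_error(area_in_range(10, 0.5, 0.4, dims))
})

test_that("measure_frame applies QC in order and recovers the truth", {
  cfg <- scene_config(depth_noise_sd = 0)
  tr <- frame_truth(center = c(420, 240), orientation = 40,
                    true_length = 200, true_width = 80)
  m <- measure_frame(render_frame(cfg, tr))
  expect_equal(m$qc, "OK")
  expect_lt(abs(m$length_px - 200), 2)
  expect_lt(abs(m$width_px - 80), 2)

  trb <- frame_truth(center = c(5, 240), touches_border = TRUE,
                     true_length = 200, true_width = 80)
  mb <- measure_frame(render_frame(cfg, trb))
  expect_equal(mb$qc, "BORDER_ATTACHED")
  expect_true(is.na(mb$length_px))

  # blob covering ~half the frame fails the 40% area ceiling
  g <- gray_with_blobs(100, 100, list(c(11, 85, 11, 76)))  # 4950 px of 10^4
  fp <- frame_pair(array(g, c(100, 100, 3)), NULL, 1L)
  ma <- measure_frame(fp)
  expect_equal(ma$qc, "AREA_OUT_OF_RANGE")

  # empty pen
  fe <- frame_pair(array(70L, c(100, 100, 3)), NULL, 1L)
  expect_equal(measure_frame(fe)$qc, "NO_OBJECT")
})

test_that("median aggregation is robust and errors on empty input", {
  m <- data.frame(frame = 1:3, qc = "OK", length_px = c(100, 101, 250),
                  width_px = c(40, 41, 90), area_px = 1)
  agg <- aggregate_length_width(m)
  expect_equal(agg$median_length_px, 101)
  expect_equal(agg$n_used, 3)

  one <- data.frame(frame = 1:2, qc = c("OK", "BORDER_ATTACHED"),
                    length_px = c(120, NA), width_px = c(50, NA), area_px = 1)
  agg1 <- aggregate_length_width(one)
  expect_equal(agg1$median_length_px, 120)
  expect_equal(agg1$median_width_px, 50)
  expect_equal(agg1$n_used, 1)

  bad <- data.frame(frame = 1, qc = "NO_OBJECT", length_px = NA,
                    width_px = NA, area_px = NA)
  expect_error(aggregate_length_width(bad),
               class = "pigmorph_no_valid_frames")

  # contamination bound: with < 50% contaminated frames the aggregate lies
  # between the clean extremes
  clean <- rnorm(60, 200, 0.5)
  dirty <- rnorm(40, 260, 10)
  mm <- data.frame(frame = 1:100, qc = "OK", length_px = c(clean, dirty),
                   width_px = 80, area_px = 1)
  med <- aggregate_length_width(mm)$median_length_px
  expect_gte(med, min(clean))
  expect_lte(med, max(dirty))
})

test_that("measurement is rotation-invariant and scale-equivariant", {
  cfg <- scene_config(depth_noise_sd = 0)
  angs <- seq(0, 170, by = 10)
  lens <- wids <- numeric(length(angs))
  for (i in seq_along(angs)) {
    tr <- frame_truth(center = c(420, 240), orientation = angs[i],
                      true_length = 200, true_width = 84)
    m <- measure_frame(render_frame(cfg, tr))
    expect_equal(m$qc, "OK")
    lens[i] <- m$length_px
    wids[i] <- m$width_px
  }
  expect_lt(diff(range(lens)), 2)
  expect_lt(diff(range(wids)), 2)

  tr1 <- frame_truth(center = c(420, 240), orientation = 30,
                     true_length = 130, true_width = 54)
  tr2 <- frame_truth(center = c(420, 240), orientation = 30,
                     true_length = 260, true_width = 108)
  m1 <- measure_frame(render_frame(cfg, tr1))
  m2 <- measure_frame(render_frame(cfg, tr2))
  expect_lt(abs(m2$length_px / m1$length_px - 2), 0.02 * 2)
  expect_lt(abs(m2$width_px / m1$width_px - 2), 0.02 * 2)
})

test_that("streaming video measurement equals the per-frame path", {
  cfg <- scene_config(border_fraction = 0.2, blur_fraction = 0.2)
  v <- simulate_video(cfg, 40, seed = 21)
  fast <- measure_video(v)
  slow <- measure_video(lapply(1:40, function(i) get_frame(v, i)))
  expect_equal(fast$qc, slow$qc)
  ok <- fast$qc == "OK"
  expect_equal(fast$length_px[ok], slow$length_px[ok])
  expect_equal(fast$width_px[ok], slow$width_px[ok])
})

test_that("QC is sound on synthetic videos", {
  cfg <- scene_config(border_fraction = 0.25, blur_fraction = 0,
                      depth_noise_sd = 0)
  v <- simulate_video(cfg, 300, seed = 31)
  m <- measure_video(v)
  flagged <- v$truth$touches_border
  expect_true(all(m$qc[flagged] %in%
                    c("BORDER_ATTACHED", "NO_OBJECT", "AREA_OUT_OF_RANGE")))
  # no interior noiseless unblurred frame is rejected
  interior <- !flagged & !v$truth$blurred
  expect_true(all(m$qc[interior] == "OK"))
})
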