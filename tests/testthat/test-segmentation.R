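test_that("fixed thresholding selects the stated side of the cut", {
  r <- matrix(0, 10, 10)
  r[4, 7] <- 200
  m <- threshold_residual(r, "fixed", value = 50, polarity = "bright")
  expect_identical(which(m$pixels), which(r == 200))
  expect_equal(m$threshold_used, 50)
  expect_false(any(threshold_residual(matrix(0, 5, 5), "fixed",
                                      value = 1)$pixels))
  dark <- threshold_residual(r, "fixed", value = 50, polarity = "dark")
  expect_equal(sum(dark$pixels), 99)
})

test_that("Otsu equals the exhaustive between-class-variance search", {
  # two-level image: 40 px at 10, 24 px at 200
  img <- matrix(c(rep(10, 40), rep(200, 24)), 8, 8)
  t <- otsu_threshold(img)
  expect_equal(t, oracle_otsu(img))
  expect_gt(t, 10); expect_lt(t, 200)
  m <- threshold_residual(img, "otsu", polarity = "bright")
  expect_equal(sum(m$pixels), 24)

  set.seed(5)
  for (i in 1:25) {
    x <- matrix(sample(0:255, 256, TRUE), 16, 16)
    expect_equal(otsu_threshold(x), oracle_otsu(x))
  }
  # low-dynamic-range images too
  for (i in 1:10) {
    x <- matrix(sample(0:7, 256, TRUE), 16, 16)
    expect_equal(otsu_threshold(x), oracle_otsu(x))
  }
  expect_error(otsu_threshold(matrix(3, 4, 4)),
               class = "microcensus_degenerate_error")
})

test_that("bright-polarity foreground shrinks as the threshold rises", {
  set.seed(6)
  r <- matrix(sample(0:255, 400, TRUE), 20, 20)
  counts <- vapply(seq(0, 250, by = 10), function(t)
    sum(threshold_residual(r, "fixed", value = t)$pixels), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("labeling honours connectivity and matches the flood-fill oracle", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_equal(label_particles(m, 8)$n, 1)
  expect_equal(label_particles(m, 4)$n, 2)
  expect_equal(label_particles(matrix(FALSE, 4, 4))$n, 0)

  # k disjoint filled squares
  big <- matrix(FALSE, 30, 30)
  for (k in 0:3) big[(k * 7 + 1):(k * 7 + 3), 11:13] <- TRUE
  expect_equal(label_particles(big, 8)$n, 4)

  set.seed(9)
  for (i in 1:20) {
    nr <- sample(5:32, 1); nc <- sample(5:32, 1)
    mask <- matrix(stats::runif(nr * nc) < 0.4, nr, nc)
    for (conn in c(4, 8)) {
      got <- label_particles(mask, conn)$labels
      expect_identical(strip_attr(got), strip_attr(oracle_label(mask, conn)))
    }
  }
})

test_that("measurements report physical units from the calibration", {
  scale <- scale_calibration(10)
  lab <- matrix(0L, 20, 20)
  lab[6:15, 6:15] <- 1L  # 10x10 px = 1 mm^2 at 10 px/mm
  rec <- measure_particles(lab, matrix(100, 20, 20), scale)
  expect_equal(rec$area_mm2, 1.0)
  expect_equal(rec$centroid_row, 10.5)
  expect_equal(rec$centroid_col, 10.5)
  expect_equal(rec$mean_intensity, 100)
  expect_equal(rec$bbox_min_row, 6); expect_equal(rec$bbox_max_row, 16)
  expect_false(rec$touches_edge)

  one <- matrix(0L, 5, 5); one[3, 4] <- 1L
  r1 <- measure_particles(one, matrix(0, 5, 5), scale)
  expect_equal(r1$area_mm2, 1 / 100)
  expect_equal(c(r1$centroid_row, r1$centroid_col), c(3, 4))
  expect_gt(r1$length_mm, 0)

  expect_error(measure_particles(lab, matrix(0, 20, 20), "oops"),
               "calibrat", class = "microcensus_validation_error")
})

test_that("particle length is the moment-ellipse major axis", {
  scale <- scale_calibration(1)
  lab <- matrix(0L, 40, 40)
  lab[5:8, 6:35] <- 1L  # 4 x 30 rectangle, long axis along columns
  rec <- measure_particles(lab, matrix(0, 40, 40), scale)
  # closed form: variance of 30 unit pixels = (30^2-1)/12 + 1/12 = 75
  expect_equal(rec$length_px, 4 * sqrt(75), tolerance = 1e-12)
  # and a rendered 3:1 ellipse measures close to its true length
  px <- microcensus:::ellipse_pixels(30, 30, 12, 4, pi / 5, 60, 60)
  lab2 <- matrix(0L, 60, 60); lab2[px] <- 1L
  rec2 <- measure_particles(lab2, matrix(0, 60, 60), scale)
  expect_equal(rec2$length_px, 24, tolerance = 0.06)
})

test_that("measurements are translation-invariant", {
  scale <- scale_calibration(2)
  base <- matrix(0L, 30, 30)
  px <- microcensus:::ellipse_pixels(10, 12, 6, 2, 0.7, 30, 30)
  base[px] <- 1L
  shift <- matrix(0L, 30, 30)
  shift[7:30, 5:30] <- base[1:24, 1:26]  # translate by (+6, +4)
  a <- measure_particles(base, matrix(0, 30, 30), scale)
  b <- measure_particles(shift, matrix(0, 30, 30), scale)
  expect_equal(b$centroid_row, a$centroid_row + 6)
  expect_equal(b$centroid_col, a$centroid_col + 4)
  expect_equal(b$area_mm2, a$area_mm2)
  expect_equal(b$length_mm, a$length_mm)
})

test_that("summed particle areas equal the foreground pixel count", {
  set.seed(10)
  scale <- scale_calibration(1)
  for (i in 1:5) {
    mask <- matrix(stats::runif(900) < 0.3, 30, 30)
    lab <- label_particles(mask, 8)
    rec <- measure_particles(lab, matrix(0, 30, 30), scale)
    expect_equal(sum(rec$area_px), sum(mask))
  }
})

test_that("mean colour is carried per particle from RGB frames", {
  lab <- matrix(0L, 6, 6); lab[2:3, 2:3] <- 1L
  frame <- array(0, c(6, 6, 3))
  frame[, , 1] <- 200; frame[, , 2] <- 50; frame[, , 3] <- 10
  rec <- measure_particles(lab, frame, scale_calibration(1))
  expect_equal(c(rec$mean_r, rec$mean_g, rec$mean_b), c(200, 50, 10))
})

test_that("particle filtering gates size, region and edge contact", {
  rec <- data.frame(area_mm2 = c(0.5, 1.5, 3.0),
                    centroid_row = c(5, 10, 40),
                    centroid_col = c(5, 10, 40),
                    touches_edge = c(TRUE, FALSE, FALSE))
  expect_equal(filter_particles(rec, 0, Inf), rec)
  expect_equal(filter_particles(rec, 1, 2)$area_mm2, 1.5)
  roi <- roi_rect(1, 1, 20, 20)
  expect_equal(nrow(filter_particles(rec, 0, Inf, roi = roi)), 2)
  expect_equal(nrow(filter_particles(rec, 0, Inf, exclude_edge = TRUE)), 2)
  expect_error(filter_particles(rec, 2, 1),
               class = "microcensus_validation_error")
})

test_that("rois answer membership for all three shapes", {
  expect_equal(roi_contains(roi_rect(2, 2, 5, 5), c(2, 4.9, 5), c(2, 2, 2)),
               c(TRUE, TRUE, FALSE))
  expect_equal(roi_contains(roi_disk(10, 10, 3), c(10, 10), c(12.9, 13.5)),
               c(TRUE, FALSE))
  tri <- roi_polygon(c(0, 10, 0), c(0, 0, 10))
  expect_true(roi_contains(tri, 2, 2))
  expect_false(roi_contains(tri, 9, 9))
})

test_that("scale calibration derives pixels/mm from a reference square", {
  bg <- matrix(200, 100, 100)
  bg[26:75, 31:80] <- 10  # 50x50 px black square
  cal <- calibrate_scale(bg, reference_side_mm = 5)
  expect_equal(cal$pixels_per_mm, 10)
  expect_equal(cal$source, "reference_square")

  expect_error(calibrate_scale(matrix(255, 50, 50), 5),
               class = "microcensus_calibration_error")

  # 40x41 dark blob, side 4 mm -> sqrt(1640)/4
  bg2 <- matrix(200, 100, 100)
  bg2[10:49, 10:50] <- 12
  expect_equal(calibrate_scale(bg2, 4)$pixels_per_mm, sqrt(1640) / 4)

  # clearly non-square component fails the aspect gate
  bg3 <- matrix(200, 100, 100)
  bg3[10:19, 10:60] <- 12
  expect_error(calibrate_scale(bg3, 4),
               class = "microcensus_calibration_error")
})
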