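test_that("stacks load from files in order, preserving shape and channels", {
  dir <- withr::local_tempdir()
  set.seed(1)
  for (i in 1:5) {
    png::writePNG(matrix(0.5, 10, 10), file.path(dir, sprintf("f%02d.png", i)))
  }
  s <- load_stack(list.files(dir, full.names = TRUE))
  expect_equal(n_frames(s), 5)
  expect_equal(dim(s$frames[[1]]), c(10L, 10L))
  expect_equal(s$frame_index, 1:5)

  # RGB TIFFs keep 3 channels and exact integer values
  rgbdir <- withr::local_tempdir()
  arr <- array(sample(0:255, 8 * 8 * 3, TRUE), c(8, 8, 3))
  for (i in 1:3)
    tiff::writeTIFF(arr / 255, file.path(rgbdir, sprintf("c%d.tif", i)),
                    bits.per.sample = 8)
  s2 <- load_stack(list.files(rgbdir, full.names = TRUE))
  expect_equal(dim(s2$frames[[2]]), c(8L, 8L, 3L))
  expect_equal(s2$frames[[1]], arr)

  # shape mismatch names the offending file
  bad <- file.path(dir, "zz.png")
  png::writePNG(matrix(0.5, 10, 11), bad)
  expect_error(load_stack(list.files(dir, full.names = TRUE)),
               class = "microcensus_validation_error")
  expect_error(load_stack(file.path(dir, "missing.png")),
               "missing.png", class = "microcensus_io_error")
})

test_that("a multi-page TIFF expands into its pages", {
  f <- withr::local_tempfile(fileext = ".tif")
  pages <- lapply(1:4, function(i) matrix((i * 10) / 255, 6, 6))
  tiff::writeTIFF(pages, f, bits.per.sample = 8)
  s <- load_stack(f)
  expect_equal(n_frames(s), 4)
  expect_equal(s$frames[[3]][1, 1], 30)
})

test_that("image stacks validate their invariants", {
  f <- matrix(0, 4, 4)
  expect_error(image_stack(list()), class = "microcensus_validation_error")
  expect_error(image_stack(list(f, matrix(0, 4, 5))),
               class = "microcensus_validation_error")
  expect_error(image_stack(list(matrix(300, 4, 4))),
               class = "microcensus_validation_error")
  expect_error(image_stack(list(f, f), frame_index = c(2, 1)),
               class = "microcensus_validation_error")
})

test_that("grayscale conversion uses luminance weights with round half up", {
  px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))
  expect_equal(as.vector(to_grayscale(px(255, 255, 255))), 255)
  expect_equal(as.vector(to_grayscale(px(0, 0, 0))), 0)
  # 0.2126*100 + 0.7152*200 + 0.0722*50 = 167.93 -> 168
  expect_equal(as.vector(to_grayscale(px(100, 200, 50))), 168)
  m <- matrix(7, 3, 3)
  expect_identical(to_grayscale(m), m)
  expect_error(to_grayscale(array(0, c(2, 2, 2))),
               class = "microcensus_validation_error")
})

test_that("projections reduce pixel series by the stated statistics", {
  expect_equal(project(const_stack(c(5, 3, 7)), "min")$image[1, 1], 3)
  expect_equal(project(const_stack(c(5, 3, 7)), "max")$image[1, 1], 7)
  # even-count median: mean of the two central order statistics, half up
  expect_equal(project(const_stack(c(5, 3, 7, 9)), "median")$image[1, 1], 6)
  # 70/3 = 23.33 -> 23
  expect_equal(project(const_stack(c(10, 20, 40)), "mean")$image[1, 1], 23)
  # single frame: identity for every method
  one <- image_stack(list(matrix(sample(0:255, 36), 6, 6)))
  for (m in c("min", "max", "median", "mean"))
    expect_equal(project(one, m)$image, one$frames[[1]])
})

test_that("projection matches the brute-force per-pixel oracle on random stacks", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(2:7, 1)
    frames <- lapply(seq_len(n), function(i) matrix(sample(0:255, 64, TRUE), 8, 8))
    s <- image_stack(frames)
    for (m in c("min", "max", "median", "mean"))
      expect_equal(project(s, m)$image, oracle_project(frames, m))
  }
})

test_that("projection is permutation-invariant and min/max bound the frames", {
  set.seed(7)
  frames <- lapply(1:5, function(i) matrix(sample(0:255, 100, TRUE), 10, 10))
  s <- image_stack(frames)
  perm <- image_stack(frames[c(3, 1, 5, 2, 4)])
  for (m in c("min", "max", "median", "mean"))
    expect_equal(project(s, m)$image, project(perm, m)$image)
  lo <- project(s, "min")$image
  hi <- project(s, "max")$image
  for (f in frames) {
    expect_true(all(lo <= f))
    expect_true(all(f <= hi))
  }
})

test_that("RGB projection is channelwise", {
  set.seed(8)
  frames <- lapply(1:3, function(i) array(sample(0:255, 48, TRUE), c(4, 4, 3)))
  bg <- project(image_stack(frames), "min")$image
  for (k in 1:3)
    expect_equal(bg[, , k],
                 oracle_project(lapply(frames, function(f) f[, , k]), "min"))
})

test_that("background removal clips, differences, and stays symmetric", {
  b <- matrix(12, 3, 3)
  f <- matrix(10, 3, 3)
  expect_equal(remove_background(f, b, "subtract")$image, matrix(0, 3, 3))
  expect_equal(remove_background(f, b, "difference")$image, matrix(2, 3, 3))
  expect_equal(remove_background(b, b, "difference")$image, matrix(0, 3, 3))
  expect_error(remove_background(matrix(0, 2, 2), b),
               class = "microcensus_validation_error")
  set.seed(3)
  x <- matrix(sample(0:255, 64, TRUE), 8, 8)
  y <- matrix(sample(0:255, 64, TRUE), 8, 8)
  expect_equal(remove_background(x, y, "difference")$image,
               remove_background(y, x, "difference")$image)
  expect_true(all(remove_background(x, y, "subtract")$image <=
                    remove_background(x, y, "difference")$image))
  expect_true(all(remove_background(x, y, "difference")$image >= 0))
})

test_that("registration recovers injected integer translations", {
  set.seed(11)
  ref <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  # frame translated by (+3, -2): content of ref moved down 3, left 2,
  # vacated margins filled with fresh noise
  shifted <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  shifted[4:64, 1:62] <- ref[1:61, 3:64]
  s <- image_stack(list(ref, shifted))
  out <- register_stack(s, reference_index = 1)
  expect_equal(unname(out$shifts[2, ]), c(-3, 2))
  expect_equal(out$stack$frames[[2]], ref)

  # identical frames: zero shifts
  s0 <- image_stack(list(ref, ref, ref))
  expect_true(all(register_stack(s0)$shifts == 0))

  # agreement with an exhaustive +/-5 px search on a smaller case
  small <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
  mv <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
  mv[1:28, 6:32] <- small[5:32, 1:27]  # translated by (-4, +5)
  mu <- mean(small); mv_mu <- mean(mv)
  best <- c(NA, NA); bestscore <- -Inf
  for (dr in -5:5) for (dc in -5:5) {
    rs <- max(1, 1 + dr):min(32, 32 + dr)
    cs <- max(1, 1 + dc):min(32, 32 + dc)
    ov <- sum((small[rs, cs] - mu) * (mv[rs - dr, cs - dc] - mv_mu))
    if (ov > bestscore) { bestscore <- ov; best <- c(dr, dc) }
  }
  out2 <- register_stack(image_stack(list(small, mv)))
  expect_equal(unname(out2$shifts[2, ]), best)
  expect_equal(unname(out2$shifts[2, ]), c(4, -5))

  expect_error(register_stack(s, reference_index = 9),
               class = "microcensus_validation_error")
  # independent pure-noise frames: shifts reported, no error
  s3 <- image_stack(list(matrix(sample(0:255, 256, TRUE), 16, 16),
                         matrix(sample(0:255, 256, TRUE), 16, 16)))
  expect_silent(register_stack(s3))
})

test_that("registration recovers shifts up to a quarter of the frame size", {
  set.seed(21)
  ref <- matrix(sample(0:255, 48 * 48, TRUE), 48, 48)
  for (d in list(c(12, -12), c(-10, 7), c(0, 12))) {
    mv <- matrix(sample(0:255, 48 * 48, TRUE), 48, 48)
    rs <- max(1, 1 + d[1]):min(48, 48 + d[1])
    cs <- max(1, 1 + d[2]):min(48, 48 + d[2])
    mv[rs, cs] <- ref[rs - d[1], cs - d[2]]
    out <- register_stack(image_stack(list(ref, mv)))
    expect_equal(unname(out$shifts[2, ]), -d)
  }
})

test_that("images round-trip through the writers", {
  img <- matrix(sample(0:255, 100, TRUE), 10, 10)
  f <- withr::local_tempfile(fileext = ".png")
  write_image(img, f)
  expect_equal(round(png::readPNG(f) * 255), img)
})
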