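test_that("write then read is lossless for 8-bit TIFF and PNG", {
  dir <- withr::local_tempdir()
  img <- withr::with_seed(5, random_rgb_image(32, 32))
  for (ext in c("tif", "png")) {
    path <- file.path(dir, paste0("rt.", ext))
    write_image(img, path)
    back <- read_image(path)
    expect_identical(back, array(as.integer(img), dim = dim(img)), info = ext)
  }
})

test_that("grayscale inputs are replicated across the three channels", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "gray.tif")
  tiff::writeTIFF(matrix(77 / 255, 4, 4), path, bits.per.sample = 8L)
  img <- read_image(path)
  expect_equal(dim(img), c(4L, 4L, 3L))
  expect_true(all(img == 77L))
})

test_that("16-bit samples rescale to 8-bit by integer division by 257", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "deep.tif")
  vals16 <- c(0, 257, 65535, 30000)
  tiff::writeTIFF(matrix(vals16 / 65535, 2, 2), path, bits.per.sample = 16L)
  img <- read_image(path)
  expect_equal(as.vector(img[, , 1]), as.integer(vals16 %/% 257))
  expect_equal(max(img), 255L)  # 65535 %/% 257
})

test_that("unsupported formats and missing files are rejected", {
  expect_error(read_image("nope.tif"), "not found")
  dir <- withr::local_tempdir()
  expect_error(write_image(random_rgb_image(2, 2), file.path(dir, "x.bmp")),
               "unsupported")
})

test_that("segmentation isolates a red window on a white background", {
  img <- flat_image(80, 100, c(255, 255, 255),
                    rect = c(20, 25, 60, 40), rect_color = c(255, 80, 80))
  mask <- segment_detection_window(img)
  expect_equal(sum(mask), 60 * 40)
  # exact footprint, counted by brute force
  expected <- matrix(FALSE, 80, 100)
  expected[26:65, 21:80] <- TRUE
  expect_identical(unname(mask), expected)
})

test_that("segmentation fails cleanly when nothing saturated exists", {
  white <- flat_image(40, 40, c(255, 255, 255))
  expect_error(segment_detection_window(white), "window not found")
  expect_s3_class(tryCatch(segment_detection_window(white), error = identity),
                  "argmark_window_not_found")
  # saturated but tiny component below the area floor
  speck <- flat_image(50, 50, c(255, 255, 255),
                      rect = c(0, 0, 2, 2), rect_color = c(255, 0, 0))
  expect_error(segment_detection_window(speck, min_area_fraction = 0.01),
               "window not found")
})

test_that("the largest of several passing components wins", {
  img <- flat_image(60, 80, c(255, 255, 255))
  img[1:20, 1:25, 2:3] <- 0; img[1:20, 1:25, 1] <- 255      # 500 px block
  img[31:60, 41:70, 2:3] <- 0; img[31:60, 41:70, 1] <- 255  # 900 px block
  mask <- segment_detection_window(img)
  expect_equal(sum(mask), 900)
  expect_true(all(mask[31:60, 41:70]))
  expect_false(any(mask[1:20, 1:25]))
})

test_that("segmentation is invariant to uniform brightness scaling", {
  img <- flat_image(60, 60, c(240, 240, 240),
                    rect = c(10, 10, 30, 25), rect_color = c(250, 90, 110))
  mask0 <- segment_detection_window(img)
  for (c_scale in c(0.4, 0.75)) {
    expect_identical(segment_detection_window(img * c_scale), mask0)
  }
})

test_that("segmentation is idempotent on its own masked image", {
  img <- flat_image(70, 70, c(255, 255, 255),
                    rect = c(15, 20, 35, 30), rect_color = c(255, 120, 120))
  mask <- segment_detection_window(img)
  masked <- img
  for (ch in 1:3) {
    plane <- masked[, , ch]
    plane[!mask] <- 255  # blank everything outside the ROI
    masked[, , ch] <- plane
  }
  expect_identical(segment_detection_window(masked), mask)
})

test_that("explicit rectangle ROI respects bounds and 0-based origin", {
  img <- flat_image(20, 30, c(255, 255, 255))
  mask <- roi_mask(img, c(5, 2, 10, 4))
  expect_equal(sum(mask), 40)
  expect_true(all(mask[3:6, 6:15]))
  expect_error(roi_mask(img, c(25, 0, 10, 5)), "outside")
})
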