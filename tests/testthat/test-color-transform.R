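test_that("red-to-magenta substitution copies red into blue and is idempotent", {
  px <- array(c(255, 0, 0), dim = c(1, 1, 3))
  expect_equal(red_to_magenta(px)[1, 1, ], c(255, 0, 255))
  px2 <- array(c(10, 20, 30), dim = c(1, 1, 3))
  expect_equal(red_to_magenta(px2)[1, 1, ], c(10, 20, 10))

  withr::with_seed(11, {
    for (i in 1:5) {
      img <- random_rgb_image(8, 8)
      tinted <- red_to_magenta(img)
      expect_identical(tinted[, , 1], img[, , 1])   # red untouched
      expect_identical(tinted[, , 2], img[, , 2])   # green untouched
      expect_identical(tinted[, , 3], img[, , 1])   # blue = red
      expect_identical(red_to_magenta(tinted), tinted)  # idempotent
    }
  })
})

test_that("RGB to HSB matches the hexcone definition on known pixels", {
  magenta <- rgb_to_hsb(255, 0, 255)
  expect_equal(magenta$hue, 300)
  expect_equal(magenta$saturation, 100)
  expect_equal(magenta$brightness, 100)

  pale <- rgb_to_hsb(255, 200, 255)
  expect_equal(pale$saturation, 100 * 55 / 255, tolerance = 1e-12)

  black <- rgb_to_hsb(0, 0, 0)
  expect_equal(black$saturation, 0)
  expect_equal(black$brightness, 0)

  expect_error(rgb_to_hsb(300, 0, 0), "0, 255")
})

test_that("RGB to HSB agrees with the rgb2hsv oracle on random pixels", {
  withr::with_seed(42, {
    r <- sample(0:255, 500, replace = TRUE)
    g <- sample(0:255, 500, replace = TRUE)
    b <- sample(0:255, 500, replace = TRUE)
  })
  got <- rgb_to_hsb(r, g, b)
  ref <- oracle_hsb(r, g, b)
  expect_equal(got$saturation, ref$saturation, tolerance = 1e-9)
  expect_equal(got$brightness, ref$brightness, tolerance = 1e-9)
  achromatic <- (pmax(r, g, b) - pmin(r, g, b)) == 0
  expect_equal((got$hue %% 360)[!achromatic], (ref$hue %% 360)[!achromatic],
               tolerance = 1e-9)
})

test_that("saturation is invariant under uniform channel scaling", {
  withr::with_seed(7, {
    r <- runif(200, 1, 255); g <- runif(200, 0, 255); b <- runif(200, 0, 255)
  })
  s0 <- rgb_to_hsb(r, g, b)$saturation
  for (c_scale in c(0.25, 0.5, 0.9, 1)) {
    sc <- rgb_to_hsb(c_scale * r, c_scale * g, c_scale * b)$saturation
    expect_equal(sc, s0, tolerance = 1e-9)
  }
})

test_that("tinting preserves saturation for pure-red render-model pixels", {
  s <- seq(0, 1, by = 0.05)
  r <- rep(255, length(s)); gb <- 255 * (1 - s)
  untinted <- rgb_to_hsb(r, gb, gb)$saturation
  tinted_px <- rgb_to_hsb(r, gb, r)$saturation  # after B <- R
  expect_equal(untinted, 100 * s, tolerance = 1e-9)
  expect_equal(tinted_px, 100 * s, tolerance = 1e-9)
})

test_that("measure_window means match a brute-force per-pixel oracle", {
  withr::with_seed(99, {
    for (i in 1:4) {
      img <- random_rgb_image(16, 16)
      mask <- matrix(sample(c(TRUE, FALSE), 256, replace = TRUE, prob = c(.6, .4)),
                     16, 16)
      if (!any(mask)) mask[1, 1] <- TRUE
      got <- measure_window(img, mask, tint = TRUE)

      # brute force: loop pixels, tint by hand, oracle saturation
      sats <- reds <- numeric(0)
      for (rr in 1:16) for (cc in 1:16) if (mask[rr, cc]) {
        p <- img[rr, cc, ]
        reds <- c(reds, p[1])
        sats <- c(sats, oracle_hsb(p[1], p[2], p[1])$saturation)
      }
      expect_equal(got$pixel_count, sum(mask))
      expect_equal(got$mean_red, mean(reds), tolerance = 1e-12)
      expect_equal(got$mean_saturation, mean(sats), tolerance = 1e-9)
    }
  })
})

test_that("measure_window edge behaviour: gray fixed point, red untouched by tint", {
  gray <- flat_image(6, 6, c(100, 100, 100))
  expect_equal(measure_window(gray, tint = TRUE)$mean_saturation, 0)

  pale <- flat_image(6, 6, c(255, 200, 200))
  expect_equal(measure_window(pale, tint = TRUE)$mean_saturation,
               100 * 55 / 255, tolerance = 1e-9)

  img <- random_rgb_image(10, 10)
  expect_equal(measure_window(img, tint = TRUE)$mean_red,
               measure_window(img, tint = FALSE)$mean_red)

  expect_error(measure_window(img, matrix(FALSE, 10, 10)), "empty mask")
  expect_error(measure_window(img, matrix(TRUE, 5, 5)), "dimensions")
})
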