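#' Red-to-magenta channel substitution
#'
#' Replaces the blue channel of an RGB image with a copy of the red channel,
#' so every pixel \code{(R, G, B)} becomes \code{(R, G, R)}. Reds turn
#' magenta while the red and green channels are untouched, which boosts the
#' red complex's contribution to HSB saturation before measurement. The
#' operation is idempotent.
#'
#' @param image An RGB image array (`height x width x 3`, integer values in
#'   0--255) as returned by [read_image()] or [render_detection_window()].
#' @return The tinted image array, same dimensions and storage.
#' @examples
#' px <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' red_to_magenta(px)[1, 1, ]  # 255 0 255
#' @export
red_to_magenta <- function(image) {
  check_rgb_image(image)
  image[, , 3L] <- image[, , 1L]
  image
}

#' Convert RGB values to HSB (hue, saturation, brightness)
#'
#' Hexcone HSB model on 8-bit channels: with `M = max(R,G,B)` and
#' `m = min(R,G,B)`, brightness is `100 * M / 255`, saturation is
#' `100 * (M - m) / M` (0 when `M = 0`, by convention), and hue is the
#' standard hexagonal angle in degrees in `[0, 360)`.
#'
#' All three arguments are recycled to a common length, so whole channel
#' planes can be converted in one call.
#'
#' @param r,g,b Numeric vectors of channel values in 0--255.
#' @return A list with numeric components `hue` (degrees), `saturation`
#'   (percent) and `brightness` (percent).
#' @examples
#' rgb_to_hsb(255, 0, 255)   # magenta: hue 300, S 100, B 100
#' rgb_to_hsb(255, 200, 255) # S = 100 * 55 / 255
#' @export
rgb_to_hsb <- function(r, g, b) {
  n <- max(length(r), length(g), length(b))
  r <- rep_len(as.numeric(r), n)
  g <- rep_len(as.numeric(g), n)
  b <- rep_len(as.numeric(b), n)
  if (any(r < 0 | r > 255 | g < 0 | g > 255 | b < 0 | b > 255, na.rm = TRUE)) {
    stop("channel values must lie in [0, 255]", call. = FALSE)
  }
  M <- pmax(r, g, b)
  m <- pmin(r, g, b)
  delta <- M - m

  sat <- ifelse(M > 0, 100 * delta / M, 0)
  bri <- 100 * M / 255

  hue <- numeric(n)
  chroma <- ifelse(delta > 0, delta, 1)  # guard division; hue 0 when delta == 0
  hr <- (M == r) & (delta > 0)
  hg <- (M == g) & !hr & (delta > 0)
  hb <- (M == b) & !hr & !hg & (delta > 0)
  hue[hr] <- 60 * (((g - b) / chroma)[hr] %% 6)
  hue[hg] <- 60 * (((b - r) / chroma)[hg] + 2)
  hue[hb] <- 60 * (((r - g) / chroma)[hb] + 4)
  hue <- hue %% 360

  list(hue = hue, saturation = sat, brightness = bri)
}

#' Per-pixel HSB planes of an image
#'
#' @param image An RGB image array (`height x width x 3`, 0--255).
#' @return A list of three `height x width` matrices: `hue`, `saturation`,
#'   `brightness`, units as in [rgb_to_hsb()].
#' @export
image_hsb <- function(image) {
  check_rgb_image(image)
  hsb <- rgb_to_hsb(image[, , 1L], image[, , 2L], image[, , 3L])
  d <- dim(image)[1:2]
  lapply(hsb, function(x) matrix(x, d[1L], d[2L]))
}

#' Mean color metrics over a region of interest
#'
#' The measurement at the heart of the assay readout: mean red-channel value
#' and mean per-pixel HSB saturation over the masked pixels. With
#' `tint = TRUE` (the default, the protocol's final form) saturation is
#' computed after the red-to-magenta substitution; mean red is always taken
#' from the untinted image. Per-pixel saturations are computed in floating
#' point and averaged without an intermediate 8-bit re-quantisation.
#'
#' @param image An RGB image array (0--255).
#' @param mask Logical matrix congruent with the image, or `NULL` to use
#'   every pixel.
#' @param tint Apply [red_to_magenta()] before the saturation measurement?
#' @return A `color_metrics` list: `mean_red` (0--255), `mean_saturation`
#'   (percent), `pixel_count`.
#' @export
measure_window <- function(image, mask = NULL, tint = TRUE) {
  check_rgb_image(image)
  d <- dim(image)
  if (is.null(mask)) mask <- matrix(TRUE, d[1L], d[2L])
  if (!is.logical(mask) || !identical(dim(mask), d[1:2])) {
    stop("mask must be a logical matrix with the image's dimensions", call. = FALSE)
  }
  if (!any(mask)) stop("empty mask: no pixels to measure", call. = FALSE)

  mean_red <- mean(image[, , 1L][mask])
  simg <- if (tint) red_to_magenta(image) else image
  sat <- rgb_to_hsb(simg[, , 1L][mask], simg[, , 2L][mask], simg[, , 3L][mask])$saturation
  structure(
    list(mean_red = mean_red, mean_saturation = mean(sat),
         pixel_count = sum(mask)),
    class = "color_metrics"
  )
}

#' @export
print.color_metrics <- function(x, ...) {
  cat(sprintf("color metrics over %d px: mean red %.1f, mean saturation %.1f%%\n",
              x$pixel_count, x$mean_red, x$mean_saturation))
  invisible(x)
}

# shared validator: height x width x 3 array, finite, 0-255
check_rgb_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3L] != 3L) {
    stop("expected an RGB image array of dimension height x width x 3", call. = FALSE)
  }
  if (dim(image)[1L] < 1L || dim(image)[2L] < 1L) {
    stop("image dimensions must be positive", call. = FALSE)
  }
  rng <- range(image)
  if (!all(is.finite(rng)) || rng[1L] < 0 || rng[2L] > 255) {
    stop("channel values must lie in [0, 255]", call. = FALSE)
  }
  invisible(image)
}
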