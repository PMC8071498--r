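#' Forward model for rendering detection-window images
#'
#' Describes how a known arginine concentration turns into a scanned
#' detection-window image: the window's mean HSB saturation is linear in
#' concentration, `S(C) = a + b * C` percent (clamped to [0, 100]), on a
#' constant background. Window pixels are pure red at full brightness,
#' `(255, 255 * (1 - s), 255 * (1 - s))` with `s = S / 100`, so saturation
#' alone encodes concentration; i.i.d. Gaussian channel noise is added to
#' the window region, clipped to [0, 255] and rounded to 8 bits.
#'
#' The defaults (`intercept 5 %`, `slope 0.65 %/µM`) place the assay's
#' 20--120 µM working range inside 18--83 % saturation, well away from both
#' clamp bounds.
#'
#' @param intercept Saturation (percent) at 0 µM.
#' @param slope Saturation gain in percent per µM; must be positive.
#' @param pixel_noise_sd Gaussian noise SD on the 0--255 channel scale.
#' @param image_size `c(width, height)` of the rendered image, pixels.
#' @param window `c(x, y, width, height)` of the colored region, 0-based
#'   top-left origin; must cover at least 1 % of the image.
#' @param background RGB triple of the surround (default white).
#' @return A `forward_model` object.
#' @export
forward_model <- function(intercept = 5, slope = 0.65, pixel_noise_sd = 2,
                          image_size = c(96L, 72L),
                          window = c(18L, 16L, 60L, 40L),
                          background = c(255L, 255L, 255L)) {
  stopifnot(slope > 0, intercept >= 0, pixel_noise_sd >= 0,
            length(image_size) == 2L, all(image_size >= 1),
            length(window) == 4L, all(window[3:4] >= 1),
            length(background) == 3L, all(background >= 0 & background <= 255))
  if (window[1L] < 0 || window[2L] < 0 ||
      window[1L] + window[3L] > image_size[1L] ||
      window[2L] + window[4L] > image_size[2L]) {
    stop("window lies outside the image bounds", call. = FALSE)
  }
  if (window[3L] * window[4L] < 0.01 * prod(image_size)) {
    stop("window must cover at least 1% of the image area", call. = FALSE)
  }
  structure(
    list(intercept = intercept, slope = slope, pixel_noise_sd = pixel_noise_sd,
         image_size = as.integer(image_size), window = as.numeric(window),
         background = as.integer(background)),
    class = "forward_model"
  )
}

#' @export
print.forward_model <- function(x, ...) {
  cat(sprintf(
    "forward model: S = %.2f + %.3f * C %%, noise SD %.1f, image %dx%d, window %gx%g at (%g, %g)\n",
    x$intercept, x$slope, x$pixel_noise_sd, x$image_size[1L], x$image_size[2L],
    x$window[3L], x$window[4L], x$window[1L], x$window[2L]))
  invisible(x)
}

#' Predicted window saturation at a concentration
#'
#' @param model A [forward_model()].
#' @param concentration Concentration(s) in µM.
#' @return Saturation in percent, clamped to [0, 100].
#' @export
predict_saturation <- function(model, concentration) {
  stopifnot(inherits(model, "forward_model"))
  pmin(100, pmax(0, model$intercept + model$slope * concentration))
}

#' Render a synthetic detection-window image
#'
#' Inverse of the measurement: draws the window at the saturation the
#' forward model predicts for `concentration`, on the model's background,
#' with Gaussian pixel noise in the window region. Deterministic for a
#' fixed seed.
#'
#' @param concentration Arginine concentration in µM (non-negative scalar).
#' @param model A [forward_model()].
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return An RGB image array (`height x width x 3`, integer 0--255).
#' @examples
#' img <- render_detection_window(60, forward_model(pixel_noise_sd = 0))
#' measure_window(img, segment_detection_window(img))
#' @export
render_detection_window <- function(concentration, model = forward_model(),
                                    seed = NULL) {
  stopifnot(inherits(model, "forward_model"),
            length(concentration) == 1L, concentration >= 0)
  render <- function() {
    w <- model$image_size[1L]; h <- model$image_size[2L]
    img <- array(rep(model$background, each = w * h), dim = c(h, w, 3L))
    s <- predict_saturation(model, concentration) / 100
    rows <- (model$window[2L] + 1):(model$window[2L] + model$window[4L])
    cols <- (model$window[1L] + 1):(model$window[1L] + model$window[3L])
    npx <- length(rows) * length(cols)
    win <- array(0, dim = c(length(rows), length(cols), 3L))
    win[, , 1L] <- 255
    win[, , 2L] <- win[, , 3L] <- 255 * (1 - s)
    if (model$pixel_noise_sd > 0) {
      win <- win + stats::rnorm(3 * npx, sd = model$pixel_noise_sd)
    }
    img[rows, cols, ] <- win
    img <- round(pmax(pmin(img, 255), 0))
    storage.mode(img) <- "integer"
    img
  }
  if (is.null(seed)) render() else withr::with_seed(seed, render())
}

#' Render a standard series of calibration images
#'
#' One image per standard concentration, paired with its nominal value.
#' The default series is the assay's six standards, 20--120 µM.
#'
#' @param model A [forward_model()].
#' @param concentrations Standard concentrations in µM; at least two
#'   distinct values.
#' @param seed Integer seed, or `NULL`.
#' @return A tibble with columns `concentration` and `image` (list of
#'   image arrays).
#' @export
generate_standard_series <- function(model = forward_model(),
                                     concentrations = seq(20, 120, by = 20),
                                     seed = NULL) {
  stopifnot(inherits(model, "forward_model"), all(concentrations >= 0))
  if (length(unique(concentrations)) < 2L) {
    stop("need at least two distinct standard concentrations", call. = FALSE)
  }
  build <- function() {
    tibble::tibble(
      concentration = as.numeric(concentrations),
      image = lapply(concentrations, render_detection_window, model = model)
    )
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}
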