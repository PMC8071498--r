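#' Fit the linear saturation--concentration calibration
#'
#' Ordinary least squares of mean window saturation (percent) on standard
#' concentration (µM): classical calibration, regressing response on
#' concentration and inverting for unknowns with [invert_calibration()].
#'
#' @param series A data frame with numeric columns `concentration` (µM) and
#'   `mean_saturation` (percent) — e.g. a rendered standard series passed
#'   through [measure_window()]. At least two distinct concentrations.
#' @return A `calibration_model`: `slope` (percent per µM), `intercept`
#'   (percent), `r_squared`, `residual_sd` (percent, n - 2 df; 0 when
#'   n = 2), `n_points`, `saturation_range` (span of the standards'
#'   saturations, used for the extrapolation flag), and the standards
#'   themselves.
#' @examples
#' std <- data.frame(concentration = seq(20, 120, 20),
#'                   mean_saturation = 5 + 0.65 * seq(20, 120, 20))
#' fit_calibration(std)
#' @export
fit_calibration <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("concentration", "mean_saturation") %in% names(series)))
  conc <- series$concentration
  sat <- series$mean_saturation
  n <- length(conc)
  if (n < 2L || length(unique(conc)) < 2L) {
    stop("calibration needs at least two distinct concentrations", call. = FALSE)
  }
  fit <- stats::lm(sat ~ conc)
  slope <- unname(stats::coef(fit)[2L])
  if (slope <= 0) {
    stop("non-responsive assay: calibration slope is not positive", call. = FALSE)
  }
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((sat - mean(sat))^2)
  structure(
    list(slope = slope,
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = 1 - ss_res / ss_tot,
         residual_sd = if (n > 2L) sqrt(ss_res / (n - 2L)) else 0,
         n_points = n,
         saturation_range = range(sat),
         standards = tibble::tibble(concentration = conc, mean_saturation = sat)),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("calibration: S = %.3f + %.4f * C  (n = %d, R^2 = %.4f, residual SD %.2f%%)\n",
              x$intercept, x$slope, x$n_points, x$r_squared, x$residual_sd))
  invisible(x)
}

#' Invert the calibration for unknown samples
#'
#' Inverse prediction: `C = (S - intercept) / slope`. Estimates below zero
#' are clamped to 0 µM, and `in_range` flags whether the observed
#' saturation lies inside the span of the fitted standards (extrapolated
#' estimates are reported but flagged).
#'
#' @param model A [calibration_model][fit_calibration()].
#' @param saturation Observed mean saturation(s), percent.
#' @return A tibble with columns `saturation_used` (percent), `value` (µM)
#'   and `in_range` (logical).
#' @export
invert_calibration <- function(model, saturation) {
  stopifnot(inherits(model, "calibration_model"))
  if (model$slope <= 0) stop("calibration slope must be positive", call. = FALSE)
  value <- (saturation - model$intercept) / model$slope
  in_range <- saturation >= model$saturation_range[1L] &
    saturation <= model$saturation_range[2L] & value >= 0
  tibble::tibble(saturation_used = as.numeric(saturation),
                 value = pmax(0, value),
                 in_range = in_range)
}

#' Measure a rendered standard series and fit the calibration
#'
#' Convenience wrapper: segments, tints and measures each standard image,
#' then fits the calibration line on the resulting mean saturations.
#'
#' @param standards A tibble from [generate_standard_series()] (columns
#'   `concentration`, `image`), or any tibble with those columns.
#' @param ... Segmentation settings passed to [segment_detection_window()].
#' @return A `calibration_model`.
#' @export
calibrate_from_images <- function(standards, ...) {
  stopifnot(all(c("concentration", "image") %in% names(standards)))
  sats <- vapply(standards$image, function(img) {
    mask <- segment_detection_window(img, ...)
    measure_window(img, mask, tint = TRUE)$mean_saturation
  }, numeric(1L))
  fit_calibration(tibble::tibble(concentration = standards$concentration,
                                 mean_saturation = sats))
}

#' Serialise / restore a calibration model as JSON
#'
#' @param model A `calibration_model`.
#' @param path Output (input) JSON path.
#' @return `path` invisibly for write; a `calibration_model` for read.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  payload <- list(slope = model$slope, intercept = model$intercept,
                  r_squared = model$r_squared, residual_sd = model$residual_sd,
                  n_points = model$n_points,
                  saturation_range = model$saturation_range,
                  standards = as.data.frame(model$standards))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
         residual_sd = x$residual_sd, n_points = x$n_points,
         saturation_range = as.numeric(x$saturation_range),
         standards = tibble::as_tibble(x$standards)),
    class = "calibration_model"
  )
}
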