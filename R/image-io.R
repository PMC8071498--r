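#' Read a scanned detection-window image
#'
#' Reads a TIFF or PNG raster into the package's working representation: an
#' integer array of dimension `height x width x 3` with values 0--255,
#' row-major, origin top-left. Grayscale inputs are replicated across the
#' three channels; an alpha channel is dropped; 16-bit samples are rescaled
#' to 8-bit by integer division by 257.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return An RGB image array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    tif = ,
    tiff = {
      info <- tiff::readTIFF(path, payload = FALSE)
      if (is.null(info$bits.per.sample)) info <- info[[1L]]  # multi-page: first
      depth <- info$bits.per.sample
      x <- tiff::readTIFF(path)  # normalised [0, 1]
      arr <- round(x * (2^depth - 1))
      storage.mode(arr) <- "integer"
      arr
    },
    png = {
      x <- png::readPNG(path, info = TRUE)
      depth <- attr(x, "info")$bit.depth
      arr <- round(x * (2^depth - 1))
      attributes(arr) <- attributes(x)[c("dim")]
      storage.mode(arr) <- "integer"
      arr
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (is.matrix(raw)) raw <- array(raw, dim = c(dim(raw), 1L))
  nc <- dim(raw)[3L]
  if (nc == 1L) {
    raw <- array(raw, dim = c(dim(raw)[1:2], 3L))  # grayscale replicated
  } else if (nc == 2L) {
    raw <- array(rep(raw[, , 1L], 3L), dim = c(dim(raw)[1:2], 3L))  # gray + alpha
  } else if (nc >= 4L) {
    raw <- raw[, , 1:3, drop = FALSE]  # drop alpha
  }
  if (max(raw) > 255L) raw <- raw %/% 257L  # 16-bit -> 8-bit
  storage.mode(raw) <- "integer"
  check_rgb_image(raw)
  raw
}

#' Write an 8-bit RGB image
#'
#' Lossless counterpart of [read_image()]: writing then reading returns
#' identical channel values. Format is chosen from the file extension
#' (`.tif`/`.tiff` or `.png`).
#'
#' @param image An RGB image array (0--255).
#' @param path Output path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  check_rgb_image(image)
  if (!dir.exists(dirname(path))) {
    stop("directory does not exist: ", dirname(path), call. = FALSE)
  }
  scaled <- image / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(scaled, path, bits.per.sample = 8L),
    png = png::writePNG(scaled, path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' Segment the detection window by color thresholding
#'
#' Selects pixels whose hue lies in a circular interval around red and whose
#' saturation clears a floor, then keeps the largest 4-connected component.
#' This stands in for interactive color thresholding of the scanned window.
#'
#' The hue interval is circular: the default `c(300, 60)` runs from magenta
#' through red (0/360) to orange-yellow, covering the assay's red complex
#' both before and after the red-to-magenta tint.
#'
#' @param image An RGB image array (0--255).
#' @param hue_range Length-2 numeric, degrees; interval traversed clockwise
#'   from the first to the second bound (wrapping at 360).
#' @param min_saturation Saturation floor in percent (0--100).
#' @param min_area_fraction Smallest admissible component area as a fraction
#'   of total image area, in (0, 1).
#' @return A logical mask matrix (`TRUE` = window pixel).
#' @seealso [measure_window()] for the measurement taken over the mask.
#' @export
segment_detection_window <- function(image, hue_range = c(300, 60),
                                     min_saturation = 5,
                                     min_area_fraction = 0.01) {
  check_rgb_image(image)
  stopifnot(length(hue_range) == 2L,
            min_saturation >= 0, min_saturation <= 100,
            min_area_fraction > 0, min_area_fraction < 1)
  hsb <- image_hsb(image)
  lo <- hue_range[1L] %% 360
  hi <- hue_range[2L] %% 360
  in_hue <- if (lo <= hi) {
    hsb$hue >= lo & hsb$hue <= hi
  } else {
    hsb$hue >= lo | hsb$hue <= hi
  }
  pass <- in_hue & hsb$saturation >= min_saturation

  if (!any(pass)) stop_window_not_found()
  labels <- EBImage::bwlabel(pass * 1)
  counts <- tabulate(labels[labels > 0])
  biggest <- which.max(counts)
  if (counts[biggest] < min_area_fraction * prod(dim(image)[1:2])) {
    stop_window_not_found()
  }
  mask <- labels == biggest
  dim(mask) <- dim(image)[1:2]
  mask
}

#' Rectangle region of interest as a mask
#'
#' Fallback when thresholding fails: an explicit rectangle given as
#' `(x, y, width, height)` with 0-based top-left origin (x = column,
#' y = row).
#'
#' @param image An RGB image array, for its dimensions.
#' @param roi Numeric length-4 vector `c(x, y, width, height)`.
#' @return A logical mask matrix.
#' @export
roi_mask <- function(image, roi) {
  check_rgb_image(image)
  stopifnot(length(roi) == 4L, roi[3L] >= 1, roi[4L] >= 1)
  d <- dim(image)[1:2]
  rows <- (roi[2L] + 1):(roi[2L] + roi[4L])
  cols <- (roi[1L] + 1):(roi[1L] + roi[3L])
  if (min(rows) < 1 || max(rows) > d[1L] || min(cols) < 1 || max(cols) > d[2L]) {
    stop("ROI extends outside the image", call. = FALSE)
  }
  mask <- matrix(FALSE, d[1L], d[2L])
  mask[rows, cols] <- TRUE
  mask
}

stop_window_not_found <- function() {
  stop(structure(
    class = c("argmark_window_not_found", "error", "condition"),
    list(message = "window not found: no sufficiently large colored component",
         call = NULL)
  ))
}
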