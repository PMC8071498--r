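# Independent oracles and fixture builders used across the suite.

# HSB reference via grDevices::rgb2hsv (independent of the package's own
# hexcone arithmetic); returns the package's units.
oracle_hsb <- function(r, g, b) {
  hsv <- grDevices::rgb2hsv(rbind(as.vector(r), as.vector(g), as.vector(b)),
                            maxColorValue = 255)
  list(hue = unname(hsv["h", ]) * 360,
       saturation = unname(hsv["s", ]) * 100,
       brightness = unname(hsv["v", ]) * 100)
}

# OLS by explicit normal equations.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  list(intercept = beta[1L], slope = beta[2L],
       r_squared = 1 - sum(res^2) / sum((y - mean(y))^2))
}

random_rgb_image <- function(h, w) {
  array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3L))
}

# uniform-color image with an optional colored rectangle (0-based x, y, w, h)
flat_image <- function(h, w, color, rect = NULL, rect_color = NULL) {
  img <- array(rep(color, each = h * w), dim = c(h, w, 3L))
  if (!is.null(rect)) {
    rows <- (rect[2L] + 1):(rect[2L] + rect[4L])
    cols <- (rect[1L] + 1):(rect[1L] + rect[3L])
    img[rows, cols, ] <- rep(rect_color, each = length(rows) * length(cols))
  }
  img
}
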