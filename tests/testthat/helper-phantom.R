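# Shared fixtures, all generated in code.

# Flat (piston) contour at a given depth spanning the window width.
flat_contour <- function(depth, width = 10, by = 0.5, frame_index = 1L) {
  dia_contour(cbind(seq(0, width, by = by), depth), frame_index = frame_index)
}

# Independent area oracle: rasterize at `res` cm and count pixel centers
# cranial to the (linearly interpolated) contour, column by column.
raster_area_oracle <- function(contour, width, res = 0.01) {
  xc <- seq(res / 2, width - res / 2, by = res)
  yc <- stats::approx(contour$points[, 1], contour$points[, 2], xout = xc,
                      rule = 2)$y
  sum(floor(yc / res + 0.5)) * res^2
}

# Random smooth monotone-x contour spanning the window, for property tests.
random_contour <- function(width = 10, depth = 12, by = 0.05) {
  x <- seq(0, width, by = by)
  y <- stats::runif(1, 3, 8) +
    stats::runif(1, -2, 2) * sin(2 * pi * x / width * stats::runif(1, 0.5, 2) +
                                 stats::runif(1, 0, 2 * pi)) +
    cumsum(stats::rnorm(length(x), sd = 0.02))
  y <- pmin(pmax(y, 0.2), depth - 0.2)
  dia_contour(cbind(x, y))
}

# Synthetic clip with a bright Gaussian band at a prescribed depth per frame
# (fast M-mode fixture without full phantom rendering).
band_clip <- function(depths, width = 10, depth = 12, spacing = 0.05,
                      sigma_cm = 0.12) {
  nx <- round(width / spacing); ny <- round(depth / spacing)
  yc <- (seq_len(ny) - 0.5) * spacing
  frames <- lapply(depths, function(d) {
    col <- 0.05 + 0.9 * exp(-(yc - d)^2 / (2 * sigma_cm^2))
    matrix(rep(col, nx), ny, nx)
  })
  cine_clip(frames, spacing = c(spacing, spacing))
}

# Welford single-pass mean/sd, as an independent check of summary stats.
welford <- function(v) {
  m <- 0; s <- 0; n <- 0
  for (x in v) {
    n <- n + 1
    d <- x - m
    m <- m + d / n
    s <- s + d * (x - m)
  }
  c(mean = m, sd = sqrt(s / (n - 1)))
}
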