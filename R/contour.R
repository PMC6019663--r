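#' Diaphragm contour
#'
#' An ordered polyline of diaphragm interface points in physical image
#' coordinates. The coordinate convention used throughout the package is:
#' origin at the image top-left, `x` lateral position in cm, `y` depth in cm
#' increasing caudally (downwards on screen). A contour is a function graph:
#' its points must be strictly increasing in `x`.
#'
#' @param points numeric n x 2 matrix of (x, y) positions in cm, n >= 3.
#' @param frame_index integer index of the cine frame the contour belongs to
#'   (1-based).
#' @param spacing length-2 numeric, cm per pixel laterally and in depth.
#' @param extrapolated logical vector, one flag per point; `TRUE` marks points
#'   that were extended beyond the traced (visible) diaphragm rather than
#'   observed.
#' @return An object of class `dia_contour`.
#' @examples
#' flat <- dia_contour(cbind(seq(0, 10, 0.5), 5))
#' area_above_contour(flat, bounds = c(10, 12)) # 50 cm^2
#' @export
dia_contour <- function(points, frame_index = 1L, spacing = c(0.05, 0.05),
                        extrapolated = NULL) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2)
    stop("`points` must be a numeric n x 2 matrix of (x, y) cm coordinates")
  if (nrow(points) < 3) stop("a contour needs at least 3 points")
  if (anyNA(points) || any(!is.finite(points)))
    stop("contour points must be finite")
  if (any(diff(points[, 1]) <= 0))
    stop("contour points must be strictly increasing in x (function graph)")
  if (any(points[, 2] < 0))
    stop("contour depth (y) must be non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2 || any(spacing <= 0))
    stop("`spacing` must be two positive cm-per-pixel values")
  extrapolated <- extrapolated %||% rep(FALSE, nrow(points))
  if (length(extrapolated) != nrow(points))
    stop("`extrapolated` must have one flag per point")
  structure(
    list(points = unname(points), frame_index = as.integer(frame_index),
         spacing = spacing, extrapolated = as.logical(extrapolated)),
    class = "dia_contour"
  )
}

#' @export
print.dia_contour <- function(x, ...) {
  cat(sprintf("<dia_contour> frame %d: %d points, x [%.2f, %.2f] cm, depth [%.2f, %.2f] cm (%d extrapolated)\n",
              x$frame_index, nrow(x$points),
              min(x$points[, 1]), max(x$points[, 1]),
              min(x$points[, 2]), max(x$points[, 2]),
              sum(x$extrapolated)))
  invisible(x)
}

# Normalize the `bounds` argument: a cine clip, a list(width, depth), or a
# numeric c(width, depth), all in cm.
as_bounds <- function(bounds) {
  if (inherits(bounds, "cine_clip")) return(bounds$bounds)
  if (is.list(bounds)) bounds <- c(bounds$width, bounds$depth)
  bounds <- as.numeric(bounds)
  if (length(bounds) != 2 || any(!is.finite(bounds)) || any(bounds <= 0))
    stop("`bounds` must give a finite positive image width and depth in cm")
  list(width = bounds[1], depth = bounds[2])
}

#' Supradiaphragmatic ("intra-thoracic") area above a contour
#'
#' Closes the traced diaphragm contour with the fixed image borders — up the
#' right border to the top of the image, across the top, and down the left
#' border — and returns the area of the resulting polygon by the shoelace
#' formula. This is the region cranial to the diaphragm inside the fixed
#' ultrasound window; its frame-to-frame change is the Area-method
#' measurement.
#'
#' The contour must reach both lateral image borders (to within half a pixel
#' spacing); partially visible contours must first be completed with
#' [extrapolate_contour()].
#'
#' @param contour a [dia_contour()].
#' @param bounds image extent: `c(width, depth)` in cm, or a `cine_clip`.
#' @return Area in cm^2 (non-negative scalar).
#' @export
area_above_contour <- function(contour, bounds) {
  stopifnot(inherits(contour, "dia_contour"))
  b <- as_bounds(bounds)
  x <- contour$points[, 1]
  y <- contour$points[, 2]
  tol <- max(contour$spacing) / 2
  if (any(x < -tol) || any(x > b$width + tol) || any(y > b$depth + tol))
    stop("contour points lie outside the image bounds")
  if (x[1] > tol || x[length(x)] < b$width - tol)
    stop("open contour: endpoints do not reach the lateral image borders; ",
         "apply extrapolate_contour() first")
  if (diff(range(x)) < tol) stop("degenerate (zero-width) contour")
  # closed polygon: contour left-to-right, then top-right and top-left corners
  px <- c(x, x[length(x)], x[1])
  py <- c(y, 0, 0)
  shoelace(px, py)
}

# Shoelace (surveyor's) polygon area, absolute value.
shoelace <- function(px, py) {
  n <- length(px)
  j <- c(2:n, 1L)
  abs(sum(px * py[j] - px[j] * py)) / 2
}

#' Extrapolate a partially visible contour to the lateral image borders
#'
#' Where the diaphragm trace does not reach a lateral image border (for
#' example because the air-filled lung obscures part of the dome), the
#' visible curve is continued to the border: a weighted quadratic is fitted
#' to the outermost 25% of visible points on the gap side (at least 4
#' points, tricube weights favouring the points nearest the gap) and
#' evaluated out to the border, clamping the extension to the image depth.
#' Extended points are flagged in `extrapolated`.
#'
#' @param partial a [dia_contour()] with at least 4 points.
#' @param bounds image extent, as in [area_above_contour()].
#' @return A `dia_contour` spanning the full image width; extended points are
#'   flagged. A contour already spanning the width is returned unchanged.
#' @export
extrapolate_contour <- function(partial, bounds) {
  stopifnot(inherits(partial, "dia_contour"))
  b <- as_bounds(bounds)
  if (nrow(partial$points) < 4)
    stop("extrapolation needs at least 4 visible points")
  tol <- max(partial$spacing) / 2
  step <- partial$spacing[1]
  x <- partial$points[, 1]
  y <- partial$points[, 2]
  flags <- partial$extrapolated

  extend <- function(side) {
    n <- length(x)
    m <- max(4L, ceiling(0.25 * n))
    idx <- if (side == "left") seq_len(min(m, n)) else seq(n - min(m, n) + 1L, n)
    xs <- x[idx]; ys <- y[idx]
    edge <- if (side == "left") x[1] else x[n]
    d <- abs(xs - edge)
    # tricube weights with bandwidth at half the segment span: the points
    # nearest the gap dominate, limiting extrapolation bias on curved domes
    w <- (1 - pmin(d / max(max(d) / 2, step), 1)^3)^3 + 1e-6
    fit <- stats::lm(ys ~ xs + I(xs^2), weights = w)
    if (side == "left") {
      new_x <- rev(seq(edge - step, 0, by = -step))
      if (length(new_x) == 0 || new_x[1] > tol) new_x <- c(0, new_x)
      new_x <- new_x[new_x < edge - step / 2]
      if (abs(new_x[1]) > 1e-12) new_x <- c(0, new_x)
    } else {
      new_x <- seq(edge + step, b$width, by = step)
      if (length(new_x) == 0 || new_x[length(new_x)] < b$width - tol)
        new_x <- c(new_x, b$width)
      new_x <- new_x[new_x > edge + step / 2]
      if (abs(new_x[length(new_x)] - b$width) > 1e-12) new_x <- c(new_x, b$width)
    }
    new_x <- unique(new_x)
    new_y <- stats::predict(fit, newdata = data.frame(xs = new_x))
    new_y <- pmin(pmax(new_y, 0), b$depth)
    if (side == "left") {
      x <<- c(new_x, x); y <<- c(new_y, y)
      flags <<- c(rep(TRUE, length(new_x)), flags)
    } else {
      x <<- c(x, new_x); y <<- c(y, new_y)
      flags <<- c(flags, rep(TRUE, length(new_x)))
    }
  }

  if (x[1] > tol) extend("left")
  if (x[length(x)] < b$width - tol) extend("right")
  dia_contour(cbind(x, y), frame_index = partial$frame_index,
              spacing = partial$spacing, extrapolated = flags)
}

# Linear interpolation of contour depth at lateral positions `x_at` (cm).
contour_depth_at <- function(contour, x_at) {
  stats::approx(contour$points[, 1], contour$points[, 2], xout = x_at,
                rule = 2)$y
}

# Most cranial contour point (minimum depth).
contour_apex <- function(contour) {
  i <- which.min(contour$points[, 2])
  contour$points[i, ]
}
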