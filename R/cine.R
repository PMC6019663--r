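#' Ultrasound cine clip
#'
#' An ordered stack of 2-D grayscale frames with physical calibration. Frames
#' are matrices indexed `[row = depth, col = lateral]`; pixel `(i, j)` has its
#' center at physical position `x = (j - 0.5) * spacing[1]`,
#' `y = (i - 0.5) * spacing[2]` cm. Intensities are on a common [0, 1] scale.
#'
#' @param frames list of numeric matrices (all the same shape), or a 3-D array
#'   `[depth, lateral, frame]`.
#' @param spacing length-2 numeric, cm per pixel (lateral, depth); must be
#'   known — physical calibration is never guessed.
#' @param frame_period seconds between frames.
#' @param id optional clip identifier carried into result tables.
#' @return An object of class `cine_clip` with derived physical `bounds`
#'   (width, depth in cm).
#' @export
cine_clip <- function(frames, spacing, frame_period = 0.1, id = "clip") {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  if (!is.list(frames) || length(frames) < 2)
    stop("a cine clip needs at least 2 frames")
  shapes <- vapply(frames, function(f) paste(dim(f), collapse = "x"), "")
  if (length(unique(shapes)) != 1) {
    bad <- which(shapes != shapes[1])[1]
    stop(sprintf("frame %d has shape %s, expected %s: mixed frame shapes",
                 bad, shapes[bad], shapes[1]))
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2 || anyNA(spacing) || any(spacing <= 0))
    stop("missing or invalid spacing metadata: cm-per-pixel must be two positive values")
  if (!is.numeric(frame_period) || frame_period <= 0)
    stop("`frame_period` must be a positive number of seconds")
  ny <- nrow(frames[[1]]); nx <- ncol(frames[[1]])
  structure(
    list(frames = frames, spacing = spacing, frame_period = frame_period,
         id = id,
         bounds = list(width = nx * spacing[1], depth = ny * spacing[2])),
    class = "cine_clip"
  )
}

#' @export
print.cine_clip <- function(x, ...) {
  cat(sprintf("<cine_clip> '%s': %d frames of %d x %d px (%.1f x %.1f cm), %.0f ms/frame\n",
              x$id, length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$bounds$width, x$bounds$depth, 1000 * x$frame_period))
  invisible(x)
}

#' M-mode scan line
#'
#' A fixed line through the image along which intensity is followed over
#' time, mimicking the M-mode cursor placed over the posterior part of the
#' diaphragm. The direction is normalized to a unit vector.
#'
#' @param origin length-2 numeric (x, y) cm, a point on the line.
#' @param direction length-2 numeric direction; defaults to straight down the
#'   beam (increasing depth).
#' @return An object of class `scan_line`.
#' @export
scan_line <- function(origin, direction = c(0, 1)) {
  origin <- as.numeric(origin); direction <- as.numeric(direction)
  if (length(origin) != 2 || anyNA(origin)) stop("`origin` must be (x, y) in cm")
  nrm <- sqrt(sum(direction^2))
  if (length(direction) != 2 || !is.finite(nrm) || nrm == 0)
    stop("`direction` must be a non-zero 2-vector")
  structure(list(origin = origin, direction = direction / nrm),
            class = "scan_line")
}
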