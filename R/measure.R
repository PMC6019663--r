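#' Select the frames of maximal and minimal diaphragm contraction
#'
#' Maximal diaphragm contraction (end-inspiration) is the frame in which the
#' diaphragm sits most caudally, i.e. the supradiaphragmatic area inside the
#' fixed window is largest; minimal contraction (pre-inspiration) is the frame
#' with the smallest area. Selection uses the same area functional as the
#' measurement itself, so the frames chosen are exactly the ones whose areas
#' are subtracted. Ties are broken by the earliest frame index.
#'
#' @param clip a [cine_clip()], or plain bounds `c(width, depth)` cm when the
#'   contours alone carry the information.
#' @param contours list of per-frame [dia_contour()] objects.
#' @return list with `frame_max`, `frame_min` (1-based positions in
#'   `contours`), the corresponding `area_max`, `area_min` (cm^2), the
#'   per-frame `areas`, and `constant` (TRUE, with a warning, when all frames
#'   have identical area).
#' @export
select_extreme_frames <- function(clip, contours) {
  if (length(contours) < 2) stop("need contours for at least 2 frames")
  b <- as_bounds(clip)
  areas <- vapply(contours, area_above_contour, numeric(1), bounds = b)
  constant <- diff(range(areas)) < 1e-12
  if (constant) warning("all frames have identical supradiaphragmatic area")
  list(frame_max = which.max(areas), frame_min = which.min(areas),
       area_max = max(areas), area_min = min(areas),
       areas = areas, constant = constant)
}

#' Area-method measurement: change in intra-thoracic area over a breath
#'
#' The Area method traces the diaphragm in the frames of maximal and minimal
#' contraction, closes each trace with the fixed image borders, and subtracts
#' the enclosed areas:
#' delta A = area at maximal contraction - area at minimal contraction.
#' The transducer (and hence the window) is fixed during the maneuver, so the
#' only change in area is due to diaphragm motion.
#'
#' @inheritParams select_extreme_frames
#' @return An `area_result`: `area_max_contraction`, `area_min_contraction`,
#'   `delta_area` (all cm^2), `frame_max`, `frame_min`, `constant`.
#' @examples
#' b <- c(10, 12)
#' cs <- lapply(c(5, 7), function(d)
#'   dia_contour(cbind(seq(0, 10, 0.5), d), frame_index = d))
#' delta_area(b, cs)$delta_area # piston: 10 cm wide x 2 cm caudal = 20 cm^2
#' @export
delta_area <- function(clip, contours) {
  sel <- select_extreme_frames(clip, contours)
  structure(
    list(area_max_contraction = sel$area_max,
         area_min_contraction = sel$area_min,
         delta_area = sel$area_max - sel$area_min,
         frame_max = sel$frame_max, frame_min = sel$frame_min,
         constant = sel$constant),
    class = "area_result"
  )
}

#' @export
print.area_result <- function(x, ...) {
  cat(sprintf("<area_result> delta A = %.1f cm^2 (max %.1f @ frame %d, min %.1f @ frame %d)\n",
              x$delta_area, x$area_max_contraction, x$frame_max,
              x$area_min_contraction, x$frame_min))
  invisible(x)
}

# Bilinear intensity interpolation at physical positions (x, y) cm.
interp_frame <- function(frame, x, y, spacing) {
  ny <- nrow(frame); nx <- ncol(frame)
  cj <- pmin(pmax(x / spacing[1] + 0.5, 1), nx) # fractional column index
  ri <- pmin(pmax(y / spacing[2] + 0.5, 1), ny) # fractional row index
  j0 <- pmin(floor(cj), nx - 1); i0 <- pmin(floor(ri), ny - 1)
  fj <- cj - j0; fi <- ri - i0
  frame[cbind(i0, j0)] * (1 - fi) * (1 - fj) +
    frame[cbind(i0 + 1, j0)] * fi * (1 - fj) +
    frame[cbind(i0, j0 + 1)] * (1 - fi) * fj +
    frame[cbind(i0 + 1, j0 + 1)] * fi * fj
}

# Bright-interface visibility test for an intensity profile: the profile is
# two-level (echo-poor thorax above, echogenic organ below) plus a narrow
# bright band, so location+scale rules (median + k MAD) degenerate when the
# two background levels are near 50/50. Instead the peak must exceed the
# maximum of the background -- the profile with a guard band around the peak
# excised -- by a relative contrast margin.
peak_visible <- function(prof, guard = 10L, contrast = 0.1) {
  i <- which.max(prof)
  bg <- prof[-(max(1L, i - guard):min(length(prof), i + guard))]
  if (length(bg) == 0) return(FALSE)
  prof[i] > (1 + contrast) * max(bg) && prof[i] > 0.02
}

# Parameter range over which origin + t * direction stays inside the window.
line_window_range <- function(line, b) {
  o <- line$origin; d <- line$direction
  lo <- -Inf; hi <- Inf
  for (ax in 1:2) {
    lim <- if (ax == 1) b$width else b$depth
    if (abs(d[ax]) < 1e-12) {
      if (o[ax] < 0 || o[ax] > lim) return(NULL)
    } else {
      t1 <- (0 - o[ax]) / d[ax]; t2 <- (lim - o[ax]) / d[ax]
      lo <- max(lo, min(t1, t2)); hi <- min(hi, max(t1, t2))
    }
  }
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) return(NULL)
  c(lo, hi)
}

#' M-mode diaphragm excursion along a scan line
#'
#' Intensity is resampled along the scan line in every frame; the diaphragm
#' is taken as the dominant bright interface, located per frame as the
#' maximum of the Gaussian-smoothed (sigma = 2 samples) line profile with
#' parabolic sub-sample refinement. The excursion is the range of this
#' position over the breath. Frames whose peak does not stand out against the
#' background (the profile outside a guard band around the peak) by a 10%
#' contrast margin carry no diaphragm echo; if at least 20% of frames fail,
#' the diaphragm is deemed not visualized along that line — the typical
#' failure of the left mid-clavicular M-mode view.
#'
#' The interface is followed with temporal coherence, the way an M-mode trace
#' is read: the frame with the highest peak contrast anchors the track, and
#' in each neighboring frame the peak is searched within `track_window` cm of
#' the previous frame's depth, so an isolated bright speckle elsewhere along
#' the line cannot hijack a single frame.
#'
#' @param clip a [cine_clip()].
#' @param line a [scan_line()]; must intersect the image.
#' @param track_window half-width (cm) of the frame-to-frame search window;
#'   must exceed the largest plausible inter-frame diaphragm motion.
#' @return An `excursion_result`: `excursion` (cm, max - min position of the
#'   interface along the line) and `depth_trace` (per-frame position along
#'   the line, cm from where the line enters the image; NA where the
#'   interface was not detected).
#' @export
m_mode_excursion <- function(clip, line, track_window = 3) {
  stopifnot(inherits(clip, "cine_clip"), inherits(line, "scan_line"))
  rng <- line_window_range(line, clip$bounds)
  if (is.null(rng)) stop("scan line does not intersect the image bounds")
  step <- min(clip$spacing)
  ts <- seq(rng[1], rng[2], by = step)
  if (length(ts) < 5) stop("scan line crosses too little of the image")
  xs <- line$origin[1] + ts * line$direction[1]
  ys <- line$origin[2] + ts * line$direction[2]
  n_f <- length(clip$frames)
  nt <- length(ts)

  raw <- vapply(clip$frames, function(fr)
    interp_frame(fr, xs, ys, clip$spacing), numeric(nt))
  profs <- apply(raw, 2, smooth1d, sigma = 2) # localization profile
  contrast <- apply(profs, 2, function(p) {
    i <- which.max(p)
    bg <- p[-(max(1L, i - 10L):min(nt, i + 10L))]
    p[i] / max(max(bg), .Machine$double.eps)
  })
  # visibility is judged on a nearly raw profile: the specular diaphragm echo
  # keeps its full amplitude there, while heavier smoothing erodes the thin
  # band toward the level of organ speckle extremes
  visible <- apply(apply(raw, 2, smooth1d, sigma = 0.5), 2, peak_visible)
  if (mean(!visible) >= 0.2)
    stop("diaphragm not visualized: no intensity peak above background in >= 20% of frames")

  win <- max(3L, round(track_window / step))
  trace <- rep(NA_real_, n_f)
  anchor <- which.max(contrast)
  trace[anchor] <- (parabolic_peak(profs[, anchor]) - 1) * step
  track <- function(order) {
    last <- trace[anchor]
    for (f in order) {
      ctr <- round(last / step) + 1L
      lo <- max(1L, ctr - win); hi <- min(nt, ctr + win)
      last <- (lo - 1L + parabolic_peak(profs[lo:hi, f]) - 1) * step
      if (visible[f]) trace[f] <<- last
    }
  }
  if (anchor < n_f) track((anchor + 1L):n_f)
  if (anchor > 1L) track(rev(seq_len(anchor - 1L)))

  structure(
    list(excursion = max(trace, na.rm = TRUE) - min(trace, na.rm = TRUE),
         depth_trace = trace, line = line),
    class = "excursion_result"
  )
}

#' @export
print.excursion_result <- function(x, ...) {
  cat(sprintf("<excursion_result> M-mode excursion = %.0f mm over %d frames\n",
              10 * x$excursion, length(x$depth_trace)))
  invisible(x)
}

#' B-mode apex displacement of the diaphragm dome
#'
#' Follows the most cranial point of the diaphragm (the dome top) across the
#' clip and reports its maximal cranio-caudal displacement, the B-mode
#' measurement performed with the scanner's caliper on the mid-axillary view.
#' A warning is issued when the apex comes within one pixel of the top image
#' border in any frame (dome top obscured / clipped).
#'
#' @inheritParams select_extreme_frames
#' @return An `apex_result`: `displacement` (cm, max - min apex depth),
#'   `apex_trace` (per-frame (x, y) of the apex), `clipped` flag.
#' @export
b_mode_apex_displacement <- function(clip, contours) {
  if (length(contours) < 2) stop("need contours for at least 2 frames")
  b <- as_bounds(clip)
  spacing <- contours[[1]]$spacing
  apex <- t(vapply(contours, contour_apex, numeric(2)))
  colnames(apex) <- c("x", "y")
  clipped <- any(apex[, "y"] <= spacing[2])
  if (clipped)
    warning("apex clipped: diaphragm top within 1 pixel of the top border")
  structure(
    list(displacement = max(apex[, "y"]) - min(apex[, "y"]),
         apex_trace = apex, clipped = clipped),
    class = "apex_result"
  )
}

#' @export
print.apex_result <- function(x, ...) {
  cat(sprintf("<apex_result> B-mode apex displacement = %.0f mm over %d frames\n",
              10 * x$displacement, nrow(x$apex_trace)))
  invisible(x)
}
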