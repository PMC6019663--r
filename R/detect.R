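#' Semi-automatic diaphragm contour detection
#'
#' A stand-in for manual tracing on the scanner: in each frame the diaphragm
#' is located column by column as the depth of maximal Gaussian-smoothed
#' intensity (the dominant bright interface), refined to sub-pixel by a
#' parabolic fit and median-filtered across columns. Columns whose peak does
#' not stand out against the column's background (the profile outside a guard
#' band around the peak) by the `contrast` margin carry no visible diaphragm:
#' interior gaps are bridged by linear interpolation and lateral gaps by
#' [extrapolate_contour()], with all such points flagged as extrapolated.
#'
#' @param clip a [cine_clip()].
#' @param sigma_px Gaussian smoothing sigma along depth, pixels.
#' @param contrast relative margin by which a column's peak must exceed its
#'   background maximum to count as a visible diaphragm echo.
#' @param guard_px half-width (pixels) of the band around the peak excluded
#'   from the background.
#' @param median_k window of the cross-column median filter (odd).
#' @return list of per-frame [dia_contour()] objects in physical (cm)
#'   coordinates.
#' @export
detect_contours <- function(clip, sigma_px = 2, contrast = 0.1, guard_px = 10L,
                            median_k = 5) {
  stopifnot(inherits(clip, "cine_clip"))
  nx <- ncol(clip$frames[[1]]); ny <- nrow(clip$frames[[1]])
  xc <- (seq_len(nx) - 0.5) * clip$spacing[1]
  lapply(seq_along(clip$frames), function(f) {
    sm <- smooth_cols(clip$frames[[f]], sigma_px)
    # visibility on a nearly raw profile (specular echo at full amplitude),
    # localization on the smoothed one
    ok <- apply(smooth_cols(clip$frames[[f]], 0.5), 2, peak_visible,
                guard = guard_px, contrast = contrast)
    if (mean(ok) < 0.5)
      stop(sprintf("diaphragm not visualized in frame %d: %d%% of columns below the brightness threshold",
                   f, round(100 * mean(!ok))))
    i <- max.col(t(sm), ties.method = "first")
    j <- seq_len(nx)
    inner <- which(i > 1L & i < ny)
    frac <- rep(0, nx)
    if (length(inner) > 0) {
      ii <- i[inner]; jj <- j[inner]
      den <- sm[cbind(ii - 1L, jj)] - 2 * sm[cbind(ii, jj)] + sm[cbind(ii + 1L, jj)]
      num <- sm[cbind(ii - 1L, jj)] - sm[cbind(ii + 1L, jj)]
      frac[inner] <- ifelse(den < 0, 0.5 * num / den, 0)
    }
    y <- (i + frac - 0.5) * clip$spacing[2]

    yk <- y[ok]
    if (sum(ok) >= median_k) yk <- stats::runmed(yk, median_k)
    y[ok] <- yk
    # bridge interior dropouts, flag them as extrapolated
    y_all <- stats::approx(xc[ok], y[ok], xout = xc, rule = 2)$y
    first_ok <- which(ok)[1]; last_ok <- which(ok)[sum(ok)]
    keep <- seq(first_ok, last_ok)
    ct <- dia_contour(cbind(xc[keep], pmin(pmax(y_all[keep], 0), clip$bounds$depth)),
                      frame_index = f, spacing = clip$spacing,
                      extrapolated = !ok[keep])
    extrapolate_contour(ct, clip$bounds)
  })
}
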