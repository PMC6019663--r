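#' Cohort simulation specification
#'
#' Parameters of a simulated method-validation study: subjects breathe at
#' self-chosen depths while all three ultrasound measurements and the
#' exhaled-volume analog are recorded per breath. Breath excursion amplitudes
#' are uniform over `amplitude_range`; effort is the performed fraction of
#' the maximal excursion. Above 80% effort the accessory respiratory muscles
#' add exhaled volume (`accessory_gain` liters per unit effort, scaled by a
#' per-breath engagement factor), volume the diaphragm cannot account for —
#' this is what degrades the measurement-volume correlation at high volumes.
#'
#' @param n_subjects,n_breaths cohort size (>= 2 subjects).
#' @param amplitude_range cm; per-breath excursion amplitude is uniform over
#'   this range.
#' @param sigma_contour sd (cm) of the smooth per-frame contour tracing
#'   error (correlation length 1 cm).
#' @param sigma_rater sd (cm) of each independent rater's contour
#'   perturbation; when > 0 two rater measurement sets are produced for
#'   agreement analysis.
#' @param accessory_gain liters per unit effort above the 0.8 threshold.
#' @param n_frames frames per breath cine.
#' @param window_width,window_depth field of view, cm.
#' @param spacing cm per pixel.
#' @param seed RNG seed; the whole cohort is reproducible.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20, n_breaths = 4,
                        amplitude_range = c(0.5, 9), sigma_contour = 0.15,
                        sigma_rater = 0, accessory_gain = 0, n_frames = 11,
                        window_width = 12, window_depth = 15,
                        spacing = c(0.05, 0.05), seed = 1) {
  stopifnot(n_subjects >= 2, n_breaths >= 1, sigma_contour >= 0,
            sigma_rater >= 0, accessory_gain >= 0, n_frames >= 3)
  amplitude_range <- as.numeric(amplitude_range)
  stopifnot(length(amplitude_range) == 2, amplitude_range[1] > 0,
            diff(amplitude_range) > 0)
  structure(
    list(n_subjects = n_subjects, n_breaths = n_breaths,
         amplitude_range = amplitude_range, sigma_contour = sigma_contour,
         sigma_rater = sigma_rater, accessory_gain = accessory_gain,
         n_frames = n_frames, window_width = window_width,
         window_depth = window_depth, spacing = spacing, seed = seed),
    class = "cohort_spec"
  )
}

# Perturb a ground-truth contour with a smooth tracing-error field.
jitter_contour <- function(ct, sd, depth) {
  if (sd <= 0) return(ct)
  y <- ct$points[, 2] + gp_noise(nrow(ct$points), diff(ct$points[1:2, 1]),
                                 sd, length_scale = 1)
  dia_contour(cbind(ct$points[, 1], pmin(pmax(y, 0), depth)),
              frame_index = ct$frame_index, spacing = ct$spacing,
              extrapolated = ct$extrapolated)
}

# All three measurements from one set of per-frame contours.
measure_contour_set <- function(contours, bounds, x_line) {
  da <- delta_area(bounds, contours)
  depths <- vapply(contours, contour_depth_at, numeric(1), x_at = x_line)
  apex <- suppressWarnings(b_mode_apex_displacement(bounds, contours))
  c(area = da$delta_area,
    mmode = max(depths) - min(depths),
    bmode = apex$displacement)
}

#' Simulate a method-validation cohort
#'
#' Draws per-subject dome geometry and per-breath excursions, produces the
#' per-frame ground-truth contours, perturbs them with tracing noise, and
#' measures every breath with all three methods. Returns the paired
#' measurement/volume study table, the ground-truth table, and (when
#' `sigma_rater > 0`) two independent raters' measurement matrices for
#' agreement analysis. With `render = TRUE` each breath's clip is rasterized
#' as well (slow; intended for end-to-end demonstrations, not the statistics).
#'
#' @param spec a [cohort_spec()].
#' @param render also rasterize each breath with [render_cine()].
#' @return list with `table` (data.frame: subject_id, breath_id, method,
#'   value, units, volume_l), `truth` (per-breath amplitudes, efforts, true
#'   delta areas, volumes), `ratings` (named list of breath x rater matrices,
#'   or NULL), and `clips` (list of [cine_clip()] or NULL).
#' @export
simulate_cohort <- function(spec, render = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    bounds <- c(spec$window_width, spec$window_depth)
    cyc <- breath_cycle(spec$n_frames)
    n_total <- spec$n_subjects * spec$n_breaths
    tab <- vector("list", n_total)
    tru <- vector("list", n_total)
    clips <- if (render) vector("list", n_total) else NULL
    ratings <- if (spec$sigma_rater > 0)
      list(area = matrix(NA_real_, n_total, 2),
           mmode = matrix(NA_real_, n_total, 2),
           bmode = matrix(NA_real_, n_total, 2)) else NULL

    k <- 0L
    for (s in seq_len(spec$n_subjects)) {
      # subjects differ in dome height and insertion depth; the chord (and so
      # the dome footprint, which fixes the volume-per-cm-of-excursion) is
      # common, making exhaled volume a monotone map of excursion when no
      # accessory muscles engage
      chord <- 10
      apex_h <- stats::runif(1, 2, 3.5)
      baseline <- stats::runif(1, 4.5, 5.5)
      x_line <- spec$window_width / 2 + chord / 4
      model_full <- dome_model(spec$window_width, spec$window_depth, chord,
                               apex_h, baseline, spec$amplitude_range[2])
      for (b in seq_len(spec$n_breaths)) {
        k <- k + 1L
        amp <- stats::runif(1, spec$amplitude_range[1], spec$amplitude_range[2])
        effort <- amp / spec$amplitude_range[2]
        engagement <- stats::runif(1) # accessory-muscle recruitment varies per breath
        model <- dome_model(spec$window_width, spec$window_depth, chord,
                            apex_h, baseline, amp)
        vol <- true_volume(model_full, spec$accessory_gain * engagement, effort)
        truth_ct <- lapply(seq_len(cyc$n_frames), function(f)
          dome_contour(model, cyc$phases[f], spacing = spec$spacing,
                       frame_index = f))
        observed <- lapply(truth_ct, jitter_contour, sd = spec$sigma_contour,
                           depth = spec$window_depth)
        m <- measure_contour_set(observed, bounds, x_line)
        if (!is.null(ratings)) {
          for (r in 1:2) {
            rated <- lapply(truth_ct, jitter_contour, sd = spec$sigma_rater,
                            depth = spec$window_depth)
            mr <- measure_contour_set(rated, bounds, x_line)
            ratings$area[k, r] <- mr["area"]
            ratings$mmode[k, r] <- mr["mmode"]
            ratings$bmode[k, r] <- mr["bmode"]
          }
        }
        if (render) {
          cfg <- render_config(spacing = spec$spacing,
                               seed = sample.int(.Machine$integer.max, 1))
          clips[[k]] <- render_cine(model, cyc, cfg,
                                    id = sprintf("s%02d_b%02d", s, b))
        }
        tab[[k]] <- data.frame(
          subject_id = s, breath_id = b,
          method = c("area", "mmode", "bmode"),
          value = unname(m),
          units = c("cm2", "cm", "cm"),
          volume_l = vol
        )
        tru[[k]] <- data.frame(
          subject_id = s, breath_id = b, amplitude_cm = amp, effort = effort,
          true_delta_area_cm2 = true_delta_area(model), volume_l = vol
        )
      }
    }
    list(table = do.call(rbind, tab), truth = do.call(rbind, tru),
         ratings = ratings, clips = clips)
  })
}
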