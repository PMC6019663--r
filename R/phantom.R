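#' Parametric diaphragm-dome phantom
#'
#' Geometry and kinematics of a synthetic hemidiaphragm: a circular-arc dome
#' (sagitta parameterization) inserted at `baseline_depth`, translating
#' caudally by up to `amplitude` cm over a breath inside a fixed ultrasound
#' window. Lateral to the dome chord the diaphragm continues flat at the
#' insertion depth. An optional `flattening` factor reduces the apex height as
#' the dome descends, emulating the flattened diaphragm of hyperinflation.
#'
#' @param window_width,window_depth field-of-view size in cm.
#' @param chord_width dome chord (insertion-to-insertion) in cm, at most the
#'   window width.
#' @param apex_height dome sagitta in cm above the insertion line; 0 gives a
#'   flat ("piston") diaphragm.
#' @param baseline_depth insertion depth at end-expiration (phase 0), cm.
#' @param amplitude cranio-caudal excursion of the dome over a full breath, cm.
#' @param flattening in [0, 1]; fraction of the apex height lost at full
#'   caudal displacement (0 = rigid translation).
#' @return A `dome_model`.
#' @export
dome_model <- function(window_width = 12, window_depth = 15, chord_width = 10,
                       apex_height = 2.5, baseline_depth = 5, amplitude = 3,
                       flattening = 0) {
  stopifnot(window_width > 0, window_depth > 0, chord_width > 0,
            apex_height >= 0, baseline_depth > 0, amplitude >= 0)
  if (chord_width > window_width)
    stop("dome chord cannot exceed the window width")
  if (baseline_depth + amplitude > window_depth)
    stop("dome exits the window depth: baseline_depth + amplitude > window_depth")
  if (apex_height >= baseline_depth)
    stop("apex would exit the window top: apex_height must be < baseline_depth")
  if (flattening < 0 || flattening > 1) stop("`flattening` must be in [0, 1]")
  structure(
    list(window_width = window_width, window_depth = window_depth,
         chord_width = chord_width, apex_height = apex_height,
         baseline_depth = baseline_depth, amplitude = amplitude,
         flattening = flattening),
    class = "dome_model"
  )
}

# Dome surface depth as a function of lateral offset from the apex axis.
# `rho` may run across the chord (contour use) or radially (volume use).
# Returns the depth (cm) of the interface at breath fraction `phase`.
dome_depth <- function(model, rho, phase) {
  base <- model$baseline_depth + phase * model$amplitude
  h <- model$apex_height * (1 - model$flattening * phase)
  half <- model$chord_width / 2
  y <- rep(base, length(rho))
  if (h > 1e-9) {
    r_circ <- (h^2 + half^2) / (2 * h) # circle through apex and insertions
    cy <- base - h + r_circ
    inside <- abs(rho) <= half
    y[inside] <- cy - sqrt(pmax(r_circ^2 - rho[inside]^2, 0))
  }
  y
}

#' Phantom contour at a breath phase
#'
#' The diaphragm interface across the full window width at breath fraction
#' `phase` (0 = end-expiration, 1 = full excursion), clipped to the window.
#'
#' @param model a [dome_model()].
#' @param phase breath fraction in [0, 1].
#' @param spacing cm-per-pixel pair used for the point grid.
#' @param frame_index frame index carried on the contour.
#' @return A [dia_contour()] spanning the window width, strictly monotone in x.
#' @export
dome_contour <- function(model, phase, spacing = c(0.05, 0.05),
                         frame_index = 1L) {
  stopifnot(inherits(model, "dome_model"))
  if (phase < 0 || phase > 1) stop("`phase` must be in [0, 1]")
  nx <- max(round(model$window_width / spacing[1]), 8) + 1
  x <- seq(0, model$window_width, length.out = nx)
  y <- dome_depth(model, x - model$window_width / 2, phase)
  y <- pmin(pmax(y, 0), model$window_depth)
  dia_contour(cbind(x, y), frame_index = frame_index, spacing = spacing)
}

#' Analytic ground-truth change in intra-thoracic area
#'
#' Trapezoid integral (step <= 0.005 cm) of the vertical gap between the
#' phase-1 and phase-0 phantom contours across the window: the true Area-
#' method value for a full breath. For a rigid translation (no flattening,
#' no clipping) this equals window width x amplitude for any dome shape.
#'
#' @param model a [dome_model()].
#' @param step integration step in cm (<= 0.005 recommended).
#' @return True delta area in cm^2.
#' @export
true_delta_area <- function(model, step = 0.005) {
  stopifnot(inherits(model, "dome_model"))
  x <- seq(0, model$window_width, by = step)
  if (x[length(x)] < model$window_width) x <- c(x, model$window_width)
  rho <- x - model$window_width / 2
  gap <- pmin(pmax(dome_depth(model, rho, 1), 0), model$window_depth) -
         pmin(pmax(dome_depth(model, rho, 0), 0), model$window_depth)
  sum((gap[-1] + gap[-length(gap)]) / 2 * diff(x))
}

#' Ground-truth exhaled-volume analog
#'
#' The dome is revolved about the vertical axis through its apex; the volume
#' swept between the end-expiratory surface and the surface at full excursion
#' is computed as a numeric solid-of-revolution integral and scaled by
#' `effort` (fraction of the full excursion actually performed). Above an
#' effort of 0.8 the accessory (secondary) respiratory muscles contribute
#' additional exhaled volume at `accessory_gain` liters per unit effort —
#' volume the diaphragm measurements cannot see.
#'
#' @param model a [dome_model()].
#' @param accessory_gain liters of accessory-muscle volume per unit effort
#'   above the 0.8 threshold.
#' @param effort breath effort in [0, 1].
#' @param step radial integration step, cm.
#' @return Volume in liters (deterministic).
#' @examples
#' piston <- dome_model(apex_height = 0, chord_width = 10, amplitude = 2)
#' true_volume(piston) * 1000 # pi * 5^2 * 2 cm^3
#' @export
true_volume <- function(model, accessory_gain = 0, effort = 1, step = 0.005) {
  stopifnot(inherits(model, "dome_model"))
  if (effort < 0 || effort > 1) stop("`effort` must be in [0, 1]")
  half <- model$chord_width / 2
  rho <- seq(0, half, by = step)
  if (rho[length(rho)] < half) rho <- c(rho, half)
  gap <- dome_depth(model, rho, 1) - dome_depth(model, rho, 0)
  integrand <- 2 * pi * rho * gap
  swept_cm3 <- sum((integrand[-1] + integrand[-length(integrand)]) / 2 * diff(rho))
  swept_cm3 / 1000 * effort + accessory_gain * max(0, effort - 0.8)
}

#' Breathing cycle phase schedule
#'
#' Maps frame indices to the fraction of full excursion. The default is a
#' raised-cosine single slow breath (end-expiration, full inspiration,
#' back to end-expiration), matching slow maneuvers performed to keep the
#' transducer still. The schedule must attain both 0 and 1 on the frame grid
#' so the extreme frames exist exactly.
#'
#' @param n_frames number of frames (odd for the default schedule, so the
#'   mid-breath frame hits phase 1 exactly).
#' @param phase_fn optional function mapping a vector in [0, 1] (normalized
#'   frame time) to phases in [0, 1].
#' @return A `breath_cycle` with `n_frames` and per-frame `phases`.
#' @export
breath_cycle <- function(n_frames = 11, phase_fn = NULL) {
  stopifnot(n_frames >= 2)
  tt <- seq(0, 1, length.out = n_frames)
  phases <- if (is.null(phase_fn)) (1 - cos(2 * pi * tt)) / 2 else phase_fn(tt)
  if (min(phases) > 1e-9 || max(phases) < 1 - 1e-9)
    stop("phase schedule must attain both 0 and 1 on the frame grid")
  if (any(phases < 0 | phases > 1)) stop("phases must lie in [0, 1]")
  structure(list(n_frames = as.integer(n_frames), phases = phases),
            class = "breath_cycle")
}
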