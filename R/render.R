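#' Rendering configuration for the B-mode phantom
#'
#' Controls how a [dome_model()] is rasterized into a speckled B-mode-like
#' cine loop: a dark (aerated, echo-poor) thorax above the diaphragm, a
#' bright diaphragm band along the interface, and an echogenic organ
#' (liver/spleen analog) below, all modulated by multiplicative speckle.
#'
#' @param spacing cm per pixel (lateral, depth).
#' @param frame_period seconds between frames.
#' @param brightness peak intensity of the diaphragm band (0-1).
#' @param thickness_px diaphragm band thickness in pixels (2 sigma of its
#'   Gaussian depth profile).
#' @param thorax_level,organ_level mean intensities above/below the interface.
#' @param organ_texture relative amplitude of the organ texture field.
#' @param speckle_sd relative sd of the multiplicative speckle field; 0
#'   renders a noise-free clip.
#' @param speckle_corr_px speckle correlation length in pixels.
#' @param obscure_prob probability that the air-filled lung obscures the dome
#'   top (suppresses the bright band near the apex for the whole clip).
#' @param obscure_halfwidth lateral half-width of the obscured patch, cm.
#' @param seed RNG seed; rendering is reproducible for a fixed seed.
#' @return A `render_config`.
#' @export
render_config <- function(spacing = c(0.05, 0.05), frame_period = 0.1,
                          brightness = 0.95, thickness_px = 5,
                          thorax_level = 0.08, organ_level = 0.45,
                          organ_texture = 0.15, speckle_sd = 0.12,
                          speckle_corr_px = 2, obscure_prob = 0,
                          obscure_halfwidth = 0.8, seed = NULL) {
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 2, all(spacing > 0), frame_period > 0,
            brightness > 0, brightness <= 1, thickness_px > 0,
            organ_texture >= 0, speckle_sd >= 0, speckle_corr_px > 0,
            obscure_halfwidth > 0)
  if (obscure_prob < 0 || obscure_prob > 1)
    stop("`obscure_prob` must be a probability in [0, 1]")
  structure(
    list(spacing = spacing, frame_period = frame_period,
         brightness = brightness, thickness_px = thickness_px,
         thorax_level = thorax_level, organ_level = organ_level,
         organ_texture = organ_texture, speckle_sd = speckle_sd,
         speckle_corr_px = speckle_corr_px, obscure_prob = obscure_prob,
         obscure_halfwidth = obscure_halfwidth, seed = seed),
    class = "render_config"
  )
}

# Gaussian smoothing of a matrix (separable, edge-renormalized).
smooth2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  t(smooth_cols(t(smooth_cols(m, sigma)), sigma))
}

#' Render a phantom breath as a B-mode-like cine loop
#'
#' Rasterizes the dome kinematics into a frame stack and returns it together
#' with the analytic ground truth: the per-frame contours, the true change in
#' intra-thoracic area over the breath, the true apex excursion, the true
#' M-mode excursion along a stated scan line (vertical, one quarter chord
#' posterior to the apex), and the exhaled-volume analog.
#'
#' @param model a [dome_model()].
#' @param cycle a [breath_cycle()].
#' @param cfg a [render_config()].
#' @param id clip identifier.
#' @return list with `clip` (a [cine_clip()]) and `truth` (list: `contours`,
#'   `delta_area`, `apex_excursion`, `mmode_excursion`, `mmode_line`,
#'   `volume_l`, `obscured`).
#' @export
render_cine <- function(model, cycle, cfg = render_config(), id = "phantom") {
  stopifnot(inherits(model, "dome_model"), inherits(cycle, "breath_cycle"),
            inherits(cfg, "render_config"))
  nx <- round(model$window_width / cfg$spacing[1])
  ny <- round(model$window_depth / cfg$spacing[2])
  if (nx < 32 || ny < 32)
    stop("window too small: need at least 32 px on each axis")
  xc <- (seq_len(nx) - 0.5) * cfg$spacing[1]
  yc <- (seq_len(ny) - 0.5) * cfg$spacing[2]
  rho <- xc - model$window_width / 2
  sigma_band <- cfg$thickness_px * cfg$spacing[2] / 2

  with_seed(cfg$seed, {
    obscured <- cfg$obscure_prob > 0 && stats::runif(1) < cfg$obscure_prob
    obs_cols <- if (obscured) abs(rho) <= cfg$obscure_halfwidth else rep(FALSE, nx)

    # anatomy texture and speckle are drawn once per clip: the organs are
    # static while the diaphragm sweeps across them (frame-to-frame speckle
    # decorrelation is not modeled)
    tex_factor <- if (cfg$organ_texture > 0) {
      tex <- smooth2d(matrix(stats::rnorm(ny * nx), ny, nx), 1.5)
      1 + cfg$organ_texture * tex / stats::sd(tex)
    } else 1
    speckle_factor <- if (cfg$speckle_sd > 0) {
      ray <- sqrt(-2 * log(matrix(stats::runif(ny * nx), ny, nx)))
      ray <- smooth2d(ray, cfg$speckle_corr_px)
      pmax(1 + cfg$speckle_sd * (ray - mean(ray)) / stats::sd(ray), 0)
    } else 1

    frames <- vector("list", cycle$n_frames)
    contours <- vector("list", cycle$n_frames)
    for (f in seq_len(cycle$n_frames)) {
      depth <- dome_depth(model, rho, cycle$phases[f])
      contours[[f]] <- dome_contour(model, cycle$phases[f],
                                    spacing = cfg$spacing, frame_index = f)
      dy <- outer(yc, depth, "-") # ny x nx signed distance below interface
      img <- ifelse(dy < 0, cfg$thorax_level, cfg$organ_level * tex_factor)
      # speckle multiplies the diffuse tissue; the specular diaphragm echo is
      # coherent and is composited on top with stable amplitude
      img <- img * speckle_factor
      band <- cfg$brightness * exp(-dy^2 / (2 * sigma_band^2))
      if (any(obs_cols)) band[, obs_cols] <- band[, obs_cols] * 0.05
      frames[[f]] <- pmin(pmax(pmax(img, band), 0), 1)
    }
  })

  # stated ground-truth M-mode line: vertical, a quarter chord lateral to
  # the apex (over the posterior dome, where movement is large)
  x_line <- model$window_width / 2 + model$chord_width / 4
  mm_depths <- vapply(cycle$phases, function(p)
    dome_depth(model, x_line - model$window_width / 2, p), numeric(1))
  apex_depths <- vapply(contours, function(ct) min(ct$points[, 2]), numeric(1))

  list(
    clip = cine_clip(frames, spacing = cfg$spacing,
                     frame_period = cfg$frame_period, id = id),
    truth = list(
      contours = contours,
      delta_area = true_delta_area(model),
      apex_excursion = max(apex_depths) - min(apex_depths),
      mmode_excursion = max(mm_depths) - min(mm_depths),
      mmode_line = scan_line(c(x_line, 0), c(0, 1)),
      volume_l = true_volume(model),
      obscured = obscured
    )
  )
}
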