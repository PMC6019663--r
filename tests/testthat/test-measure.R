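test_that("extreme-frame selection follows the supradiaphragmatic area", {
  b <- c(10, 12)
  # monotone caudal drift: deepest (last) frame is maximal contraction
  drift <- lapply(1:5, function(f) flat_contour(3 + f, frame_index = f))
  sel <- select_extreme_frames(b, drift)
  expect_identical(sel$frame_max, 5L)
  expect_identical(sel$frame_min, 1L)

  # single raised-cosine breath: extremes at mid-breath and at the first frame
  model <- dome_model()
  cyc <- breath_cycle(11)
  cts <- lapply(seq_len(11), function(f)
    dome_contour(model, cyc$phases[f], frame_index = f))
  sel <- select_extreme_frames(c(model$window_width, model$window_depth), cts)
  expect_identical(sel$frame_max, 6L) # phase 1 at mid-breath
  expect_identical(sel$frame_min, 1L) # tie with last frame broken earliest

  # constant clip: (first, first) with a warning
  const <- lapply(1:4, function(f) flat_contour(5, frame_index = f))
  expect_warning(sel <- select_extreme_frames(b, const), "identical")
  expect_identical(c(sel$frame_max, sel$frame_min), c(1L, 1L))
  expect_true(sel$constant)
})

test_that("delta area reproduces the piston closed form and its invariants", {
  b <- c(10, 12)
  piston <- lapply(c(5, 5.7, 7, 6.1), function(d) flat_contour(d))
  res <- delta_area(b, piston)
  expect_equal(res$delta_area, 20) # 10 cm x 2 cm, machine precision
  expect_equal(res$delta_area,
               res$area_max_contraction - res$area_min_contraction)
  expect_gte(res$delta_area, 0)

  # zero motion
  expect_warning(res0 <- delta_area(b, lapply(1:3, function(i) flat_contour(5))))
  expect_equal(res0$delta_area, 0)

  # invariant to vertical translation of the whole window
  shifted <- lapply(c(5, 5.7, 7, 6.1) + 2, function(d) flat_contour(d))
  expect_equal(delta_area(c(10, 14), shifted)$delta_area, 20)

  # scales linearly with window width for piston motion
  wide <- lapply(c(5, 7), function(d) flat_contour(d, width = 20))
  expect_equal(delta_area(c(20, 12), wide)$delta_area, 40)

  # frame order is irrelevant (extrema are order-free)
  reord <- piston[c(3, 1, 4, 2)]
  expect_equal(delta_area(b, reord)$delta_area, res$delta_area)
})

test_that("M-mode excursion recovers sinusoidal band motion", {
  d0 <- 6; a <- 1.5
  depths <- d0 + a * sin(2 * pi * seq(0, 1, length.out = 13))
  clip <- band_clip(depths)
  res <- m_mode_excursion(clip, scan_line(c(5, 0), c(0, 1)))
  expect_equal(res$excursion, 2 * a, tolerance = 0.05 / (2 * a)) # within 1 px
  expect_length(res$depth_trace, 13)
  expect_gte(res$excursion, 0)

  # static clip
  static <- band_clip(rep(6, 5))
  expect_equal(m_mode_excursion(static, scan_line(c(5, 0), c(0, 1)))$excursion, 0)
})

test_that("M-mode rejects lines that miss the image or see no interface", {
  clip <- band_clip(c(5, 6, 7))
  expect_error(m_mode_excursion(clip, scan_line(c(-5, 0), c(0, 1))),
               "does not intersect")
  flat <- cine_clip(replicate(5, matrix(0.3, 100, 100), simplify = FALSE),
                    c(0.05, 0.05))
  expect_error(m_mode_excursion(flat, scan_line(c(2.5, 0), c(0, 1))),
               "not visualized")
})

test_that("B-mode apex displacement equals rigid translation", {
  model <- dome_model(amplitude = 2.5)
  cts <- lapply(c(0, 0.4, 1, 0.6), function(p) dome_contour(model, p))
  res <- b_mode_apex_displacement(c(12, 15), cts)
  expect_equal(res$displacement, 2.5, tolerance = 1e-9)
  expect_identical(nrow(res$apex_trace), 4L)

  # static contours
  cts0 <- lapply(1:3, function(i) dome_contour(model, 0.5))
  expect_equal(b_mode_apex_displacement(c(12, 15), cts0)$displacement, 0)

  # apex touching the top border warns
  shallow <- lapply(c(0, 1), function(p)
    dia_contour(cbind(seq(0, 10, 0.5), 0.02 + p)))
  expect_warning(b_mode_apex_displacement(c(10, 12), shallow), "apex clipped")
})

test_that("all three methods agree exactly for pure piston motion", {
  width <- 10; disp <- 2
  depths <- c(5, 5.5, 7, 6) # min 5, max 7
  piston_cts <- lapply(seq_along(depths), function(f)
    flat_contour(depths[f], frame_index = f))
  clip <- band_clip(depths, width = width)
  da <- suppressWarnings(delta_area(clip, piston_cts))
  mm <- m_mode_excursion(clip, scan_line(c(7, 0), c(0, 1)))
  bm <- b_mode_apex_displacement(clip, piston_cts)
  px <- clip$spacing[2]
  expect_lt(abs(da$delta_area / width - disp), px)
  expect_lt(abs(mm$excursion - disp), px)
  expect_lt(abs(bm$displacement - disp), px)
  expect_lt(abs(da$delta_area / width - mm$excursion), px)
  expect_lt(abs(mm$excursion - bm$displacement), px)
})
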