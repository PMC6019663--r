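test_that("dome contour obeys the circular-arc closed form", {
  model <- dome_model(chord_width = 10, apex_height = 2.5, baseline_depth = 5,
                      amplitude = 3)
  c0 <- dome_contour(model, 0)
  # phase 0 baseline: insertions at baseline depth, apex raised by the sagitta
  expect_equal(c0$points[1, 2], 5)
  expect_equal(min(c0$points[, 2]), 5 - 2.5)
  # apex translates caudally by exactly the amplitude between phases
  c1 <- dome_contour(model, 1)
  expect_equal(min(c1$points[, 2]) - min(c0$points[, 2]), 3)
  # every arc point lies on the circle through the two insertions and apex
  h <- 2.5; half <- 5
  r <- (h^2 + half^2) / (2 * h)
  on_arc <- abs(c0$points[, 1] - model$window_width / 2) <= half - 1e-9
  d <- sqrt((c0$points[on_arc, 1] - model$window_width / 2)^2 +
            (c0$points[on_arc, 2] - (5 - h + r))^2)
  expect_equal(max(abs(d - r)), 0, tolerance = 1e-9)
  expect_error(dome_contour(model, 1.2), "phase")
})

test_that("dome model rejects geometry that exits the window", {
  expect_error(dome_model(baseline_depth = 10, amplitude = 8, window_depth = 15),
               "window depth")
  expect_error(dome_model(apex_height = 6, baseline_depth = 5), "window top")
  expect_error(dome_model(chord_width = 20, window_width = 12), "chord")
})

test_that("ground-truth delta area matches closed forms", {
  # piston: width x amplitude exactly
  flat <- dome_model(apex_height = 0, amplitude = 2, window_width = 10)
  expect_equal(true_delta_area(flat), 20, tolerance = 1e-9)
  # zero amplitude
  expect_equal(true_delta_area(dome_model(amplitude = 0)), 0)
  # rigid translation of any dome: width x amplitude (translation argument)
  dome <- dome_model(window_width = 10, chord_width = 6, apex_height = 3,
                     baseline_depth = 6, amplitude = 2)
  expect_equal(true_delta_area(dome), 20, tolerance = 1e-6)
  # flattening breaks rigidity: the dome sinks further as it flattens, so the
  # area change exceeds the rigid-translation value
  flatn <- dome_model(window_width = 10, chord_width = 6, apex_height = 3,
                      baseline_depth = 6, amplitude = 2, flattening = 0.5)
  expect_gt(true_delta_area(flatn), 20)
})

test_that("ground-truth volume is the swept solid of revolution", {
  piston <- dome_model(apex_height = 0, chord_width = 10, amplitude = 2)
  expect_equal(true_volume(piston) * 1000, pi * 5^2 * 2, tolerance = 1e-6)
  expect_equal(true_volume(piston, effort = 0), 0)
  # accessory term: zero at or below the 80% threshold, positive above
  expect_equal(true_volume(piston, accessory_gain = 1.5, effort = 0.8),
               true_volume(piston, accessory_gain = 0, effort = 0.8))
  expect_equal(true_volume(piston, accessory_gain = 1.5, effort = 0.9) -
               true_volume(piston, accessory_gain = 0, effort = 0.9),
               1.5 * 0.1)
})

test_that("breath cycle attains both extremes on the frame grid", {
  cyc <- breath_cycle(11)
  expect_equal(min(cyc$phases), 0)
  expect_equal(max(cyc$phases), 1)
  expect_error(breath_cycle(4), "attain") # even grid misses phase 1
  lin <- breath_cycle(6, phase_fn = function(t) t)
  expect_equal(lin$phases, seq(0, 1, length.out = 6))
})

test_that("rendering is deterministic and zero motion gives identical frames", {
  m <- dome_model(amplitude = 0, window_width = 6, window_depth = 6,
                  chord_width = 5, apex_height = 1.2, baseline_depth = 2.5)
  cyc <- breath_cycle(5, phase_fn = function(t) c(0, 1, 0, 1, 0))
  a <- render_cine(m, cyc, render_config(seed = 9))
  b <- render_cine(m, cyc, render_config(seed = 9))
  expect_identical(a$clip$frames, b$clip$frames)
  for (f in 2:5) expect_identical(a$clip$frames[[f]], a$clip$frames[[1]])
  expect_error(render_cine(dome_model(window_width = 1, window_depth = 1,
                                      chord_width = 0.8, apex_height = 0.2,
                                      baseline_depth = 0.5, amplitude = 0.2),
                           breath_cycle(5, function(t) c(0, 1, 0, 1, 0)),
                           render_config()),
               "32 px")
})

test_that("measurements on a noise-free render recover the ground truth", {
  m <- dome_model(amplitude = 4)
  out <- render_cine(m, breath_cycle(11),
                     render_config(speckle_sd = 0, organ_texture = 0))
  cts <- detect_contours(out$clip)
  px <- out$clip$spacing[2]
  da <- delta_area(out$clip, cts)
  expect_lt(abs(da$delta_area - out$truth$delta_area) / out$truth$delta_area,
            0.02)
  mm <- m_mode_excursion(out$clip, out$truth$mmode_line)
  expect_lt(abs(mm$excursion - out$truth$mmode_excursion), px)
  bm <- b_mode_apex_displacement(out$clip, cts)
  expect_lt(abs(bm$displacement - out$truth$apex_excursion), px)
})

test_that("speckled render: M-mode excursion recovered within one pixel", {
  m <- dome_model(amplitude = 3)
  out <- render_cine(m, breath_cycle(11), render_config(seed = 21))
  expect_equal(out$truth$mmode_excursion, 3, tolerance = 1e-9)
  mm <- m_mode_excursion(out$clip, out$truth$mmode_line)
  expect_lt(abs(mm$excursion - 3), out$clip$spacing[2])
})

test_that("median measured delta area is monotone in amplitude", {
  amps <- c(1, 3, 5, 7)
  meds <- vapply(amps, function(a) {
    m <- dome_model(amplitude = a)
    das <- vapply(1:5, function(i) {
      cyc <- breath_cycle(7)
      cts <- lapply(seq_len(7), function(f)
        dome_contour(m, cyc$phases[f], frame_index = f))
      withr::with_seed(100 * a + i, {
        noisy <- lapply(cts, diamus:::jitter_contour, sd = 0.15, depth = 15)
        delta_area(c(12, 15), noisy)$delta_area
      })
    }, numeric(1))
    stats::median(das)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("cohort simulation is reproducible and tracks volume when clean", {
  spec <- cohort_spec(n_subjects = 8, n_breaths = 3, sigma_contour = 0,
                      accessory_gain = 0, seed = 4)
  sim <- simulate_cohort(spec)
  # noise-free, no accessory volume: measurement is a monotone map of volume
  a <- sim$table[sim$table$method == "area", ]
  expect_equal(spearman_ci(a$value, a$volume_l)$r_s, 1)
  # byte-for-byte determinism of the study table
  sim2 <- simulate_cohort(spec)
  expect_identical(sim$table, sim2$table)
  # no duplicate keys, volumes non-negative, units carried
  expect_identical(anyDuplicated(sim$table[c("subject_id", "breath_id", "method")]), 0L)
  expect_true(all(sim$table$volume_l >= 0))
  expect_setequal(unique(sim$table$units), c("cm2", "cm"))
})

test_that("two rater measurement sets are produced when rater noise is on", {
  sim <- simulate_cohort(cohort_spec(n_subjects = 4, n_breaths = 2,
                                     sigma_rater = 0.15, seed = 7))
  expect_named(sim$ratings, c("area", "mmode", "bmode"))
  expect_identical(dim(sim$ratings$area), c(8L, 2L))
  expect_false(any(sim$ratings$area[, 1] == sim$ratings$area[, 2]))
})
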