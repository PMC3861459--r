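test_that("generators are bit-reproducible under a fixed seed", {
  a <- small_speckle(seed = 42)
  b <- small_speckle(seed = 42)
  expect_identical(a$envelope$frames, b$envelope$frames)
  expect_identical(a$mask$mask, b$mask$mask)
  c1 <- simulate_ap_movie(small_movie_config(seed = 7))
  c2 <- simulate_ap_movie(small_movie_config(seed = 7))
  expect_identical(c1$movie$frames, c2$movie$frames)
  h1 <- simulate_histology_image(seed = 9)
  h2 <- simulate_histology_image(seed = 9)
  expect_identical(h1$image, h2$image)
})

test_that("null phantom lesion region is indistinguishable from background", {
  # no lesion effect: raw envelope amplitudes inside vs outside the generative
  # ellipse are identically distributed (i.i.d. draws), so two-sample p-values
  # should not concentrate at small values across seeds
  pvals <- vapply(1:10, function(s) {
    ph <- small_speckle(seed = 500 + s, lesion_shift = 1, n_frames = 60,
                        shape = c(32, 32), semiaxes = c(8, 6))
    fr <- ph$envelope$frames[, , 30]
    stats::wilcox.test(fr[ph$mask$mask], fr[!ph$mask$mask])$p.value
  }, numeric(1))
  expect_gte(sum(pvals > 0.05), 8)
})

test_that("pre-ablation Rayleigh draws recover the configured scale", {
  cfg <- speckle_phantom_config(shape = c(64, 64), n_frames = 60,
                                distribution = "rayleigh", alpha0 = 1,
                                lesion_shift = 1, seed = 21)
  ph <- simulate_speckle_sequence(cfg)
  a_hat <- rayleigh_mle(as.vector(ph$envelope$frames))
  expect_lt(abs(a_hat - 1), 0.02)
})

test_that("lesion shift profile ramps then relaxes", {
  cfg <- speckle_phantom_config(seed = 1)
  expect_equal(lesion_shift_profile(cfg, c(4.0, 4.5)), c(1, 1))
  expect_equal(lesion_shift_profile(cfg, 6.5), 1 + 0.8 / 2)   # mid-ramp
  expect_equal(lesion_shift_profile(cfg, 8.5), cfg$lesion_shift)
  late <- lesion_shift_profile(cfg, c(9.5, 12, 1e6))
  expect_true(all(diff(late) < 0))
  retained <- 1 + cfg$recovery_fraction * (cfg$lesion_shift - 1)
  expect_equal(late[3], retained, tolerance = 1e-6)
  expect_error(speckle_phantom_config(n_frames = 10, seed = 1), "span")
  expect_error(speckle_phantom_config(lesion_semiaxes = c(40, 40), seed = 1),
               "inside the grid")
})

test_that("plane-wave activation truth follows distance over velocity", {
  # CV 0.5 mm/ms at 250 um/px: 20 columns apart along propagation = 10 ms
  cfg <- ap_movie_config(shape = c(30, 30), cv_mm_per_ms = 0.5,
                         cv_angle_deg = 0, pixel_spacing_um = c(250, 250),
                         noise_sd = 0, seed = 1)
  sim <- simulate_ap_movie(cfg)
  act <- sim$truth$activation_ms
  expect_equal(act[1, 21] - act[1, 1], 10)
  expect_equal(act[15, 5] - act[3, 5], 0)   # no row component at 0 degrees
})

test_that("ground-truth lesion effects are analytic, not rendered", {
  cfg <- small_movie_config(apa_scale = 0.2, seed = 2)
  sim <- simulate_ap_movie(cfg)
  ins <- sim$mask$mask
  expect_true(all(sim$truth$delta_apa[ins] == -0.8))
  expect_true(all(sim$truth$delta_apa[!ins] == 0))
  expect_equal(sim$truth$effect_by_cycle, c(0, 0, 0.5, 1))
  expect_true(all(sim$truth$apd50_ms[ins] == 160 * 0.67))
})

test_that("noiseless movie rendering matches the template closed form", {
  cfg <- small_movie_config(seed = 3, lesion_semiaxes = c(4, 3))
  sim <- simulate_ap_movie(cfg)
  # an unablated pixel's cycle-1 trace equals baseline + apa_df * template
  p <- c(2, 2)
  tr <- sim$movie$frames[p[1], p[2], 1:500]
  tt <- (0:499) - sim$truth$activation_ms[p[1], p[2]]
  expect_equal(as.vector(tr),
               cfg$baseline_f + cfg$apa_df * ap_template(tt, cfg$upstroke_ms,
                                                         cfg$apd50_ms,
                                                         cfg$apd80_ms),
               tolerance = 1e-12)
})

test_that("config invariants reject impossible APs", {
  expect_error(ap_movie_config(apd50_ms = 300, apd80_ms = 200), "APD50 < APD80")
  expect_error(ap_movie_config(apd50_ms = 900, apd80_ms = 1100,
                               pacing_cycle_ms = 1000, seed = 1))
  expect_error(ap_movie_config(cv_mm_per_ms = 0), "cv")
  expect_error(ap_movie_config(apa_scale = 1.5), "apa_scale")
})

test_that("histology generator is exact at zero noise and flags degeneracy", {
  h <- simulate_histology_image(noise_sd = 0, outlier_fraction = 0, seed = 1)
  seg <- segment_lesion(h$image, closing_radius = 0)
  expect_identical(seg$mask, h$mask$mask)
  expect_warning(simulate_histology_image(lesion_color = c(0.5, 0.5, 0.5),
                                          background_color = c(0.5, 0.5, 0.5),
                                          noise_sd = 0, seed = 1),
                 "degenerate")
})
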