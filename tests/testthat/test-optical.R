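test_that("preprocessing filter has the specified band behaviour", {
  fs <- 1000
  nt <- 3000
  mk_movie <- function(trace) {
    optical_movie(array(rep(trace, each = 1), c(1, 1, nt)),
                  simple_meta(frame_rate_hz = fs, t0 = 0, ablation = c(NA, NA)),
                  pacing_cycle_ms = 1000)
  }
  # DC-only trace is removed by the 1 Hz high-pass edge
  dc <- preprocess_movie(mk_movie(rep(5, nt)), bin = 1)
  expect_lt(max(abs(dc$frames[1, 1, 500:2500])), 0.01 * 5)
  # 10 Hz sinusoid passes with gain within 1% of unity
  s10 <- sin(2 * pi * 10 * (0:(nt - 1)) / fs)
  f10 <- preprocess_movie(mk_movie(s10), bin = 1)
  expect_lt(abs(max(f10$frames[1, 1, 500:2500]) - 1), 0.01)
  # 200 Hz sinusoid is strongly attenuated by the 100 Hz edge
  s200 <- sin(2 * pi * 200 * (0:(nt - 1)) / fs)
  f200 <- preprocess_movie(mk_movie(s200), bin = 1)
  expect_lt(max(abs(f200$frames[1, 1, 500:2500])), 0.02)
  expect_error(preprocess_movie(mk_movie(rep(1, nt)), band_hz = c(1, 600)),
               "Nyquist")
})

test_that("3x3 binning equals the local spatial mean", {
  set.seed(9)
  frame <- matrix(runif(81), 9, 9)
  mv <- optical_movie(array(frame, c(9, 9, 600)),
                      simple_meta(frame_rate_hz = 1000, t0 = 0,
                                  ablation = c(NA, NA)), 500)
  out <- preprocess_movie(mv, bin = 3, band_hz = c(0, 100), order = 64)
  # interior pixels equal the 3x3 neighbourhood mean of the static frame
  oracle <- matrix(NA_real_, 9, 9)
  for (i in 2:8) for (j in 2:8)
    oracle[i, j] <- mean(frame[(i - 1):(i + 1), (j - 1):(j + 1)])
  expect_equal(out$frames[2:8, 2:8, 300], oracle[2:8, 2:8], tolerance = 1e-6)
})

test_that("drift correction removes the model it fits", {
  fs <- 1000; cl <- 500; nt <- 2000
  t_s <- (0:(nt - 1)) / fs
  ap <- rep(0, nt)
  for (k in 0:3) ap[(k * 500 + 26):(k * 500 + 150)] <- 1   # crude AP blocks
  lin <- correct_drift(ap + 0.3 * t_s, fs, cl, model = "linear")
  expect_lt(max(abs(lin - ap)), 1e-6)
  # zero-drift input comes back unchanged (up to the fitted constant ~ 0)
  none <- correct_drift(ap, fs, cl, model = "linear")
  expect_lt(max(abs(none - ap)), 1e-6)
  expect_error(correct_drift(ap, fs, cl, model = "poly", poly_degree = 300),
               "fewer baseline samples")
})

test_that("photobleaching drift on a rendered movie is corrected", {
  cfg <- small_movie_config(drift_linear_per_s = -0.01,
                            drift_exp_amplitude = -0.05,
                            drift_exp_tau_s = 1.5, seed = 12)
  sim <- simulate_ap_movie(cfg)
  cor <- correct_drift(sim$movie)
  # diastolic level across cycles should drift by < 2% of the APA (apa_df)
  tr <- cor$frames[12, 12, ]
  dia <- vapply(0:3, function(k) min(tr[(k * 500 + 1):((k + 1) * 500)]),
                numeric(1))
  expect_lt(diff(range(dia)), 0.02 * cfg$apa_df)
})

test_that("activation times recover the generative plane wave", {
  sim <- simulate_ap_movie(small_movie_config(seed = 13, cv_angle_deg = 30))
  act <- activation_map(sim$movie)
  err <- act[, , 2] - 500 - sim$truth$activation_ms
  expect_lt(max(abs(err)), 1)          # within one frame period
  # activation increases linearly along the propagation axis
  prof <- act[1, , 2]
  expect_lt(max(abs(diff(prof) - diff(prof)[1])), 0.05)
  # two identical traces shifted by k frames differ by exactly k frames
  base <- sim$movie$frames[5, 5, ]
  k <- 7
  shifted <- c(base[(k + 1):length(base)], base[1:k])
  arr <- array(0, c(1, 2, length(base)))
  arr[1, 1, ] <- base
  arr[1, 2, ] <- shifted
  mv2 <- optical_movie(arr, sim$movie$meta, sim$movie$pacing_cycle_ms)
  a2 <- activation_map(mv2)
  expect_equal(a2[1, 1, 2] - a2[1, 2, 2], k, tolerance = 1e-9)
})

test_that("APD maps hit the template's closed-form crossings", {
  sim <- simulate_ap_movie(small_movie_config(seed = 14))
  mv <- sim$movie
  act <- activation_map(mv)
  apd50 <- apd_map(mv, 0.5, act = act)
  apd80 <- apd_map(mv, 0.8, act = act)
  out <- !sim$mask$mask
  expect_lt(max(abs(apd50[, , 2][out] - 160)), 0.5)
  expect_lt(max(abs(apd80[, , 2][out] - 200)), 0.5)
  # level ordering holds everywhere, lesion included
  expect_true(all(apd80 >= apd50 - 1e-9, na.rm = TRUE))
  # lesion APD50 shortening matches the generative scale in the final cycle
  ins <- erode_mask(sim$mask, 1)
  rel <- apd50[, , 4][ins] / 160 - 1
  expect_true(all(abs(rel - (0.67 - 1)) < 0.03))
})

test_that("APA change recovers the generative amplitude loss", {
  sim <- simulate_ap_movie(small_movie_config(seed = 15))
  apa <- apa_and_delta(sim$movie, baseline_window_s = c(0, 0.5))
  ins <- sim$mask$mask
  expect_lt(max(abs(apa$delta_apa[, , 1:2])), 1e-9)       # pre-ablation ~ 0
  expect_equal(unname(apa$delta_apa[, , 4][ins]),
               rep(-0.8, sum(ins)), tolerance = 1e-6)
  expect_true(all(apa$delta_apa >= -1))
})

test_that("triangulation ratio divides APD maps elementwise", {
  expect_equal(triangulation_map(matrix(160, 2, 2), matrix(200, 2, 2)),
               matrix(0.8, 2, 2))
  m <- matrix(c(100, NA, 150, 200), 2, 2)
  r <- triangulation_map(m, m)
  expect_true(all(r[!is.na(r)] == 1))
  expect_true(is.na(r[2, 1]))
  expect_true(is.na(triangulation_map(matrix(1), matrix(0))[1, 1]))
  expect_error(triangulation_map(matrix(1, 2, 2), matrix(1, 3, 3)), "grid")
  sim <- simulate_ap_movie(small_movie_config(seed = 16))
  fm <- ap_feature_maps(sim$movie, baseline_window_s = c(0, 0.5))
  ins <- erode_mask(sim$mask, 1)
  tri <- fm$tri_ratio[, , 4]
  expect_lt(median(tri[ins]), median(tri[!sim$mask$mask]))
})

test_that("upstroke rate matches ramps and generative slowing", {
  # pure linear upstroke of slope s: measured derivative equals s
  nt <- 1000
  tr <- pmin(pmax((1:nt) - 100, 0), 200) * 0.005   # slope 0.005/frame over 200
  mv <- optical_movie(array(tr, c(1, 1, nt)),
                      simple_meta(frame_rate_hz = 1000, t0 = 0,
                                  ablation = c(NA, NA)), 1000)
  up <- upstroke_map(mv, normalize = FALSE)
  expect_lt(abs(up[1, 1, 1] / 0.005 - 1), 0.02)
  # invariance to a constant offset
  mv2 <- optical_movie(mv$frames + 3, mv$meta, 1000)
  expect_equal(upstroke_map(mv2, normalize = FALSE), up, tolerance = 1e-9)
  # lesion slowing factor recovered on the normalized scale
  sim <- simulate_ap_movie(small_movie_config(seed = 17))
  upn <- upstroke_map(sim$movie)
  ins <- erode_mask(sim$mask, 1)
  ratio <- upn[, , 4][ins] / median(upn[, , 4][!sim$mask$mask])
  expect_true(all(abs(ratio - 0.58) < 0.05))
})

test_that("conduction velocity recovers plane waves and masks degeneracy", {
  sim <- simulate_ap_movie(small_movie_config(seed = 18, cv_angle_deg = 35,
                                              cv_mm_per_ms = 0.4))
  act <- activation_map(sim$movie)
  cv <- conduction_velocity(act[, , 2], sim$movie$meta$pixel_spacing_um)
  sp <- cv$speed_mm_per_ms
  expect_lt(max(abs(sp[!is.na(sp)] / 0.4 - 1)), 0.05)
  ang <- cv$angle_deg
  expect_lt(max(abs(ang[!is.na(ang)] - 35)), 5)
  # simultaneous activation: gradient ~ 0 must be masked, not blow up
  flat <- conduction_velocity(matrix(10, 20, 20), c(250, 250))
  expect_true(all(is.na(flat$speed_mm_per_ms)))
  # rotating the activation map by 90 degrees rotates the vectors
  a <- act[, , 2]
  a_rot <- t(a)[, nrow(a):1]                      # 90 deg CCW in x/y
  cv_rot <- conduction_velocity(a_rot, sim$movie$meta$pixel_spacing_um)
  m1 <- median(cv$angle_deg, na.rm = TRUE)
  m2 <- median(cv_rot$angle_deg, na.rm = TRUE)
  expect_equal((m2 - m1) %% 360, 270, tolerance = 1)
})
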