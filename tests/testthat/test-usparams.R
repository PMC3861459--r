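test_that("grayscale map implements the dB definition", {
  A <- const_envelope(value = 2)
  gs <- grayscale_map(A, ref = 2)
  expect_true(all(gs$frames == 0))
  gs2 <- grayscale_map(A, ref = 20)
  expect_true(all(abs(gs2$frames + 20) < 1e-12))
  # doubling all amplitudes leaves pixel-to-pixel GS differences unchanged
  set.seed(1)
  fr <- array(runif(8 * 8 * 3, 0.1, 5), c(8, 8, 3))
  a1 <- envelope_sequence(fr, simple_meta())
  a2 <- envelope_sequence(2 * fr, simple_meta())
  g1 <- grayscale_map(a1)$frames
  g2 <- grayscale_map(a2)$frames
  expect_equal(g1 - mean(g1), g2 - mean(g2), tolerance = 1e-9)
  # zero amplitude maps to the floor; all-zero sequence has no reference
  a3 <- envelope_sequence(array(c(0, 1), c(4, 4, 2)), simple_meta())
  expect_equal(min(grayscale_map(a3, ref = 1)$frames), -60)
  expect_error(grayscale_map(const_envelope(0)), "reference")
})

test_that("IBS reduces to GS for a 1x1 window and matches E[A^2] = 2 alpha^2", {
  set.seed(2)
  fr <- array(runif(10 * 10 * 2, 0.1, 3), c(10, 10, 2))
  A <- envelope_sequence(fr, simple_meta())
  gs <- grayscale_map(A, ref = 1)
  ibs1 <- ibs_map(A, window_spec(1, 1), ref = 1)
  expect_equal(ibs1$frames, gs$frames, tolerance = 1e-12)
  expect_true(all(ibs_map(const_envelope(3), window_spec(3, 3), ref = 3)$frames == 0))
  # Rayleigh field: windowed IBS ~ 10 log10(2 alpha^2 / ref^2)
  set.seed(3)
  n <- 120
  ray <- array(sqrt(-2 * log(runif(n * n))), c(n, n, 1))   # alpha = 1
  Ar <- envelope_sequence(ray, simple_meta())
  ibs <- ibs_map(Ar, window_spec(101, 101), ref = 1)
  expect_lt(abs(ibs$frames[60, 60, 1] - 10 * log10(2)), 0.2)
})

test_that("closed-form MLEs reproduce hand-computed window values", {
  # Rayleigh: constant window and the {1, 1, sqrt 2, sqrt 2} example
  expect_equal(rayleigh_mle(rep(3, 10)), 3 / sqrt(2))
  expect_equal(rayleigh_mle(c(1, 1, sqrt(2), sqrt(2))), sqrt(6 / 8))
  # log-normal: {e^0, e^2} gives mu 1, sigma 1; constant gives sigma 0
  m <- lognormal_mle(c(exp(0), exp(2)))
  expect_equal(m$mu, 1)
  expect_equal(m$sigma, 1)
  expect_equal(lognormal_mle(rep(2.5, 9))$sigma, 0)
})

test_that("closed-form MLEs agree with numeric likelihood maximization", {
  set.seed(4)
  for (i in 1:10) {
    x <- sqrt(-2 * log(runif(200))) * runif(1, 0.5, 2)
    a_hat <- rayleigh_mle(x)
    nll <- function(a) -sum(log(x / a^2) - x^2 / (2 * a^2))
    a_num <- stats::optimize(nll, c(a_hat / 5, a_hat * 5), tol = 1e-12)$minimum
    expect_lt(abs(a_hat - a_num), 1e-6)
    y <- exp(rnorm(200, runif(1, -1, 1), runif(1, 0.2, 1)))
    m <- lognormal_mle(y)
    nll2 <- function(p) -sum(stats::dlnorm(y, p[1], exp(p[2]), log = TRUE))
    fit <- stats::optim(c(0, 0), nll2, method = "BFGS",
                        control = list(reltol = 1e-14))
    expect_lt(abs(m$mu - fit$par[1]), 1e-6)
    expect_lt(abs(m$sigma - exp(fit$par[2])), 1e-6)
  }
})

test_that("windowed maps respect scale equivariance and invariance", {
  ph <- small_speckle(seed = 31, n_frames = 60, shape = c(24, 24),
                      semiaxes = c(6, 5))
  A <- ph$envelope
  w <- window_spec(5, 5)
  for (c_scale in c(0.3, 2, 17)) {
    A2 <- envelope_sequence(c_scale * A$frames, A$meta)
    expect_equal(rayleigh_alpha_map(A2, w)$frames,
                 c_scale * rayleigh_alpha_map(A, w)$frames, tolerance = 1e-9)
    expect_equal(lognormal_sigma_map(A2, w)$frames,
                 lognormal_sigma_map(A, w)$frames, tolerance = 1e-9)
  }
})

test_that("map shapes and anchors align across parameters and edge policies", {
  ph <- small_speckle(seed = 32, n_frames = 60, shape = c(20, 20),
                      semiaxes = c(5, 4))
  for (edge in c("shrink", "na")) {
    w <- window_spec(7, 5, edge = edge)
    maps <- list(ibs_map(ph$envelope, w),
                 rayleigh_alpha_map(ph$envelope, w),
                 lognormal_sigma_map(ph$envelope, w))
    for (m in maps) expect_identical(dim(m$frames), dim(ph$envelope$frames))
    if (edge == "na") {
      na_pattern <- is.na(maps[[1]]$frames)
      expect_identical(is.na(maps[[2]]$frames), na_pattern)
      expect_identical(is.na(maps[[3]]$frames), na_pattern)
      expect_true(all(is.na(maps[[2]]$frames[1:3, , 1])))
    }
  }
  expect_error(ibs_map(ph$envelope, window_spec(50, 3)), "fit")
  expect_warning(rayleigh_alpha_map(const_envelope(0, n_frames = 2),
                                    window_spec(3, 3)), "all-zero")
})

test_that("goodness of fit prefers the generating model", {
  set.seed(5)
  r2_ray <- r2_log <- numeric(10)
  for (i in 1:10) {
    x <- sqrt(-2 * log(runif(1e4)))
    r2_ray[i] <- goodness_of_fit(x, "rayleigh")$r_squared_adj
    r2_log[i] <- goodness_of_fit(x, "lognormal")$r_squared_adj
  }
  expect_true(all(r2_ray >= 0.98))
  expect_gte(sum(r2_log < r2_ray), 9)
  g <- goodness_of_fit(sqrt(-2 * log(runif(1e4))), "rayleigh")
  expect_identical(g$dof, 43L)   # 45 bins - 1 parameter - 1
  expect_error(goodness_of_fit(rep(1, 200), "rayleigh"), "degenerate")
  expect_error(goodness_of_fit(runif(50), "rayleigh"), "100")
})
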