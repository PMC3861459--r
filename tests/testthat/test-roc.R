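test_that("ROC AUC matches hand counts and the pair-counting oracle", {
  r <- roc_curve(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$auc, 0.75)
  expect_equal(r$auc, auc_pair_count(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)))
  # random instances with heavy ties
  set.seed(1)
  for (i in 1:50) {
    n <- sample(5:120, 1)
    sc <- round(runif(n), 1)
    lab <- runif(n) < 0.5
    if (!any(lab) || all(lab)) next
    expect_equal(roc_curve(sc, lab)$auc, auc_pair_count(sc, lab),
                 tolerance = 1e-12)
  }
  # invariance under strictly monotone score transforms
  set.seed(2)
  sc <- rnorm(300); lab <- runif(300) < 0.4
  expect_equal(roc_curve(exp(sc), lab)$auc, roc_curve(sc, lab)$auc,
               tolerance = 1e-12)
  expect_equal(roc_curve(qnorm(rank(sc) / 301), lab)$auc,
               roc_curve(sc, lab)$auc, tolerance = 1e-12)
  expect_error(roc_curve(1:5, rep(TRUE, 5)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  sc <- round(rnorm(400), 1)
  lab <- runif(400) < 0.5 + 0.3 * (sc > 0)
  expect_equal(roc_curve(sc, lab)$auc,
               as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("extreme cases give chance and perfect AUC", {
  expect_equal(roc_curve(c(1, 2, 3, 10, 11, 12),
                         c(F, F, F, T, T, T))$auc, 1)
  set.seed(4)
  sc <- rnorm(4000); lab <- runif(4000) < 0.5
  expect_lt(abs(roc_curve(sc, lab)$auc - 0.5), 0.05)
})

test_that("the Youden threshold maximizes J and splits separated clusters", {
  set.seed(5)
  lo <- runif(40, 0, 0.2); hi <- runif(30, 0.6, 1)
  r <- roc_curve(c(lo, hi), rep(c(FALSE, TRUE), c(40, 30)))
  op <- optimal_threshold(r)
  expect_equal(op$youden_j, 1)
  expect_equal(op$threshold, (max(lo) + min(hi)) / 2)   # midpoint of the gap
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)
  # J at the returned operating point dominates every curve point
  sc <- rnorm(500) + rep(c(0, 1), c(300, 200))
  lab <- rep(c(FALSE, TRUE), c(300, 200))
  r2 <- roc_curve(sc, lab)
  op2 <- optimal_threshold(r2)
  expect_true(all(r2$curve$tpr - r2$curve$fpr <= op2$youden_j + 1e-12))
  m <- roc_metrics(sc, lab, op2$threshold)
  expect_equal(m$sensitivity + m$specificity - 1, op2$youden_j,
               tolerance = 1e-12)
})

test_that("leave-one-out folds behave at the degenerate extremes", {
  set.seed(6)
  base <- data.frame(score = c(rnorm(100, 1), rnorm(200, 0)),
                     label = rep(c(TRUE, FALSE), c(100, 200)))
  # identical subjects: zero variance across folds
  df <- do.call(rbind, lapply(1:4, function(s) transform(base, subject = s)))
  cv <- loo_cv(df$score, df$label, df$subject)
  expect_equal(cv$heldout_auc_sd, 0)
  expect_equal(cv$threshold_sd, 0)
  expect_equal(cv$heldout_auc, cv$train_auc)
  # permuted labels: held-out AUC near chance
  set.seed(7)
  dfn <- do.call(rbind, lapply(1:6, function(s)
    data.frame(score = rnorm(400), label = runif(400) < 0.4, subject = s)))
  cvn <- loo_cv(dfn$score, dfn$label, dfn$subject)
  expect_lt(abs(cvn$heldout_auc - 0.5), 0.06)
  # single-class subjects are skipped with a warning
  dfs <- rbind(df, data.frame(score = rnorm(50), label = TRUE, subject = 9))
  expect_warning(cv2 <- loo_cv(dfs$score, dfs$label, dfs$subject),
                 "single-class")
  expect_identical(nrow(cv2$folds), 4L)
  expect_error(loo_cv(base$score, base$label, rep(1, nrow(base))), "3 usable")
})

test_that("detection time courses track a ramped lesion", {
  ph <- small_speckle(seed = 61)
  sg <- lognormal_sigma_map(ph$envelope, window_spec(7, 7, edge = "na"))
  ex <- cumulative_extrema(sg)
  nt <- dim(ex$raw)[3]
  thr <- optimal_threshold(roc_curve(as.vector(ex$normalized[, , nt]),
                                     as.vector(ph$mask$mask)))$threshold
  tc <- detection_timecourse(ex$normalized, ph$mask, thr)
  expect_identical(nrow(tc), nt)
  # chance-level before ablation, high at the end
  expect_lt(abs(tc$auc[1] - 0.5), 0.2)
  expect_gt(tc$auc[nt], 0.95)
  # fixed threshold on a monotone extrema map: predictions never shrink
  expect_true(all(diff(tc$positive_fraction) >= -1e-12))
  expect_error(detection_timecourse(ex$normalized,
                                    matrix(FALSE, 48, 48)), "empty truth")
})

test_that("the band classifier partitions ΔAPA as configured", {
  da <- matrix(c(-0.5, -0.3, 0, -0.43, -0.19, NA), 2, 3)
  b <- band_classifier(da)
  expect_identical(b[1, 1], 2L)        # below the lesion bound
  expect_identical(b[2, 1], 1L)        # in the non-lesion change band
  expect_identical(b[1, 2], 0L)        # unchanged
  expect_identical(b[2, 2], 1L)        # exactly at the lesion bound
  expect_identical(b[1, 3], 0L)        # exactly at the change bound
  expect_true(is.na(b[2, 3]))
  expect_error(band_classifier(da, bounds = c(-0.1, -0.4)), "increasing")
})

test_that("group comparison flags distribution shifts", {
  set.seed(8)
  v <- c(rnorm(50), rnorm(50, 2))
  g <- rep(c("a", "b"), each = 50)
  expect_lt(kw_test(v, g)$p.value, 1e-6)
  expect_gt(kw_test(rnorm(100), g)$p.value, 0.01)
})
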