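fir_kernel <- function(fs, band_hz, order) {
  ny <- fs / 2
  if (band_hz[length(band_hz)] >= ny)
    stop("filter band edge must be below Nyquist")
  if (band_hz[1] <= 0) {
    b <- as.numeric(signal::fir1(order, band_hz[2] / ny, type = "low"))
    b <- b / sum(b)  # exact unit gain at DC
  } else {
    b <- as.numeric(signal::fir1(order, band_hz / ny, type = "pass"))
    b <- b - mean(b)  # exact null at DC
  }
  b
}

# zero-phase FIR filtering of trace columns via FFT with reflective padding;
# the kernel is symmetric (linear phase), applied once centred: zero net delay
filter_columns <- function(m, b) {
  nt <- nrow(m)
  h <- (length(b) - 1) %/% 2
  if (nt <= length(b)) stop("traces shorter than the filter warm-up length")
  pad_top <- m[(h + 1):2, , drop = FALSE]
  pad_bot <- m[(nt - 1):(nt - h), , drop = FALSE]
  mp <- rbind(pad_top, m, pad_bot)
  np <- nrow(mp)
  k <- numeric(np)
  k[1] <- b[h + 1]
  k[2:(h + 1)] <- b[(h + 2):length(b)]
  k[(np - h + 1):np] <- b[1:h]
  H <- Re(stats::fft(k))
  filt <- Re(stats::mvfft(stats::mvfft(mp) * H, inverse = TRUE)) / np
  filt[(h + 1):(h + nt), , drop = FALSE]
}

frames_to_traces <- function(frames) {
  d <- dim(frames)
  t(matrix(frames, d[1] * d[2], d[3]))  # nt x npix
}

traces_to_frames <- function(traces, shape) {
  array(t(traces), c(shape, nrow(traces)))
}

#' Spatiotemporal preprocessing of an optical movie
#'
#' 3 x 3 spatial binning (mean over the neighbourhood, truncated at the
#' border) followed by a zero-phase band-pass FIR filter of each pixel trace.
#' The FIR kernel is symmetric (linear phase) and applied centred, so the net
#' group delay is zero; its DC gain is forced to exactly zero so constant
#' offsets are removed by the high-pass edge.
#'
#' @param movie An [optical_movie()]; frame rate must be at least 200 Hz so
#'   the default band sits below Nyquist.
#' @param bin Spatial binning width in pixels (odd; 1 disables).
#' @param band_hz Band edges in Hz; a non-positive lower edge gives a pure
#'   low-pass.
#' @param order FIR order; the movie must be longer than the kernel.
#' @return A filtered [optical_movie()].
#' @export
preprocess_movie <- function(movie, bin = 3, band_hz = c(1, 100), order = 1024) {
  stopifnot(inherits(movie, "optical_movie"))
  fs <- movie$meta$frame_rate_hz
  if (fs < 200) stop("frame rate must be >= 200 Hz for the default band")
  kern <- fir_kernel(fs, band_hz, order)
  fr <- movie$frames
  if (bin > 1 && all(dim(fr)[1:2] >= bin)) {
    for (t in seq_len(dim(fr)[3])) {
      bs <- box_sum(fr[, , t], bin, bin)
      fr[, , t] <- bs$sum / bs$n
    }
  }
  tr <- frames_to_traces(fr)
  tr <- filter_columns(tr, kern)
  optical_movie(traces_to_frames(tr, dim(fr)[1:2]), movie$meta,
                movie$pacing_cycle_ms)
}

#' Fractional fluorescence change
#'
#' Converts raw fluorescence to `dF = (F - F0) / F0` per pixel, with the
#' background `F0` estimated as the mean of the lowest `diastolic_fraction`
#' of each pixel's samples (the diastolic level).
#'
#' @param movie An [optical_movie()] of raw fluorescence.
#' @param diastolic_fraction Fraction of lowest samples defining `F0`.
#' @return An [optical_movie()] of fractional change; pixels with `F0 <= 0`
#'   become `NA`.
#' @export
delta_f_movie <- function(movie, diastolic_fraction = 0.2) {
  stopifnot(inherits(movie, "optical_movie"))
  tr <- frames_to_traces(movie$frames)
  q <- apply(tr, 2, stats::quantile, probs = diastolic_fraction, names = FALSE)
  f0 <- vapply(seq_len(ncol(tr)),
               function(j) mean(tr[tr[, j] <= q[j], j]), numeric(1))
  bad <- f0 <= 0 | !is.finite(f0)
  f0[bad] <- NA_real_
  tr <- sweep(sweep(tr, 2, f0, `-`), 2, f0, `/`)
  optical_movie_na(traces_to_frames(tr, dim(movie$frames)[1:2]), movie$meta,
                   movie$pacing_cycle_ms)
}

# internal constructor tolerating NA pixels (masked)
optical_movie_na <- function(frames, meta, pacing_cycle_ms) {
  structure(list(frames = frames, meta = meta,
                 pacing_cycle_ms = as.numeric(pacing_cycle_ms)),
            class = c("optical_movie", "frame_stack"))
}

#' Beat-ensemble average of selected pacing cycles
#'
#' Averages the frames of the selected cycles sample-by-sample (classic beat
#' averaging), reducing uncorrelated noise by the square root of the number
#' of cycles without distorting the AP shape.  Use steady-state cycles
#' (all-baseline, or all post-ablation).
#'
#' @param movie An [optical_movie()].
#' @param cycles Integer indices of the cycles to average.
#' @return A one-cycle [optical_movie()].
#' @export
average_cycles <- function(movie, cycles) {
  cyc <- cycle_windows(movie)
  if (any(cycles < 1 | cycles > nrow(cyc))) stop("cycle index out of range")
  spc <- cyc[1, 2] - cyc[1, 1] + 1L
  acc <- array(0, c(dim(movie$frames)[1:2], spc))
  for (k in cycles)
    acc <- acc + movie$frames[, , cyc[k, 1]:cyc[k, 2], drop = FALSE]
  optical_movie_na(acc / length(cycles), movie$meta, movie$pacing_cycle_ms)
}

#' Pacing cycle windows of a movie
#'
#' @param movie An [optical_movie()].
#' @return Integer matrix with one row per complete cycle, columns
#'   `start`, `end` (frame indices).
#' @export
cycle_windows <- function(movie) {
  fs <- movie$meta$frame_rate_hz
  spc <- round(movie$pacing_cycle_ms * fs / 1000)
  nt <- dim(movie$frames)[3]
  nc <- nt %/% spc
  if (nc < 1) stop("movie shorter than one pacing cycle")
  cbind(start = (seq_len(nc) - 1L) * spc + 1L, end = seq_len(nc) * spc)
}

#' Baseline-drift correction
#'
#' Fits a drift model to the diastolic samples (by default the last 10% of
#' each pacing cycle, just before the next stimulus) and subtracts the fitted
#' drift from the whole trace.  `model = "auto"` fits linear, logarithmic and
#' cubic-polynomial models and keeps, per pixel, the one with the smallest
#' residual on the baseline samples.
#'
#' @param x An [optical_movie()] or a numeric trace.
#' @param frame_rate_hz,pacing_cycle_ms Required when `x` is a bare trace.
#' @param model `"auto"`, `"linear"`, `"log"`, or `"poly"`.
#' @param poly_degree Degree of the polynomial model.
#' @param baseline_fraction Fraction of each cycle (taken from its end) used
#'   as drift-fit support.
#' @return Same type as `x`, drift-corrected (diastolic level near zero).
#' @export
correct_drift <- function(x, frame_rate_hz = NULL, pacing_cycle_ms = NULL,
                          model = c("auto", "linear", "log", "poly"),
                          poly_degree = 3, baseline_fraction = 0.1) {
  model <- match.arg(model)
  if (inherits(x, "optical_movie")) {
    tr <- frames_to_traces(x$frames)
    fs <- x$meta$frame_rate_hz
    cl <- x$pacing_cycle_ms
  } else {
    if (is.null(frame_rate_hz) || is.null(pacing_cycle_ms))
      stop("frame_rate_hz and pacing_cycle_ms are required for a bare trace")
    tr <- matrix(x, ncol = 1)
    fs <- frame_rate_hz
    cl <- pacing_cycle_ms
  }
  nt <- nrow(tr)
  spc <- round(cl * fs / 1000)
  ncyc <- nt %/% spc
  nb <- max(1L, round(baseline_fraction * spc))
  bidx <- as.vector(vapply(seq_len(ncyc),
                           function(k) (k * spc - nb + 1L):(k * spc),
                           integer(nb)))
  bidx <- bidx[bidx >= 1 & bidx <= nt]
  times <- (seq_len(nt) - 1) / fs
  npar_needed <- if (model == "poly") poly_degree + 1
                 else if (model == "auto") max(2, poly_degree + 1) else 2
  if (length(bidx) < npar_needed)
    stop("fewer baseline samples than model parameters")
  designs <- list(
    linear = cbind(1, times),
    log = cbind(1, log1p(times)),
    poly = cbind(1, stats::poly(times, degree = poly_degree, raw = FALSE)))
  use <- if (model == "auto") names(designs) else model
  fits <- lapply(designs[use], function(D) {
    f <- stats::lm.fit(D[bidx, , drop = FALSE], tr[bidx, , drop = FALSE])
    pred <- D %*% f$coefficients
    rss <- colSums((tr[bidx, , drop = FALSE] - pred[bidx, , drop = FALSE])^2)
    list(pred = pred, rss = rss)
  })
  if (length(fits) == 1) {
    corrected <- tr - fits[[1]]$pred
  } else {
    rss <- do.call(cbind, lapply(fits, `[[`, "rss"))
    best <- max.col(-rss, ties.method = "first")
    corrected <- tr
    for (i in seq_along(fits)) {
      sel <- best == i
      if (any(sel))
        corrected[, sel] <- tr[, sel, drop = FALSE] -
          fits[[i]]$pred[, sel, drop = FALSE]
    }
  }
  if (inherits(x, "optical_movie"))
    optical_movie_na(traces_to_frames(corrected, dim(x$frames)[1:2]),
                     x$meta, x$pacing_cycle_ms)
  else as.vector(corrected)
}

# central-difference temporal derivative of traces (nt x npix), per ms
trace_derivative <- function(tr, fs) {
  nt <- nrow(tr)
  d <- matrix(NA_real_, nt, ncol(tr))
  dt_ms <- 1000 / fs
  d[2:(nt - 1), ] <- (tr[3:nt, , drop = FALSE] - tr[1:(nt - 2), , drop = FALSE]) /
    (2 * dt_ms)
  d
}

# per-cycle arg-max of the derivative with parabolic sub-frame refinement;
# a short centred boxcar (smooth_ms) suppresses peak-picking noise bias while
# leaving ramps and symmetric peaks unbiased; returns activation times
# (ms, movie clock) and refined peak values
derivative_peaks <- function(tr, fs, cyc, refine = TRUE, smooth_ms = 5) {
  dt_ms <- 1000 / fs
  d <- trace_derivative(tr, fs)
  k <- max(1L, round(smooth_ms * fs / 1000))
  if (k %% 2 == 0) k <- k + 1L
  if (k > 1) {
    dsm <- stats::filter(d, rep(1 / k, k), sides = 2)
    d <- matrix(as.numeric(dsm), nrow(d), ncol(d))
  }
  npix <- ncol(tr)
  ncyc <- nrow(cyc)
  act <- matrix(NA_real_, npix, ncyc)
  pk <- matrix(NA_real_, npix, ncyc)
  for (k in seq_len(ncyc)) {
    win <- cyc[k, 1]:cyc[k, 2]
    dw <- d[win, , drop = FALSE]
    dw[is.na(dw)] <- -Inf
    j <- max.col(t(dw), ties.method = "first")
    flat <- apply(tr[win, , drop = FALSE], 2,
                  function(v) max(v) - min(v)) == 0
    y2 <- dw[cbind(j, seq_len(npix))]
    delta <- numeric(npix)
    yref <- y2
    interior <- j > 1 & j < length(win)
    if (refine && any(interior)) {
      ii <- which(interior)
      y1 <- dw[cbind(j[ii] - 1L, ii)]
      y3 <- dw[cbind(j[ii] + 1L, ii)]
      den <- y1 - 2 * y2[ii] + y3
      ok <- is.finite(den) & abs(den) > .Machine$double.eps
      dl <- numeric(length(ii))
      dl[ok] <- 0.5 * (y1[ok] - y3[ok]) / den[ok]
      dl <- pmin(pmax(dl, -1), 1)
      delta[ii] <- dl
      yref[ii] <- y2[ii] - 0.25 * (y1 - y3) * dl
    }
    t_ms <- (win[j] - 1 + delta) * dt_ms
    t_ms[flat] <- NA_real_
    yref[flat] <- NA_real_
    act[, k] <- t_ms
    pk[, k] <- yref
  }
  list(act_ms = act, peak = pk)
}

#' Per-pixel, per-cycle activation times
#'
#' Activation is the time at which `d(dF)/dt` reaches its maximum within each
#' pacing cycle (central differences, with parabolic sub-frame refinement of
#' the derivative peak).  Flat traces give `NA`.
#'
#' @param movie An [optical_movie()] (filtered / fractional-change data).
#' @param refine Parabolic sub-frame interpolation of the peak time.
#' @param smooth_ms Centred boxcar applied to the derivative before peak
#'   picking (ms; 0 disables).
#' @return 3D array `(rows, cols, cycle)` of activation times in ms on the
#'   movie clock.
#' @export
activation_map <- function(movie, refine = TRUE, smooth_ms = 5) {
  stopifnot(inherits(movie, "optical_movie"))
  cyc <- cycle_windows(movie)
  tr <- frames_to_traces(movie$frames)
  dp <- derivative_peaks(tr, movie$meta$frame_rate_hz, cyc, refine, smooth_ms)
  array(dp$act_ms, c(dim(movie$frames)[1:2], nrow(cyc)))
}

per_cycle_extrema <- function(tr, cyc) {
  npix <- ncol(tr)
  ncyc <- nrow(cyc)
  pk <- matrix(NA_real_, npix, ncyc)
  pk_idx <- matrix(NA_integer_, npix, ncyc)
  dia <- matrix(NA_real_, npix, ncyc)
  for (k in seq_len(ncyc)) {
    w <- tr[cyc[k, 1]:cyc[k, 2], , drop = FALSE]
    jmax <- max.col(t(w), ties.method = "first")
    jmin <- max.col(-t(w), ties.method = "first")
    pk[, k] <- w[cbind(jmax, seq_len(npix))]
    dia[, k] <- w[cbind(jmin, seq_len(npix))]
    pk_idx[, k] <- cyc[k, 1] + jmax - 1L
  }
  list(peak = pk, peak_idx = pk_idx, diastole = dia)
}

#' Action-potential duration maps
#'
#' APD at fraction `f` of repolarization: the time from the activation
#' instant to the first post-peak crossing of the level
#' `diastole + (1 - f) * (peak - diastole)` (amplitude fallen to `(1 - f)` of
#' the peak above diastole), with linear sub-frame interpolation at the
#' crossing.  Traces that never repolarize to the level within the cycle give
#' `NA`.
#'
#' @param movie An [optical_movie()].
#' @param fraction Repolarization fraction, e.g. `0.5` (APD50) or `0.8`
#'   (APD80).
#' @param act Optional precomputed [activation_map()] result.
#' @return 3D array `(rows, cols, cycle)` of APDs in ms.
#' @export
apd_map <- function(movie, fraction = 0.5, act = NULL) {
  stopifnot(inherits(movie, "optical_movie"),
            fraction > 0, fraction < 1)
  cyc <- cycle_windows(movie)
  tr <- frames_to_traces(movie$frames)
  fs <- movie$meta$frame_rate_hz
  dt_ms <- 1000 / fs
  if (is.null(act)) act <- activation_map(movie)
  shape <- dim(movie$frames)[1:2]
  npix <- prod(shape)
  ncyc <- nrow(cyc)
  actm <- matrix(act, npix, ncyc)
  ex <- per_cycle_extrema(tr, cyc)
  apd <- matrix(NA_real_, npix, ncyc)
  for (k in seq_len(ncyc)) {
    lo <- cyc[k, 1]; hi <- cyc[k, 2]
    for (p in seq_len(npix)) {
      a <- actm[p, k]
      if (is.na(a)) next
      pkv <- ex$peak[p, k]; dv <- ex$diastole[p, k]
      amp <- pkv - dv
      if (!is.finite(amp) || amp <= 0) next
      level <- dv + (1 - fraction) * amp
      j0 <- ex$peak_idx[p, k]
      v <- tr[j0:hi, p]
      below <- which(v <= level)
      if (length(below) == 0) next
      jb <- below[1]
      if (jb == 1) {
        t_cross <- (j0 - 1) * dt_ms
      } else {
        v1 <- v[jb - 1]; v2 <- v[jb]
        fr <- (v1 - level) / (v1 - v2)
        t_cross <- (j0 + jb - 2 - 1 + fr) * dt_ms
      }
      apd[p, k] <- t_cross - a
    }
  }
  array(apd, c(shape, ncyc))
}

#' AP amplitude and its change relative to the pre-ablation baseline
#'
#' The per-cycle amplitude (peak minus diastole of the trace) is normalized
#' by the per-pixel mean amplitude over the baseline cycles (those starting
#' inside `baseline_window_s`), so baseline APA is 1 by construction;
#' `dAPA = APA - 1` (negative = reduction).
#'
#' @param movie An [optical_movie()].
#' @param baseline_window_s Time window (s, movie clock) whose cycles define
#'   the baseline.
#' @return `list(apa, delta_apa, apa_raw, baseline_cycles)`; `apa` and
#'   `delta_apa` are `(rows, cols, cycle)` arrays; pixels with zero baseline
#'   amplitude are `NA`.
#' @export
apa_and_delta <- function(movie, baseline_window_s = c(1, 4)) {
  stopifnot(inherits(movie, "optical_movie"))
  cyc <- cycle_windows(movie)
  fs <- movie$meta$frame_rate_hz
  start_s <- (cyc[, 1] - 1) / fs
  bcyc <- which(start_s >= baseline_window_s[1] & start_s < baseline_window_s[2])
  if (length(bcyc) == 0) stop("no cycles inside the baseline window")
  tr <- frames_to_traces(movie$frames)
  ex <- per_cycle_extrema(tr, cyc)
  amp <- ex$peak - ex$diastole
  base <- rowMeans(amp[, bcyc, drop = FALSE])
  base[base <= 0 | !is.finite(base)] <- NA_real_
  apa <- amp / base
  shape <- dim(movie$frames)[1:2]
  list(apa = array(apa, c(shape, nrow(cyc))),
       delta_apa = array(apa - 1, c(shape, nrow(cyc))),
       apa_raw = array(amp, c(shape, nrow(cyc))),
       baseline_cycles = bcyc)
}

#' AP triangulation (APD50 / APD80 ratio) map
#'
#' @param apd50,apd80 APD arrays or matrices on the same grid.
#' @return Element-wise ratio; `NA` where either input is missing, `NA` where
#'   APD80 is zero.
#' @export
triangulation_map <- function(apd50, apd80) {
  if (!all(dim(apd50) == dim(apd80))) stop("APD maps must share a grid")
  r <- apd50 / apd80
  r[!is.finite(r)] <- NA_real_
  r
}

#' Maximum upstroke rate map
#'
#' Per cycle, the maximum temporal derivative of the per-cycle normalized
#' trace (0..1 between diastole and peak), in units of normalized amplitude
#' per ms, with parabolic refinement of the derivative peak value.
#'
#' @param movie An [optical_movie()].
#' @param normalize Normalize each cycle to 0..1 before differentiating; with
#'   `FALSE` the value is on the trace's own amplitude scale.
#' @param smooth_ms Centred boxcar applied to the derivative before peak
#'   picking (ms; 0 disables).
#' @return 3D array `(rows, cols, cycle)`.
#' @export
upstroke_map <- function(movie, normalize = TRUE, smooth_ms = 5) {
  stopifnot(inherits(movie, "optical_movie"))
  cyc <- cycle_windows(movie)
  tr <- frames_to_traces(movie$frames)
  fs <- movie$meta$frame_rate_hz
  if (normalize) {
    ex <- per_cycle_extrema(tr, cyc)
    trn <- tr
    for (k in seq_len(nrow(cyc))) {
      w <- cyc[k, 1]:cyc[k, 2]
      amp <- ex$peak[, k] - ex$diastole[, k]
      amp[amp <= 0] <- NA_real_
      trn[w, ] <- sweep(sweep(tr[w, , drop = FALSE], 2, ex$diastole[, k], `-`),
                        2, amp, `/`)
    }
    tr <- trn
  }
  dp <- derivative_peaks(tr, fs, cyc, refine = TRUE, smooth_ms = smooth_ms)
  array(dp$peak, c(dim(movie$frames)[1:2], nrow(cyc)))
}

#' Conduction-velocity vector field from an activation map
#'
#' Fits a local plane to the activation time over a square neighbourhood and
#' converts its gradient `g` (ms/mm) to the conduction-velocity vector
#' `CV = g / |g|^2` (mm/ms, pointing along propagation).  Pixels whose
#' gradient magnitude falls below `min_grad_ms_per_mm` (near-simultaneous
#' activation) and border pixels without a full neighbourhood are masked.
#'
#' @param act Activation-time matrix in ms (one cycle), `NA` allowed.
#' @param pixel_spacing_um Pixel spacing `(axial/row, lateral/col)` in um.
#' @param neighborhood Odd window size for the plane fit (default 5).
#' @param min_grad_ms_per_mm Gradient-magnitude mask threshold.
#' @return `list(vx, vy, speed_mm_per_ms, angle_deg)` matrices; `vx` is the
#'   column (lateral) component, `vy` the row component, angle measured from
#'   +x toward +y (rows).
#' @export
conduction_velocity <- function(act, pixel_spacing_um,
                                neighborhood = 5, min_grad_ms_per_mm = 0.02) {
  if (length(dim(act)) == 3) act <- act[, , 1]
  if (!is.matrix(act)) stop("act must be a matrix")
  h <- neighborhood
  if (h %% 2 != 1) stop("neighborhood must be odd")
  nr <- nrow(act); nc <- ncol(act)
  sy <- pixel_spacing_um[1] / 1000  # mm per row
  sx <- pixel_spacing_um[2] / 1000  # mm per col
  xmm <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE) * sx
  ymm <- matrix(seq_len(nr) - 1, nr, nc) * sy
  Tn <- act
  nas <- is.na(Tn)
  Tz <- ifelse(nas, 0, Tn)
  ok <- 1 - nas
  bs_n  <- box_sum(ok, h, h)
  bs_t  <- box_sum(Tz, h, h)
  bs_x  <- box_sum(ok * xmm, h, h)
  bs_y  <- box_sum(ok * ymm, h, h)
  bs_tx <- box_sum(Tz * xmm, h, h)
  bs_ty <- box_sum(Tz * ymm, h, h)
  bs_xx <- box_sum(ok * xmm^2, h, h)
  bs_yy <- box_sum(ok * ymm^2, h, h)
  n <- bs_n$sum
  # centred least-squares slopes (x and y are separable over a full window;
  # with missing pixels this is an approximation, so demand few misses)
  sxx <- bs_xx$sum - bs_x$sum^2 / n
  syy <- bs_yy$sum - bs_y$sum^2 / n
  stx <- bs_tx$sum - bs_t$sum * bs_x$sum / n
  sty <- bs_ty$sum - bs_t$sum * bs_y$sum / n
  gx <- stx / sxx
  gy <- sty / syy
  valid <- bs_n$interior & (n >= 0.8 * h * h) & sxx > 0 & syy > 0
  gx[!valid] <- NA_real_
  gy[!valid] <- NA_real_
  g2 <- gx^2 + gy^2
  low <- sqrt(g2) < min_grad_ms_per_mm
  vx <- gx / g2
  vy <- gy / g2
  vx[low] <- NA_real_
  vy[low] <- NA_real_
  speed <- sqrt(vx^2 + vy^2)
  angle <- atan2(vy, vx) * 180 / pi
  list(vx = vx, vy = vy, speed_mm_per_ms = speed, angle_deg = angle)
}

#' All EP feature maps of a movie
#'
#' Convenience wrapper: activation, APD50/APD80 and their ratio, APA and
#' dAPA, upstroke rate, and the conduction-velocity field of one reference
#' cycle.
#'
#' @param movie An [optical_movie()] (already preprocessed/drift-corrected as
#'   appropriate).
#' @param baseline_window_s Baseline window for APA normalization (s).
#' @param cv_cycle Cycle index whose activation map feeds the CV fit.
#' @return Object of class `ap_feature_maps`.
#' @export
ap_feature_maps <- function(movie, baseline_window_s = c(1, 4), cv_cycle = 1) {
  act <- activation_map(movie)
  apd50 <- apd_map(movie, 0.5, act = act)
  apd80 <- apd_map(movie, 0.8, act = act)
  apa <- apa_and_delta(movie, baseline_window_s)
  cv <- conduction_velocity(act[, , cv_cycle], movie$meta$pixel_spacing_um)
  structure(list(activation_ms = act,
                 apd50_ms = apd50, apd80_ms = apd80,
                 tri_ratio = triangulation_map(apd50, apd80),
                 apa = apa$apa, delta_apa = apa$delta_apa,
                 upstroke = upstroke_map(movie),
                 cv = cv,
                 baseline_cycles = apa$baseline_cycles),
            class = "ap_feature_maps")
}

#' @export
print.ap_feature_maps <- function(x, ...) {
  d <- dim(x$activation_ms)
  cat(sprintf("<ap_feature_maps> %d x %d px, %d cycles\n", d[1], d[2], d[3]))
  lastc <- d[3]
  cat(sprintf("  final-cycle dAPA: median %.3f (min %.3f)\n",
              stats::median(x$delta_apa[, , lastc], na.rm = TRUE),
              min(x$delta_apa[, , lastc], na.rm = TRUE)))
  cat(sprintf("  APD50/APD80 (cycle 1): median %.3f / %.3f ms\n",
              stats::median(x$apd50_ms[, , 1], na.rm = TRUE),
              stats::median(x$apd80_ms[, , 1], na.rm = TRUE)))
  invisible(x)
}
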