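#' Sliding estimation window specification
#'
#' @param height_px,width_px Window extent in pixels (rows, cols).  The
#'   default 100 x 13 is the standard estimation window for high-frequency
#'   envelope statistics at this pixel scale.
#' @param stride Length-2 integer `(row, col)` stride between anchors.
#' @param edge `"shrink"` recomputes border anchors with the window truncated
#'   at the frame boundary (map keeps the frame shape); `"na"` marks them NA.
#' @return Object of class `window_spec`.
#' @export
window_spec <- function(height_px = 100, width_px = 13, stride = c(1L, 1L),
                        edge = c("shrink", "na")) {
  edge <- match.arg(edge)
  if (height_px < 1 || width_px < 1) stop("window must be at least 1 x 1")
  if (any(stride < 1)) stop("stride must be >= 1")
  structure(list(height_px = as.integer(height_px),
                 width_px = as.integer(width_px),
                 stride = as.integer(rep(stride, length.out = 2)),
                 edge = edge),
            class = "window_spec")
}

# clamped integral-image window sums; returns list(sum, n) of frame shape
box_sum <- function(m, h, w) {
  nr <- nrow(m); nc <- ncol(m)
  if (h > nr || w > nc) stop("window does not fit inside the frame")
  A <- apply(m, 2, cumsum)
  if (is.null(dim(A))) A <- matrix(A, nrow = nr)
  B <- t(apply(A, 1, cumsum))
  if (is.null(dim(B))) B <- matrix(B, nrow = nr)
  S <- matrix(0, nr + 1, nc + 1)
  S[-1, -1] <- B
  top <- (h - 1) %/% 2; bot <- h - 1 - top
  left <- (w - 1) %/% 2; right <- w - 1 - left
  r1 <- pmax(seq_len(nr) - top, 1L); r2 <- pmin(seq_len(nr) + bot, nr)
  c1 <- pmax(seq_len(nc) - left, 1L); c2 <- pmin(seq_len(nc) + right, nc)
  s <- S[r2 + 1, c2 + 1, drop = FALSE] - S[r1, c2 + 1, drop = FALSE] -
       S[r2 + 1, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
  n <- outer(r2 - r1 + 1, c2 - c1 + 1)
  list(sum = s, n = n,
       interior = outer(seq_len(nr) - top >= 1 & seq_len(nr) + bot <= nr,
                        seq_len(nc) - left >= 1 & seq_len(nc) + right <= nc,
                        `&`))
}

apply_edge_stride <- function(x, w, interior) {
  if (w$edge == "na") x[!interior] <- NA_real_
  if (any(w$stride > 1L))
    x <- x[seq(1, nrow(x), by = w$stride[1]),
           seq(1, ncol(x), by = w$stride[2]), drop = FALSE]
  x
}

new_param_map <- function(param, frames, units, meta, window = NULL) {
  structure(list(param = param, frames = frames, units = units, meta = meta,
                 window = window),
            class = "parametric_map_sequence")
}

#' @export
print.parametric_map_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<parametric_map_sequence> %s [%s], %d x %d px, %d frames\n",
              x$param, x$units, d[1], d[2], d[3]))
  invisible(x)
}

baseline_frame_idx <- function(meta, nt) {
  aw <- meta$ablation_window_s
  times <- meta$time_origin_s + (seq_len(nt) - 1) / meta$frame_rate_hz
  if (all(is.finite(aw))) which(times < aw[1]) else integer(0)
}

reference_amplitude <- function(A) {
  nt <- dim(A$frames)[3]
  idx <- baseline_frame_idx(A$meta, nt)
  if (length(idx) == 0) idx <- seq_len(nt)
  ref <- max(A$frames[, , idx])
  if (ref <= 0) stop("no positive reference amplitude (all-zero sequence)")
  ref
}

#' Grayscale (log-compressed envelope) map
#'
#' `GS = 20 log10(A / ref)` per pixel, with `ref` the maximum envelope over
#' the pre-ablation baseline frames by default.  Zero amplitudes map to
#' `floor_db`.
#'
#' @param A An [envelope_sequence()].
#' @param ref Positive reference amplitude; default from the baseline frames.
#' @param floor_db Value assigned where `A == 0`.
#' @return A `parametric_map_sequence` (param `"GS"`, units dB).
#' @export
grayscale_map <- function(A, ref = NULL, floor_db = -60) {
  stopifnot(inherits(A, "envelope_sequence"))
  if (is.null(ref)) ref <- reference_amplitude(A)
  if (ref <= 0) stop("ref must be positive")
  gs <- 20 * log10(A$frames / ref)
  gs[A$frames == 0] <- floor_db
  new_param_map("GS", gs, "dB", A$meta)
}

#' Integrated backscatter (IBS) map
#'
#' Per pixel, `IBS = 10 log10( mean over window of A^2 / ref^2 )`, the
#' windowed mean-square envelope in dB relative to the same reference as
#' [grayscale_map()].  A 1 x 1 window reduces IBS to the GS value.
#'
#' @param A An [envelope_sequence()].
#' @param w A [window_spec()].
#' @inheritParams grayscale_map
#' @return A `parametric_map_sequence` (param `"IBS"`, units dB).
#' @export
ibs_map <- function(A, w = window_spec(), ref = NULL, floor_db = -60) {
  stopifnot(inherits(A, "envelope_sequence"), inherits(w, "window_spec"))
  if (is.null(ref)) ref <- reference_amplitude(A)
  nt <- dim(A$frames)[3]
  out <- NULL
  for (t in seq_len(nt)) {
    bs <- box_sum(A$frames[, , t]^2, w$height_px, w$width_px)
    ms <- bs$sum / bs$n
    v <- ifelse(ms > 0, 10 * log10(ms / ref^2), floor_db)
    v <- apply_edge_stride(v, w, bs$interior)
    if (is.null(out)) out <- array(0, c(dim(v), nt))
    out[, , t] <- v
  }
  new_param_map("IBS", out, "dB", A$meta, w)
}

#' Closed-form Rayleigh maximum-likelihood estimate
#'
#' `alpha_hat = sqrt( sum(x^2) / (2 n) )`.
#'
#' @param x Non-negative amplitude samples.
#' @return The MLE of the Rayleigh scale parameter.
#' @export
rayleigh_mle <- function(x) sqrt(sum(x^2) / (2 * length(x)))

#' Closed-form log-normal maximum-likelihood estimates
#'
#' `mu_hat = mean(log x)`, `sigma_hat = sqrt(mean((log x - mu_hat)^2))`
#' (the 1/N MLE variance), computed over strictly positive samples.
#'
#' @param x Positive amplitude samples (zeros are excluded by callers).
#' @return `list(mu, sigma)`.
#' @export
lognormal_mle <- function(x) {
  lx <- log(x)
  mu <- mean(lx)
  list(mu = mu, sigma = sqrt(mean((lx - mu)^2)))
}

#' Sliding-window Rayleigh scale parameter map
#'
#' The closed-form Rayleigh MLE over each estimation window, assigned to the
#' window's centre (anchor) pixel.  All-zero windows yield `NA` with a
#' warning.
#'
#' @inheritParams ibs_map
#' @return A `parametric_map_sequence` (param `"alpha"`, linear units).
#' @export
rayleigh_alpha_map <- function(A, w = window_spec()) {
  stopifnot(inherits(A, "envelope_sequence"), inherits(w, "window_spec"))
  nt <- dim(A$frames)[3]
  out <- NULL
  n_undef <- 0L
  for (t in seq_len(nt)) {
    bs <- box_sum(A$frames[, , t]^2, w$height_px, w$width_px)
    al <- sqrt(bs$sum / (2 * bs$n))
    bad <- bs$sum <= 0
    n_undef <- n_undef + sum(bad)
    al[bad] <- NA_real_
    al <- apply_edge_stride(al, w, bs$interior)
    if (is.null(out)) out <- array(0, c(dim(al), nt))
    out[, , t] <- al
  }
  if (n_undef > 0)
    warning(sprintf("%d all-zero windows: alpha undefined (NA)", n_undef))
  new_param_map("alpha", out, "linear", A$meta, w)
}

#' Sliding-window log-normal scale (sigma) parameter map
#'
#' The closed-form log-normal MLE of the log-scale sd over each estimation
#' window, zeros excluded; windows with fewer than 2 positive samples yield
#' `NA`.  The total number of excluded zero samples is attached as attribute
#' `n_zero_excluded`.
#'
#' @inheritParams ibs_map
#' @return A `parametric_map_sequence` (param `"sigma"`, dimensionless).
#' @export
lognormal_sigma_map <- function(A, w = window_spec()) {
  stopifnot(inherits(A, "envelope_sequence"), inherits(w, "window_spec"))
  nt <- dim(A$frames)[3]
  out <- NULL
  n_zero <- 0L
  n_undef <- 0L
  for (t in seq_len(nt)) {
    fr <- A$frames[, , t]
    pos <- fr > 0
    n_zero <- n_zero + sum(!pos)
    lx <- ifelse(pos, log(pmax(fr, .Machine$double.xmin)), 0)
    bn <- box_sum(pos + 0, w$height_px, w$width_px)
    b1 <- box_sum(lx, w$height_px, w$width_px)
    b2 <- box_sum(lx^2, w$height_px, w$width_px)
    N <- bn$sum
    mu <- b1$sum / N
    v <- b2$sum / N - mu^2
    sg <- sqrt(pmax(v, 0))
    bad <- N < 2
    n_undef <- n_undef + sum(bad)
    sg[bad] <- NA_real_
    sg <- apply_edge_stride(sg, w, bn$interior)
    if (is.null(out)) out <- array(0, c(dim(sg), nt))
    out[, , t] <- sg
  }
  if (n_undef > 0)
    warning(sprintf("%d windows with < 2 positive samples: sigma undefined (NA)",
                    n_undef))
  res <- new_param_map("sigma", out, "dimensionless", A$meta, w)
  attr(res, "n_zero_excluded") <- n_zero
  res
}

#' Goodness of fit of an amplitude model to windowed envelope samples
#'
#' Fits the model pdf at its MLE to the normalized histogram of the samples
#' (equal-width bins over `[0, max]`) and reports adjusted R-squared,
#' chi-squared on counts, and the degrees of freedom `bins - parameters - 1`.
#'
#' @param x Amplitude samples (>= 100).
#' @param model `"rayleigh"` or `"lognormal"`.
#' @param bins Number of histogram bins (default 45, giving dof in the 40s).
#' @return `list(model, r_squared, r_squared_adj, chi_squared, dof, params)`.
#' @export
goodness_of_fit <- function(x, model = c("rayleigh", "lognormal"), bins = 45) {
  model <- match.arg(model)
  bins <- as.integer(bins)
  x <- x[is.finite(x)]
  if (length(x) < 100) stop("need at least 100 samples")
  if (max(x) <= min(x)) stop("degenerate histogram: constant data")
  if (model == "lognormal") x <- x[x > 0]
  n <- length(x)
  brks <- seq(0, max(x), length.out = bins + 1)
  cnt <- tabulate(pmin(findInterval(x, brks, rightmost.closed = TRUE), bins),
                  nbins = bins)
  width <- diff(brks)[1]
  if (model == "rayleigh") {
    a <- rayleigh_mle(x)
    cdf <- function(q) 1 - exp(-q^2 / (2 * a^2))
    params <- list(alpha = a); npar <- 1L
  } else {
    m <- lognormal_mle(x)
    cdf <- function(q) stats::plnorm(q, meanlog = m$mu, sdlog = m$sigma)
    params <- m; npar <- 2L
  }
  p <- diff(cdf(brks))
  obs_d <- cnt / (n * width)
  exp_d <- p / width
  ss_res <- sum((obs_d - exp_d)^2)
  ss_tot <- sum((obs_d - mean(obs_d))^2)
  r2 <- 1 - ss_res / ss_tot
  r2_adj <- 1 - (1 - r2) * (bins - 1) / (bins - npar - 1)
  keep <- p > 1e-12
  chi2 <- sum((cnt[keep] - n * p[keep])^2 / (n * p[keep]))
  structure(list(model = model, r_squared = r2, r_squared_adj = r2_adj,
                 chi_squared = chi2, dof = bins - npar - 1L, params = params,
                 n = n, bins = bins),
            class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  cat(sprintf("<gof_report> %s fit, n = %d: adj R^2 = %.4f, chi^2 = %.1f (dof %d)\n",
              x$model, x$n, x$r_squared_adj, x$chi_squared, x$dof))
  invisible(x)
}
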