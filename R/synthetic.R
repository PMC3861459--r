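ellipse_mask <- function(shape, center, semiaxes) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((r - center[1]) / semiaxes[1])^2 + ((c - center[2]) / semiaxes[2])^2 <= 1
}

#' Speckle phantom configuration
#'
#' Defines a synthetic envelope sequence whose lesion region undergoes a
#' time-progressive shift in first-order scatterer statistics.  Defaults mirror
#' the imaging conditions of the study design: 11 frames/s M2D imaging starting
#' at t = 4 s with a 4 s ablation window at 4.5–8.5 s.  The lesion shift ramps
#' linearly from identity to `lesion_shift` across the ablation window and then
#' relaxes exponentially toward a retained fraction (`recovery_fraction`) of
#' the peak shift, modelling the reversible component of the echogenicity
#' change (transient gas bodies, heating) that motivates cumulative-extrema
#' imaging.
#'
#' @param shape Grid `(rows, cols)`.
#' @param frame_rate_hz Frames per second.
#' @param n_frames Number of frames.
#' @param time_origin_s Acquisition start on the experiment clock (s).
#' @param ablation_window_s `(start, stop)` of the ablation window (s).
#' @param distribution `"lognormal"` or `"rayleigh"` baseline amplitude model.
#' @param mu0,sigma0 Log-normal baseline parameters (log-scale mean/sd).
#' @param alpha0 Rayleigh baseline scale.
#' @param lesion_center Ellipse centre `(row, col)`; default grid centre.
#' @param lesion_semiaxes Ellipse semi-axes `(rows, cols)` in pixels.
#' @param lesion_shift Peak multiplicative shift of the distribution parameter
#'   (sigma for log-normal, alpha for Rayleigh) inside the lesion.
#' @param recovery_fraction Fraction of the peak shift retained as t -> Inf
#'   after ablation (1 = fully irreversible, 0 = fully reversible).
#' @param recovery_tau_s Exponential relaxation time constant (s).
#' @param noise_floor Additive non-negative amplitude offset.
#' @param pixel_spacing_um Pixel spacing `(axial, lateral)` in micrometres.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return Object of class `speckle_phantom_config`.
#' @export
speckle_phantom_config <- function(shape = c(64, 64),
                                   frame_rate_hz = 11,
                                   n_frames = 88,
                                   time_origin_s = 4,
                                   ablation_window_s = c(4.5, 8.5),
                                   distribution = c("lognormal", "rayleigh"),
                                   mu0 = 0, sigma0 = 0.3, alpha0 = 1,
                                   lesion_center = NULL,
                                   lesion_semiaxes = c(16, 10),
                                   lesion_shift = 1.8,
                                   recovery_fraction = 0.5,
                                   recovery_tau_s = 1.5,
                                   noise_floor = 0,
                                   pixel_spacing_um = c(98, 115),
                                   seed = 1L) {
  distribution <- match.arg(distribution)
  if (distribution == "lognormal" && sigma0 < 0) stop("sigma0 must be >= 0")
  if (distribution == "rayleigh" && alpha0 <= 0) stop("alpha0 must be > 0")
  if (is.null(lesion_center)) lesion_center <- (shape + 1) / 2
  if (lesion_center[1] - lesion_semiaxes[1] < 1 ||
      lesion_center[1] + lesion_semiaxes[1] > shape[1] ||
      lesion_center[2] - lesion_semiaxes[2] < 1 ||
      lesion_center[2] + lesion_semiaxes[2] > shape[2])
    stop("lesion ellipse must lie inside the grid")
  t_end <- time_origin_s + (n_frames - 1) / frame_rate_hz
  if (t_end < ablation_window_s[2])
    stop("sequence must span the ablation window")
  structure(list(shape = shape, frame_rate_hz = frame_rate_hz,
                 n_frames = n_frames, time_origin_s = time_origin_s,
                 ablation_window_s = ablation_window_s,
                 distribution = distribution, mu0 = mu0, sigma0 = sigma0,
                 alpha0 = alpha0, lesion_center = lesion_center,
                 lesion_semiaxes = lesion_semiaxes,
                 lesion_shift = lesion_shift,
                 recovery_fraction = recovery_fraction,
                 recovery_tau_s = recovery_tau_s,
                 noise_floor = noise_floor,
                 pixel_spacing_um = pixel_spacing_um,
                 seed = as.integer(seed)),
            class = "speckle_phantom_config")
}

#' Lesion shift multiplier over time
#'
#' Identity before ablation onset, linear ramp to `lesion_shift` across the
#' ablation window, then exponential relaxation toward
#' `1 + recovery_fraction * (lesion_shift - 1)`.
#'
#' @param cfg A [speckle_phantom_config()].
#' @param times Times (s) on the experiment clock.
#' @return Numeric multiplier per time point.
#' @export
lesion_shift_profile <- function(cfg, times) {
  aw <- cfg$ablation_window_s
  peak <- cfg$lesion_shift - 1
  frac <- pmin(pmax((times - aw[1]) / (aw[2] - aw[1]), 0), 1)
  f <- 1 + peak * frac
  post <- times > aw[2]
  if (any(post)) {
    retained <- cfg$recovery_fraction * peak
    decayed <- (peak - retained) * exp(-(times[post] - aw[2]) / cfg$recovery_tau_s)
    f[post] <- 1 + retained + decayed
  }
  f
}

#' Simulate a speckle envelope sequence with a forming lesion
#'
#' Per-pixel amplitudes are drawn i.i.d. from the configured first-order
#' distribution; inside the lesion ellipse the distribution parameter follows
#' [lesion_shift_profile()].  The returned mask is the generative ellipse.
#'
#' @param cfg A [speckle_phantom_config()].
#' @return `list(envelope = envelope_sequence, mask = lesion_mask)`.
#' @export
simulate_speckle_sequence <- function(cfg) {
  stopifnot(inherits(cfg, "speckle_phantom_config"))
  set.seed(cfg$seed)
  shape <- cfg$shape
  inside <- ellipse_mask(shape, cfg$lesion_center, cfg$lesion_semiaxes)
  times <- cfg$time_origin_s + (seq_len(cfg$n_frames) - 1) / cfg$frame_rate_hz
  shift <- lesion_shift_profile(cfg, times)
  npx <- prod(shape)
  fr <- array(0, c(shape, cfg$n_frames))
  for (t in seq_len(cfg$n_frames)) {
    if (cfg$distribution == "lognormal") {
      sig <- matrix(cfg$sigma0, shape[1], shape[2])
      sig[inside] <- cfg$sigma0 * shift[t]
      a <- matrix(stats::rlnorm(npx, meanlog = cfg$mu0, sdlog = as.vector(sig)),
                  shape[1], shape[2])
    } else {
      al <- matrix(cfg$alpha0, shape[1], shape[2])
      al[inside] <- cfg$alpha0 * shift[t]
      # Rayleigh(alpha) draw: alpha * sqrt(-2 log U)
      a <- matrix(as.vector(al) * sqrt(-2 * log(stats::runif(npx))),
                  shape[1], shape[2])
    }
    fr[, , t] <- a + cfg$noise_floor
  }
  meta <- acquisition_meta(cfg$frame_rate_hz, cfg$pixel_spacing_um,
                           time_origin_s = cfg$time_origin_s,
                           ablation_window_s = cfg$ablation_window_s)
  list(envelope = envelope_sequence(fr, meta),
       mask = lesion_mask(inside, "synthetic-truth"))
}

ap_template_params <- function(upstroke_ms, apd50_ms, apd80_ms) {
  if (!(apd50_ms > 0 && apd50_ms < apd80_ms))
    stop("need 0 < APD50 < APD80")
  tau <- (apd80_ms - apd50_ms) / log(0.5 / 0.2)
  t_plateau <- apd50_ms - tau * log(2)
  if (t_plateau <= upstroke_ms / 2)
    stop("APD50/APD80 too short for the configured upstroke")
  list(tau = tau, t_plateau = t_plateau, upstroke_ms = upstroke_ms)
}

#' Action-potential template
#'
#' Normalized (0..1) optical AP shape as a function of time relative to the
#' activation instant: a raised-cosine upstroke of duration `upstroke_ms`
#' centred on t = 0 (so the derivative maximum — the operational activation
#' marker — is unique and sits exactly at t = 0), a flat plateau, and an
#' exponential repolarization whose plateau end and rate are solved so the
#' 50% and 80% repolarization crossings land exactly at `apd50_ms` and
#' `apd80_ms`.
#'
#' @param t_ms Times relative to activation (ms); vector or array.
#' @param upstroke_ms Upstroke duration (ms).
#' @param apd50_ms,apd80_ms Target AP durations (ms), `0 < apd50 < apd80`.
#' @return Template values, same shape as `t_ms`.
#' @export
ap_template <- function(t_ms, upstroke_ms = 20, apd50_ms = 160, apd80_ms = 200) {
  p <- ap_template_params(upstroke_ms, apd50_ms, apd80_ms)
  u2 <- upstroke_ms / 2
  v <- ifelse(t_ms < -u2, 0,
       ifelse(t_ms <= u2, (1 + sin(pi * t_ms / upstroke_ms)) / 2,
       ifelse(t_ms <= p$t_plateau, 1,
              exp(-(t_ms - p$t_plateau) / p$tau))))
  v
}

#' AP movie configuration
#'
#' Defines a paced optical-mapping movie: a planar wave of templated APs,
#' a lesion region whose AP amplitude, durations, and upstroke rate are scaled
#' (linearly ramped over the ablation window), multiplicative photobleaching
#' drift, and additive sensor noise.  Defaults mirror the study design:
#' 1000 frames/s, pacing cycle 1000 ms, ~250 um/px, lesion APA reduced ~80%,
#' APD50/APD80 shortened ~33%/21%, upstroke slowed to ~58%.
#'
#' @param shape Grid `(rows, cols)`.
#' @param frame_rate_hz Frames per second.
#' @param pacing_cycle_ms Pacing cycle length (ms).
#' @param n_cycles Number of paced cycles; the movie spans
#'   `n_cycles * pacing_cycle_ms`.
#' @param upstroke_ms,apd50_ms,apd80_ms Template parameters (ms).
#' @param apa_df Fractional-fluorescence AP amplitude (ΔF/F units).
#' @param baseline_f Background fluorescence level.
#' @param cv_mm_per_ms Plane-wave conduction speed (mm/ms), > 0.
#' @param cv_angle_deg Propagation direction, degrees from +x (columns),
#'   y pointing down rows.
#' @param first_activation_ms Activation time at the grid origin within each
#'   cycle (ms after the cycle start).
#' @param pixel_spacing_um Pixel spacing `(axial, lateral)` um.
#' @param lesion_center,lesion_semiaxes Lesion ellipse; `NULL` centre = grid
#'   centre.
#' @param apa_scale Lesion APA multiplier in `[0, 1]` at full effect.
#' @param apd50_scale,apd80_scale Lesion APD multipliers at full effect.
#' @param upstroke_scale Lesion upstroke-rate multiplier at full effect
#'   (durations stretch by its inverse).
#' @param ablation_window_s Ablation window on the movie clock (s); lesion
#'   effects ramp linearly across it, cycle by cycle.
#' @param drift_linear_per_s Linear multiplicative drift slope (per s).
#' @param drift_exp_amplitude,drift_exp_tau_s Exponential drift component:
#'   `drift(t) = 1 + drift_linear_per_s * t + drift_exp_amplitude *
#'   (1 - exp(-t / drift_exp_tau_s))`.
#' @param noise_sd Additive Gaussian noise sd (fluorescence units).
#' @param seed Integer seed.
#' @return Object of class `ap_movie_config`.
#' @export
ap_movie_config <- function(shape = c(40, 40),
                            frame_rate_hz = 1000,
                            pacing_cycle_ms = 1000,
                            n_cycles = 12,
                            upstroke_ms = 20,
                            apd50_ms = 160, apd80_ms = 200,
                            apa_df = 0.05, baseline_f = 1,
                            cv_mm_per_ms = 0.5, cv_angle_deg = 0,
                            first_activation_ms = 50,
                            pixel_spacing_um = c(250, 250),
                            lesion_center = NULL,
                            lesion_semiaxes = c(10, 7),
                            apa_scale = 0.2,
                            apd50_scale = 0.67, apd80_scale = 0.79,
                            upstroke_scale = 0.58,
                            ablation_window_s = c(4.5, 8.5),
                            drift_linear_per_s = -0.002,
                            drift_exp_amplitude = -0.02,
                            drift_exp_tau_s = 8,
                            noise_sd = 0.005,
                            seed = 1L) {
  if (cv_mm_per_ms <= 0) stop("cv_mm_per_ms must be > 0")
  if (!(apd50_ms > 0 && apd50_ms < apd80_ms && apd80_ms < pacing_cycle_ms))
    stop("need 0 < APD50 < APD80 < pacing cycle")
  if (apa_scale < 0 || apa_scale > 1) stop("apa_scale must be in [0, 1]")
  if (max(apd50_ms, apd80_ms) >= pacing_cycle_ms)
    stop("APD must be shorter than the pacing cycle")
  if (is.null(lesion_center)) lesion_center <- (shape + 1) / 2
  ap_template_params(upstroke_ms, apd50_ms, apd80_ms)                # validate
  ap_template_params(upstroke_ms / upstroke_scale,
                     apd50_ms * apd50_scale, apd80_ms * apd80_scale) # validate
  structure(as.list(environment()), class = "ap_movie_config")
}

#' Per-cycle lesion effect ramp
#'
#' Linear ramp of the lesion effect over the ablation window, evaluated at the
#' start time of each pacing cycle: 0 before onset, 1 after the window.
#'
#' @param cfg An [ap_movie_config()].
#' @return Numeric vector, one ramp value in `[0, 1]` per cycle.
#' @export
lesion_effect_by_cycle <- function(cfg) {
  starts_s <- (seq_len(cfg$n_cycles) - 1) * cfg$pacing_cycle_ms / 1000
  aw <- cfg$ablation_window_s
  pmin(pmax((starts_s - aw[1]) / (aw[2] - aw[1]), 0), 1)
}

activation_offset_map <- function(cfg) {
  shape <- cfg$shape
  sx <- cfg$pixel_spacing_um[2] / 1000  # mm per column step
  sy <- cfg$pixel_spacing_um[1] / 1000  # mm per row step
  th <- cfg$cv_angle_deg * pi / 180
  r <- matrix(seq_len(shape[1]) - 1, shape[1], shape[2])
  c <- matrix(seq_len(shape[2]) - 1, shape[1], shape[2], byrow = TRUE)
  proj_mm <- c * sx * cos(th) + r * sy * sin(th)
  cfg$first_activation_ms + proj_mm / cfg$cv_mm_per_ms
}

#' Simulate a paced optical-mapping movie with a forming lesion
#'
#' Renders `F(x,y;t) = drift(t) * (baseline_f + APA(x,y,cycle) *
#' template(t - activation(x,y,cycle))) + noise`.  The plane-wave activation
#' map, per-cycle lesion effects, and all feature maps in the returned ground
#' truth are computed analytically from the configuration, never from the
#' rendered movie.
#'
#' @param cfg An [ap_movie_config()].
#' @return `list(movie = optical_movie, truth = list(...), mask = lesion_mask)`.
#'   Ground truth contains the per-cycle activation offsets (`activation_ms`,
#'   within-cycle), baseline and lesion template durations (`apd50_ms`,
#'   `apd80_ms` maps at full effect), per-cycle effect ramp
#'   (`effect_by_cycle`), final normalized APA and ΔAPA maps, normalized
#'   upstroke-rate ratio map, and the CV field (`cv_mm_per_ms`,
#'   `cv_angle_deg`).
#' @export
simulate_ap_movie <- function(cfg) {
  stopifnot(inherits(cfg, "ap_movie_config"))
  set.seed(cfg$seed)
  shape <- cfg$shape
  npx <- prod(shape)
  dt_ms <- 1000 / cfg$frame_rate_hz
  spc <- round(cfg$pacing_cycle_ms / dt_ms)  # samples per cycle
  nt <- spc * cfg$n_cycles
  inside <- ellipse_mask(shape, cfg$lesion_center, cfg$lesion_semiaxes)
  act <- activation_offset_map(cfg)          # ms within cycle
  eff <- lesion_effect_by_cycle(cfg)

  fr <- array(0, c(shape, nt))
  tcyc <- (seq_len(spc) - 1) * dt_ms         # ms within cycle
  act_v <- as.vector(act)
  ins_v <- as.vector(inside)
  for (k in seq_len(cfg$n_cycles)) {
    e <- eff[k]
    # relative times: pixels x samples
    rel <- outer(-act_v, tcyc, `+`)
    amp <- matrix(0, npx, spc)
    idx_out <- which(!ins_v)
    if (length(idx_out))
      amp[idx_out, ] <- ap_template(rel[idx_out, , drop = FALSE],
                                    cfg$upstroke_ms, cfg$apd50_ms, cfg$apd80_ms)
    idx_in <- which(ins_v)
    if (length(idx_in)) {
      # scales interpolate linearly with the ramp
      s_apa  <- 1 + e * (cfg$apa_scale  - 1)
      s_a50  <- 1 + e * (cfg$apd50_scale - 1)
      s_a80  <- 1 + e * (cfg$apd80_scale - 1)
      s_up   <- 1 + e * (cfg$upstroke_scale - 1)
      amp[idx_in, ] <- s_apa *
        ap_template(rel[idx_in, , drop = FALSE],
                    cfg$upstroke_ms / s_up,
                    cfg$apd50_ms * s_a50, cfg$apd80_ms * s_a80)
    }
    tt <- seq_len(spc) + (k - 1) * spc
    fr[, , tt] <- array(cfg$baseline_f + cfg$apa_df * amp, c(shape, spc))
  }
  times_s <- (seq_len(nt) - 1) * dt_ms / 1000
  drift <- 1 + cfg$drift_linear_per_s * times_s +
    cfg$drift_exp_amplitude * (1 - exp(-times_s / cfg$drift_exp_tau_s))
  fr <- sweep(fr, 3, drift, `*`)
  if (cfg$noise_sd > 0)
    fr <- fr + array(stats::rnorm(length(fr), sd = cfg$noise_sd), dim(fr))

  meta <- acquisition_meta(cfg$frame_rate_hz, cfg$pixel_spacing_um,
                           time_origin_s = 0,
                           ablation_window_s = cfg$ablation_window_s)
  e_fin <- eff[cfg$n_cycles]
  apa_fin <- matrix(1, shape[1], shape[2])
  apa_fin[inside] <- 1 + e_fin * (cfg$apa_scale - 1)
  apd50_t <- matrix(cfg$apd50_ms, shape[1], shape[2])
  apd50_t[inside] <- cfg$apd50_ms * (1 + e_fin * (cfg$apd50_scale - 1))
  apd80_t <- matrix(cfg$apd80_ms, shape[1], shape[2])
  apd80_t[inside] <- cfg$apd80_ms * (1 + e_fin * (cfg$apd80_scale - 1))
  up_t <- matrix(1, shape[1], shape[2])
  up_t[inside] <- 1 + e_fin * (cfg$upstroke_scale - 1)
  truth <- list(activation_ms = act,
                effect_by_cycle = eff,
                apa = apa_fin, delta_apa = apa_fin - 1,
                apd50_ms = apd50_t, apd80_ms = apd80_t,
                upstroke_ratio = up_t,
                cv_mm_per_ms = cfg$cv_mm_per_ms,
                cv_angle_deg = cfg$cv_angle_deg)
  list(movie = optical_movie(fr, meta, cfg$pacing_cycle_ms),
       truth = truth,
       mask = lesion_mask(inside, "synthetic-truth"))
}

#' Simulate an RGB histology image with a lesion
#'
#' Lesion pixels are drawn around `lesion_color`, background around
#' `background_color`, with Gaussian colour noise plus isolated single-pixel
#' class outliers that exercise the MRF smoothing of [segment_lesion()].
#'
#' @param shape Image `(rows, cols)`.
#' @param lesion_center,lesion_semiaxes Lesion ellipse (pixels); `NULL` centre
#'   = image centre.
#' @param lesion_color,background_color sRGB triples in `[0, 1]`; defaults are
#'   the pale coagulated-tissue pink vs. dark myocardial red of a trichrome
#'   slide.
#' @param noise_sd Gaussian colour noise sd per channel.
#' @param outlier_fraction Fraction of pixels swapped to the opposite class
#'   colour.
#' @param seed Integer seed.
#' @return `list(image = rows x cols x 3 array, mask = lesion_mask)`.
#' @export
simulate_histology_image <- function(shape = c(120, 160),
                                     lesion_center = NULL,
                                     lesion_semiaxes = c(28, 40),
                                     lesion_color = c(0.90, 0.74, 0.76),
                                     background_color = c(0.52, 0.13, 0.20),
                                     noise_sd = 0.03,
                                     outlier_fraction = 0.01,
                                     seed = 1L) {
  if (all(lesion_color == background_color) && noise_sd == 0)
    warning("identical class colors with zero noise: degenerate segmentation")
  if (is.null(lesion_center)) lesion_center <- (shape + 1) / 2
  set.seed(as.integer(seed))
  inside <- ellipse_mask(shape, lesion_center, lesion_semiaxes)
  img <- array(0, c(shape, 3))
  for (ch in 1:3) {
    base <- ifelse(inside, lesion_color[ch], background_color[ch])
    img[, , ch] <- base
  }
  if (outlier_fraction > 0) {
    n_out <- round(outlier_fraction * prod(shape))
    idx <- sample.int(prod(shape), n_out)
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[idx] <- ifelse(inside[idx], background_color[ch], lesion_color[ch])
      img[, , ch] <- pl
    }
  }
  if (noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), sd = noise_sd), dim(img))
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = lesion_mask(inside, "synthetic-truth"))
}

#' Simulate a per-subject ΔAPA pixel cohort
#'
#' Draws per-pixel ΔAPA values for lesion and non-lesion pixels from Gaussian
#' distributions.  Defaults are the pooled canine-wedge regime this pipeline
#' targets: inside-lesion ΔAPA −0.57 ± 0.16 over 2058 pixels, outside
#' −0.16 ± 0.15 over 4117 pixels, 13 subjects.
#'
#' @param n_subjects Number of subjects (wedges/phantoms).
#' @param n_inside,n_outside Pixels per subject inside/outside the lesion.
#' @param inside_mean,inside_sd,outside_mean,outside_sd ΔAPA moments.
#' @param seed Integer seed.
#' @return A data.frame with columns `delta_apa`, `label` (TRUE = lesion),
#'   `subject`.
#' @export
simulate_delta_apa_cohort <- function(n_subjects = 13,
                                      n_inside = 2058, n_outside = 4117,
                                      inside_mean = -0.57, inside_sd = 0.16,
                                      outside_mean = -0.16, outside_sd = 0.15,
                                      seed = 1L) {
  set.seed(as.integer(seed))
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    da <- c(stats::rnorm(n_inside, inside_mean, inside_sd),
            stats::rnorm(n_outside, outside_mean, outside_sd))
    out[[s]] <- data.frame(delta_apa = da,
                           label = rep(c(TRUE, FALSE), c(n_inside, n_outside)),
                           subject = s)
  }
  do.call(rbind, out)
}

#' Simulate a three-band ΔAPA map
#'
#' A ΔAPA map with a lesion core, a surrounding band of sub-lesion APA
#' reduction, and unchanged tissue outside, plus Gaussian noise.  Used to
#' exercise [band_classifier()] and threshold recovery.
#'
#' @param shape Grid `(rows, cols)`.
#' @param lesion_center Ellipse centre; `NULL` = grid centre.
#' @param core_semiaxes,band_semiaxes Inner (lesion) and outer (band) ellipse
#'   semi-axes in pixels; the band is the outer ellipse minus the core.
#' @param core_effect,band_effect,outside_effect Mean ΔAPA per region.
#' @param noise_sd Gaussian noise sd.
#' @param seed Integer seed.
#' @return `list(delta_apa = matrix, region = matrix of 2/1/0 codes
#'   (lesion/band/unchanged), mask = lesion_mask of the core)`.
#' @export
simulate_delta_apa_map <- function(shape = c(60, 60),
                                   lesion_center = NULL,
                                   core_semiaxes = c(12, 9),
                                   band_semiaxes = c(18, 14),
                                   core_effect = -0.6,
                                   band_effect = -0.31,
                                   outside_effect = 0,
                                   noise_sd = 0.05,
                                   seed = 1L) {
  if (is.null(lesion_center)) lesion_center <- (shape + 1) / 2
  set.seed(as.integer(seed))
  core <- ellipse_mask(shape, lesion_center, core_semiaxes)
  outer_e <- ellipse_mask(shape, lesion_center, band_semiaxes)
  band <- outer_e & !core
  da <- matrix(outside_effect, shape[1], shape[2])
  da[band] <- band_effect
  da[core] <- core_effect
  da <- da + matrix(stats::rnorm(prod(shape), sd = noise_sd), shape[1], shape[2])
  region <- matrix(0L, shape[1], shape[2])
  region[band] <- 1L
  region[core] <- 2L
  list(delta_apa = da, region = region,
       mask = lesion_mask(core, "synthetic-truth"))
}
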