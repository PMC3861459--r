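# Shared fixture builders; everything is generated in code at test time.

simple_meta <- function(frame_rate_hz = 11, ablation = c(4.5, 8.5),
                        t0 = 4, spacing = c(100, 100)) {
  acquisition_meta(frame_rate_hz, spacing, time_origin_s = t0,
                   ablation_window_s = ablation)
}

# constant-amplitude envelope stack
const_envelope <- function(value = 1, shape = c(8, 8), n_frames = 4,
                           meta = simple_meta()) {
  envelope_sequence(array(value, c(shape, n_frames)), meta)
}

# small speckle phantom used across detection tests
small_speckle <- function(seed, lesion_shift = 1.8, shape = c(48, 48),
                          n_frames = 70, semiaxes = c(12, 8)) {
  simulate_speckle_sequence(speckle_phantom_config(
    shape = shape, n_frames = n_frames, lesion_semiaxes = semiaxes,
    lesion_shift = lesion_shift, seed = seed))
}

# small paced movie: 500 ms cycles so four cycles span an ablation ramp
small_movie_config <- function(..., seed = 1) {
  args <- list(shape = c(24, 24), pacing_cycle_ms = 500, n_cycles = 4,
               apd50_ms = 160, apd80_ms = 200,
               ablation_window_s = c(0.5, 1.5),
               noise_sd = 0, drift_linear_per_s = 0,
               drift_exp_amplitude = 0, seed = seed)
  do.call(ap_movie_config, utils::modifyList(args, list(...)))
}

erode_mask <- function(mask, radius = 2) {
  m <- if (inherits(mask, "lesion_mask")) mask$mask else mask
  EBImage::erode(m + 0, EBImage::makeBrush(2 * radius + 1, "disc")) > 0
}

# exhaustive pair-counting AUC oracle: P(s_pos > s_neg) + 0.5 P(tie)
auc_pair_count <- function(score, label) {
  sp <- score[as.logical(label)]
  sn <- score[!as.logical(label)]
  cmp <- outer(sp, sn, `-`)
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(sp) * length(sn))
}
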