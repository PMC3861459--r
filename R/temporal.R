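map_frames <- function(X) {
  if (inherits(X, c("parametric_map_sequence", "frame_stack"))) X$frames
  else if (is.array(X) && length(dim(X)) == 3) X
  else stop("X must be a parametric_map_sequence, frame stack, or 3D array")
}

map_meta <- function(X) {
  if (inherits(X, c("parametric_map_sequence", "frame_stack"))) X$meta else NULL
}

#' Baseline frame specification
#'
#' Which frames form the pre-ablation baseline.  The default (`frames = NULL`)
#' resolves, per sequence, to all frames acquired before the ablation onset in
#' the sequence metadata — the signal average of the pre-HIFU frames.
#'
#' @param frames Integer frame indices (1-based), or `NULL` for the default.
#' @return Object of class `baseline_spec`.
#' @export
baseline_spec <- function(frames = NULL) {
  if (!is.null(frames)) {
    frames <- as.integer(frames)
    if (length(frames) == 0) stop("baseline must be non-empty")
    if (any(frames < 1)) stop("baseline indices must be >= 1")
  }
  structure(list(frames = frames), class = "baseline_spec")
}

resolve_baseline <- function(X, b) {
  fr <- map_frames(X)
  nt <- dim(fr)[3]
  idx <- if (!is.null(b$frames)) b$frames else {
    meta <- map_meta(X)
    if (is.null(meta)) stop("no metadata: give explicit baseline frames")
    baseline_frame_idx(meta, nt)
  }
  if (length(idx) == 0) stop("empty baseline: no frames precede ablation onset")
  if (max(idx) > nt) stop("baseline index beyond sequence length")
  idx
}

#' Transient (frame-to-frame) change map
#'
#' `|dX|_t(.; t) = |X(.; t) - X(.; t-1)|` for `t >= 2`; the first frame is
#' undefined and returned as `NA`.
#'
#' @param X A `parametric_map_sequence` or 3D array.
#' @param signed Return signed differences instead of absolute values.
#' @return 3D array of the same shape (first frame `NA`), with attribute
#'   `kind = "transient"`.
#' @export
transient_change <- function(X, signed = FALSE) {
  fr <- map_frames(X)
  nt <- dim(fr)[3]
  if (nt < 2) stop("need at least 2 frames")
  out <- array(NA_real_, dim(fr))
  d <- fr[, , 2:nt, drop = FALSE] - fr[, , 1:(nt - 1), drop = FALSE]
  out[, , 2:nt] <- if (signed) d else abs(d)
  attr(out, "kind") <- "transient"
  out
}

#' Cumulative change map vs. the pre-ablation baseline
#'
#' `dX_c(.; t) = X(.; t) - mean over baseline frames`, returned both signed
#' and absolute.
#'
#' @param X A `parametric_map_sequence` or 3D array.
#' @param b A [baseline_spec()].
#' @return `list(signed = 3D array, abs = 3D array, baseline_frames = idx)`.
#' @export
cumulative_change <- function(X, b = baseline_spec()) {
  fr <- map_frames(X)
  idx <- resolve_baseline(X, b)
  base <- apply(fr[, , idx, drop = FALSE], c(1, 2), mean)
  d <- sweep(fr, c(1, 2), base, `-`)
  attr(d, "kind") <- "cumulative"
  list(signed = d, abs = abs(d), baseline_frames = idx)
}

#' Cumulative extrema map
#'
#' Per-pixel running maximum of the absolute cumulative change,
#' `raw(.; t) = max over t' <= t of |dX_c(.; t')|`, normalized to `[0, 1]` by
#' one global scale factor (the maximum over all pixels and frames), so a
#' single dimensionless threshold applies to the whole sequence and per-pixel
#' monotonicity is preserved.  The raw map and scale are kept for
#' cross-sequence threshold transfer.
#'
#' @inheritParams cumulative_change
#' @param normalize Normalize by the global maximum (skipped with a warning
#'   when the raw map is all zero).
#' @return `list(normalized, raw, scale, baseline_frames)`; `normalized` is
#'   `NULL` when `normalize = FALSE`.
#' @export
cumulative_extrema <- function(X, b = baseline_spec(), normalize = TRUE) {
  cc <- cumulative_change(X, b)
  a <- cc$abs
  nt <- dim(a)[3]
  raw <- a
  for (t in 2:nt) raw[, , t] <- pmax(raw[, , t], raw[, , t - 1])
  attr(raw, "kind") <- "cumulative_extrema"
  scale <- max(raw, na.rm = TRUE)
  normalized <- NULL
  if (normalize) {
    if (scale <= 0) {
      warning("all-zero cumulative extrema: normalization skipped")
      normalized <- raw
      scale <- 1
    } else normalized <- raw / scale
  }
  list(normalized = normalized, raw = raw, scale = scale,
       baseline_frames = cc$baseline_frames)
}

#' All three temporal-evolution maps of a parameter sequence
#'
#' Convenience wrapper returning the transient, cumulative (signed and
#' absolute), and cumulative-extrema maps of one parametric sequence.
#'
#' @inheritParams cumulative_change
#' @return Object of class `temporal_maps`.
#' @export
temporal_maps <- function(X, b = baseline_spec()) {
  structure(list(transient = transient_change(X),
                 cumulative = cumulative_change(X, b),
                 extrema = cumulative_extrema(X, b),
                 param = if (inherits(X, "parametric_map_sequence")) X$param else NA),
            class = "temporal_maps")
}

#' @export
print.temporal_maps <- function(x, ...) {
  d <- dim(x$transient)
  cat(sprintf("<temporal_maps> param %s, %d x %d px, %d frames (baseline: %s)\n",
              x$param, d[1], d[2], d[3],
              paste(range(x$cumulative$baseline_frames), collapse = "..")))
  invisible(x)
}
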