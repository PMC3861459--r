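#' Acquisition metadata
#'
#' Shared metadata for frame stacks: frame rate, pixel spacing, optional RF
#' sample rate, the acquisition start on the shared experiment clock, and the
#' ablation (HIFU-on) window on that clock.
#'
#' @param frame_rate_hz Frames per second, > 0.
#' @param pixel_spacing_um Length-2 numeric, (axial, lateral) pixel spacing in
#'   micrometres; both > 0.
#' @param rf_sample_rate_hz RF sampling rate in Hz, or `NULL` when the stack is
#'   envelope/fluorescence data.
#' @param time_origin_s Time of the first frame on the experiment clock (s).
#' @param ablation_window_s Length-2 numeric `(start, stop)` of the ablation
#'   window in seconds, or `c(NA, NA)` when no ablation was applied.
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(frame_rate_hz,
                             pixel_spacing_um,
                             rf_sample_rate_hz = NULL,
                             time_origin_s = 0,
                             ablation_window_s = c(NA_real_, NA_real_)) {
  if (!is.numeric(frame_rate_hz) || length(frame_rate_hz) != 1 || frame_rate_hz <= 0)
    stop("frame_rate_hz must be a single positive number")
  if (length(pixel_spacing_um) != 2 || any(pixel_spacing_um <= 0))
    stop("pixel_spacing_um must be two positive numbers (axial, lateral)")
  aw <- as.numeric(ablation_window_s)
  if (length(aw) != 2) stop("ablation_window_s must have length 2")
  if (all(!is.na(aw)) && aw[1] >= aw[2])
    stop("ablation window start must precede stop")
  structure(list(frame_rate_hz = as.numeric(frame_rate_hz),
                 pixel_spacing_um = as.numeric(pixel_spacing_um),
                 rf_sample_rate_hz = if (is.null(rf_sample_rate_hz)) NULL
                                     else as.numeric(rf_sample_rate_hz),
                 time_origin_s = as.numeric(time_origin_s),
                 ablation_window_s = aw),
            class = "acquisition_meta")
}

check_frames3d <- function(frames) {
  if (!is.array(frames) || length(dim(frames)) != 3)
    stop("frames must be a 3D array (row = axial/depth, col = lateral, t)")
  if (any(!is.finite(frames))) stop("frames must be finite")
  invisible(frames)
}

#' Ultrasound envelope sequence
#'
#' A time-ordered stack of non-negative envelope amplitude frames
#' `A(x, y; t)` with acquisition metadata.  Row index is axial (depth), column
#' index is lateral, both 0-based at pixel centres in the on-disk convention.
#'
#' @param frames 3D numeric array `(rows, cols, t)`, all values >= 0.
#' @param meta An [acquisition_meta()].
#' @return Object of class `envelope_sequence`.
#' @export
envelope_sequence <- function(frames, meta) {
  check_frames3d(frames)
  if (any(frames < 0)) stop("envelope amplitudes must be non-negative")
  if (!inherits(meta, "acquisition_meta")) stop("meta must be an acquisition_meta")
  structure(list(frames = frames, meta = meta),
            class = c("envelope_sequence", "frame_stack"))
}

#' Optical-mapping fluorescence movie
#'
#' @param frames 3D numeric array `(rows, cols, t)` of fluorescence samples.
#' @param meta An [acquisition_meta()]; frame rate is of order 1000 Hz.
#' @param pacing_cycle_ms Pacing cycle length in milliseconds, > 0.
#' @return Object of class `optical_movie`.
#' @export
optical_movie <- function(frames, meta, pacing_cycle_ms) {
  check_frames3d(frames)
  if (!inherits(meta, "acquisition_meta")) stop("meta must be an acquisition_meta")
  if (!is.numeric(pacing_cycle_ms) || pacing_cycle_ms <= 0)
    stop("pacing_cycle_ms must be > 0")
  structure(list(frames = frames, meta = meta,
                 pacing_cycle_ms = as.numeric(pacing_cycle_ms)),
            class = c("optical_movie", "frame_stack"))
}

#' Binary lesion mask
#'
#' @param mask Logical (or 0/1) matrix; `TRUE` = lesion.
#' @param provenance One of `"gross"`, `"MT"`, `"TTC"`, `"predicted"`,
#'   `"synthetic-truth"`.
#' @return Object of class `lesion_mask`.
#' @export
lesion_mask <- function(mask,
                        provenance = c("synthetic-truth", "gross", "MT", "TTC",
                                       "predicted")) {
  provenance <- match.arg(provenance)
  if (!is.matrix(mask)) stop("mask must be a matrix")
  m <- mask
  storage.mode(m) <- "logical"
  if (any(is.na(m))) stop("mask must not contain NA")
  structure(list(mask = m, provenance = provenance), class = "lesion_mask")
}

#' Frame times on the experiment clock
#'
#' @param x A `frame_stack` (envelope sequence or optical movie).
#' @return Numeric vector of frame times in seconds.
#' @export
frame_times <- function(x) {
  nt <- dim(x$frames)[3]
  x$meta$time_origin_s + (seq_len(nt) - 1) / x$meta$frame_rate_hz
}

#' @export
print.envelope_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<envelope_sequence> %d x %d px, %d frames @ %.3g fps, t = %.3g..%.3g s\n",
              d[1], d[2], d[3], x$meta$frame_rate_hz,
              min(frame_times(x)), max(frame_times(x))))
  invisible(x)
}

#' @export
print.optical_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<optical_movie> %d x %d px, %d frames @ %.4g fps, pacing CL %g ms\n",
              d[1], d[2], d[3], x$meta$frame_rate_hz, x$pacing_cycle_ms))
  invisible(x)
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %d x %d px, %d lesion px (%.1f%%), provenance: %s\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask), x$provenance))
  invisible(x)
}

meta_to_list <- function(meta) {
  list(frame_rate_hz = meta$frame_rate_hz,
       pixel_spacing_um = meta$pixel_spacing_um,
       rf_sample_rate_hz = meta$rf_sample_rate_hz,
       time_origin_s = meta$time_origin_s,
       ablation_window_s = meta$ablation_window_s)
}

meta_from_list <- function(l) {
  aw <- unlist(l$ablation_window_s)
  if (is.null(aw)) aw <- c(NA_real_, NA_real_)
  acquisition_meta(frame_rate_hz = l$frame_rate_hz,
                   pixel_spacing_um = unlist(l$pixel_spacing_um),
                   rf_sample_rate_hz = l$rf_sample_rate_hz,
                   time_origin_s = if (is.null(l$time_origin_s)) 0 else l$time_origin_s,
                   ablation_window_s = aw)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a frame stack to a multi-page TIFF with JSON sidecar
#'
#' Frames are stored as 32-bit float TIFF pages, linearly rescaled to `[0, 1]`
#' (the TIFF writer clips outside that range); the affine scale is recorded in
#' the sidecar, so the round trip is lossless to 32-bit float precision of the
#' data range.  Metadata (and pacing for movies) live in `<path>.json`.
#'
#' @param x An [envelope_sequence()] or [optical_movie()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path) {
  if (!inherits(x, "frame_stack")) stop("x must be an envelope_sequence or optical_movie")
  fr <- x$frames
  lo <- min(fr); hi <- max(fr)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(fr)[3]), function(t) (fr[, , t] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  side <- list(kind = if (inherits(x, "optical_movie")) "optical" else "envelope",
               offset = lo, scale = scale,
               meta = meta_to_list(x$meta))
  if (inherits(x, "optical_movie")) side$pacing_cycle_ms <- x$pacing_cycle_ms
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a frame stack or RGB image from disk
#'
#' Stacks are multi-page TIFFs with a `<path>.json` sidecar written by
#' [write_stack()]; `kind = "rgb"` reads a PNG/TIFF RGB image (histology or
#' gross photograph) and returns an `rows x cols x 3` array in `[0, 1]`.
#'
#' @param path File path.
#' @param kind `"envelope"`, `"optical"`, or `"rgb"`.
#' @return [envelope_sequence()], [optical_movie()], or an RGB array.
#' @export
read_stack <- function(path, kind = c("envelope", "optical", "rgb")) {
  kind <- match.arg(kind)
  if (kind == "rgb") {
    img <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
           else tiff::readTIFF(path)
    if (length(dim(img)) != 3 || dim(img)[3] < 3)
      stop("rgb image must have 3 channels")
    return(img[, , 1:3, drop = FALSE])
  }
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("missing JSON sidecar: ", sp)
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must have the same shape")
  fr <- array(0, c(dims[1, 1], dims[2, 1], length(pages)))
  for (t in seq_along(pages)) fr[, , t] <- pages[[t]]
  fr <- fr * side$scale + side$offset
  meta <- meta_from_list(side$meta)
  if (kind == "envelope") {
    fr[fr < 0 & fr > -1e-6 * side$scale] <- 0  # float32 jitter at the zero bound
    if (any(fr < 0)) stop("negative envelope values in stack")
    envelope_sequence(fr, meta)
  } else {
    if (is.null(side$pacing_cycle_ms)) stop("sidecar lacks pacing_cycle_ms")
    optical_movie(fr, meta, side$pacing_cycle_ms)
  }
}

#' Write a binary mask as a 0/255 PNG
#' @param mask A [lesion_mask()] or logical matrix.
#' @param path Output PNG path.
#' @export
write_mask <- function(mask, path) {
  m <- if (inherits(mask, "lesion_mask")) mask$mask else mask
  png::writePNG(ifelse(m, 1, 0), path)
  invisible(path)
}

#' Read a 0/255 PNG mask
#' @param path PNG path.
#' @param provenance Passed to [lesion_mask()].
#' @export
read_mask <- function(path, provenance = "predicted") {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  lesion_mask(img > 0.5, provenance = provenance)
}

#' Write per-pixel or per-frame feature records to CSV
#'
#' Deterministic column order (as given), one row per record, header always
#' written (an empty record set yields a header-only file).
#'
#' @param records A data.frame.
#' @param path Output path.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records)) stop("records must be a data.frame")
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_table()]
#' @param path CSV path.
#' @export
read_table_csv <- function(path) utils::read.csv(path)

analytic_envelope <- function(m) {
  # column-wise analytic-signal magnitude via FFT (each column is one A-line)
  n <- nrow(m)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  X <- stats::mvfft(m)
  Mod(stats::mvfft(X * h, inverse = TRUE)) / n
}

#' Envelope detection of RF frames
#'
#' Computes the magnitude of the analytic signal (Hilbert transform) of each
#' A-line.  Each frame is `(depth sample, scan line)`; the analytic signal is
#' taken along the depth (row) direction over the full line, without tapering.
#'
#' @param rf_frames 3D array `(depth, line, t)` of real RF samples, or a
#'   matrix for a single frame.
#' @param sample_rate RF sample rate in Hz.
#' @param meta Optional [acquisition_meta()] to attach; when `NULL` a minimal
#'   one is built (frame rate 1 Hz, unit spacing).
#' @return An [envelope_sequence()] of the same shape.
#' @export
envelope_from_rf <- function(rf_frames, sample_rate, meta = NULL) {
  if (is.matrix(rf_frames)) rf_frames <- array(rf_frames, c(dim(rf_frames), 1))
  check_frames3d(rf_frames)
  if (dim(rf_frames)[1] < 4) stop("each A-line needs at least 4 samples")
  env <- rf_frames
  for (t in seq_len(dim(rf_frames)[3]))
    env[, , t] <- analytic_envelope(matrix(rf_frames[, , t],
                                           dim(rf_frames)[1]))
  if (is.null(meta))
    meta <- acquisition_meta(frame_rate_hz = 1, pixel_spacing_um = c(1, 1),
                             rf_sample_rate_hz = sample_rate)
  envelope_sequence(env, meta)
}
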