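#' Preprocessing configuration
#'
#' Parameters of the signal-conditioning chain applied before connectivity
#' analysis: DC-offset removal, 60 Hz line-noise notch, 0.2–250 Hz band-pass
#' (24 dB/octave), topographic-PCA artifact projection, and a
#' nearest-neighbour surface Laplacian.
#'
#' @param notch_hz Line-noise frequency (Hz).
#' @param notch_q Notch quality factor; stop-band width is `notch_hz / notch_q`.
#' @param band_hz Band-pass edges (Hz). An upper edge at or above Nyquist is
#'   degenerate and the filter reduces to a high-pass at the lower edge.
#' @param slope_db_oct Roll-off steepness; must be a positive multiple of
#'   6 dB/octave (order = slope / 6).
#' @param artifact_cor_threshold Minimum |correlation| between a spatial
#'   principal component and the artifact topography for projection.
#' @param artifact_max_components Cap on projected-out components.
#' @param laplacian_k Nearest-neighbour count of the surface Laplacian.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(notch_hz = 60, notch_q = 30,
                              band_hz = c(0.2, 250), slope_db_oct = 24,
                              artifact_cor_threshold = 0.9,
                              artifact_max_components = 3L,
                              laplacian_k = 4L) {
  if (band_hz[1L] <= 0 || band_hz[1L] >= band_hz[2L])
    stopf("band edges must satisfy 0 < low < high")
  if (slope_db_oct <= 0 || slope_db_oct %% 6 != 0)
    stopf("slope must be a positive multiple of 6 dB/octave")
  structure(list(notch_hz = notch_hz, notch_q = notch_q, band_hz = band_hz,
                 slope_db_oct = slope_db_oct,
                 artifact_cor_threshold = artifact_cor_threshold,
                 artifact_max_components = as.integer(artifact_max_components),
                 laplacian_k = as.integer(laplacian_k)),
            class = "preprocess_config")
}

#' Remove per-channel DC offset
#'
#' Subtracts each channel's mean, emulating the running DC-offset
#' compensation of the acquisition frontend. Idempotent.
#'
#' @param rec An [recording()].
#' @return A recording with zero-mean channels.
#' @export
remove_dc <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  rec$data <- rec$data - rowMeans(rec$data)
  rec
}

#' Line-noise notch filter
#'
#' Second-order Butterworth band-stop centred on `notch_hz` with width
#' `notch_hz / notch_q`, applied forward–backward (zero phase).
#'
#' @param rec An [recording()].
#' @param config A [preprocess_config()].
#' @return Filtered recording.
#' @export
notch_filter <- function(rec, config = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  f0 <- config$notch_hz
  if (f0 >= rec$fs / 2) stopf("notch frequency must be below Nyquist (%g Hz)",
                              rec$fs / 2)
  bw <- f0 / config$notch_q
  edges <- c(f0 - bw / 2, f0 + bw / 2) / (rec$fs / 2)
  filt <- signal::butter(2, edges, type = "stop")
  rec$data <- filter_rows(filt, rec$data)
  rec
}

#' Band-pass filter
#'
#' Butterworth band-pass at `config$band_hz` with order `slope / 6` per edge,
#' applied forward–backward. When the upper edge reaches Nyquist (the default
#' 0.2–250 Hz at fs = 500) the band-pass degenerates to a high-pass at the
#' lower edge.
#'
#' @inheritParams notch_filter
#' @return Filtered recording.
#' @export
bandpass_filter <- function(rec, config = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  lo <- config$band_hz[1L]; hi <- config$band_hz[2L]
  if (lo <= 0) stopf("low band edge must be > 0")
  ord <- as.integer(config$slope_db_oct / 6)
  nyq <- rec$fs / 2
  filt <- if (hi >= nyq) {
    signal::butter(ord, lo / nyq, type = "high")
  } else {
    signal::butter(ord, c(lo, hi) / nyq, type = "pass")
  }
  rec$data <- filter_rows(filt, rec$data)
  rec
}

#' Topographic-PCA artifact projection
#'
#' Spatial principal components are fitted on user-marked artifact intervals;
#' the first component defines the artifact topography. Components whose
#' channel-space correlation with that topography exceeds
#' `artifact_cor_threshold` (the leading component always qualifies) are
#' projected out of the entire recording, up to `artifact_max_components`.
#' With no marked intervals the recording is returned unchanged.
#'
#' @param rec An [recording()].
#' @param artifact_intervals data.frame with `start_s`, `end_s` columns
#'   (seconds), or NULL.
#' @param config A [preprocess_config()].
#' @return List with `recording` (cleaned) and `n_removed` (components
#'   projected out; signal rank drops by this number).
#' @export
spatial_pca_artifact_removal <- function(rec, artifact_intervals = NULL,
                                         config = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(artifact_intervals) || nrow(artifact_intervals) == 0L)
    return(list(recording = rec, n_removed = 0L))
  dur <- ncol(rec$data) / rec$fs
  if (any(artifact_intervals$start_s < 0) ||
      any(artifact_intervals$end_s > dur + 1e-9))
    stopf("artifact interval outside recording")
  cols <- unlist(lapply(seq_len(nrow(artifact_intervals)), function(k) {
    i0 <- floor(artifact_intervals$start_s[k] * rec$fs) + 1L
    i1 <- floor(artifact_intervals$end_s[k] * rec$fs)
    i0:i1
  }))
  A <- rec$data[, cols, drop = FALSE]
  A <- A - rowMeans(A)
  # artifact topography: channel pattern at the moment of peak amplitude
  # inside the marked intervals ("highest amplitude" criterion)
  peak <- which.max(apply(abs(A), 2L, max))
  topo <- A[, peak]
  pca <- svd(A, nu = min(nrow(A), ncol(A)), nv = 0L)
  cors <- abs(apply(pca$u, 2L, stats::cor, y = topo))
  keep_out <- which(cors >= config$artifact_cor_threshold)
  keep_out <- keep_out[seq_len(min(length(keep_out),
                                   config$artifact_max_components))]
  V <- pca$u[, keep_out, drop = FALSE]
  rec$data <- rec$data - V %*% crossprod(V, rec$data)
  list(recording = rec, n_removed = length(keep_out))
}

#' Surface Laplacian re-referencing
#'
#' Nearest-neighbour ("small") Laplacian: every channel is replaced by its
#' value minus the mean of its `k` nearest neighbours in montage space. This
#' sharpens topography and removes common-mode activity (a signal identical
#' on all channels maps to zero).
#'
#' @param rec An [recording()] whose channels all appear in `mont`.
#' @param mont An `eeg_montage` supplying 3-D positions.
#' @param config A [preprocess_config()] (uses `laplacian_k`).
#' @return Re-referenced recording.
#' @export
surface_laplacian <- function(rec, mont, config = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(mont, "eeg_montage"))
  k <- config$laplacian_k
  n <- nrow(rec$data)
  if (k >= n) stopf("laplacian_k (%d) must be below channel count (%d)", k, n)
  idx <- match(rec$labels, mont$channels$name)
  if (anyNA(idx)) stopf("montage positions missing for: %s",
                        paste(rec$labels[is.na(idx)], collapse = ", "))
  pos <- as.matrix(mont$channels[idx, c("x", "y", "z")])
  D <- as.matrix(stats::dist(pos))
  out <- rec$data
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2:(k + 1L)]  # skip self
    out[i, ] <- rec$data[i, ] - colMeans(rec$data[nb, , drop = FALSE])
  }
  rec$data <- out
  rec
}

#' Full preprocessing chain
#'
#' DC removal, notch, band-pass, optional topographic-PCA artifact
#' projection, surface Laplacian — in that order. Deterministic;
#' channel count and labels are preserved.
#'
#' @inheritParams spatial_pca_artifact_removal
#' @param mont Montage for the Laplacian step; skip the step with NULL.
#' @return Preprocessed recording.
#' @export
preprocess_recording <- function(rec, mont = NULL, artifact_intervals = NULL,
                                 config = preprocess_config()) {
  rec <- remove_dc(rec)
  rec <- notch_filter(rec, config)
  rec <- bandpass_filter(rec, config)
  rec <- spatial_pca_artifact_removal(rec, artifact_intervals, config)$recording
  if (!is.null(mont)) rec <- surface_laplacian(rec, mont, config)
  rec
}
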