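#' Connectivity estimation configuration
#'
#' Functional connectivity is the magnitude-squared coherence between channel
#' pairs, estimated per 1-second window by Welch's method: the window is cut
#' into Hann-tapered sub-segments with 50% overlap, cross-spectra are averaged
#' over sub-segments, and coherence is averaged over the aggregation band.
#' With a single sub-segment coherence is identically 1, so the sub-segment
#' must be shorter than the window.
#'
#' @param window_s Layer (window) length in seconds.
#' @param subseg Sub-segment length in samples for spectral estimation;
#'   `NULL` (default) uses 40% of the window length, which gives exactly four
#'   half-overlapped sub-segments per window (200 samples at 500 Hz).
#' @param overlap Fractional sub-segment overlap in \[0, 1).
#' @param band_hz Length-2 aggregation band (Hz); coherence is the arithmetic
#'   mean over frequency bins inside it.
#' @return A `connectivity_config` list.
#' @export
connectivity_config <- function(window_s = 1, subseg = NULL, overlap = 0.5,
                                band_hz = c(1, 50)) {
  if (overlap < 0 || overlap >= 1) stopf("overlap must lie in [0, 1)")
  structure(list(window_s = window_s,
                 subseg = if (!is.null(subseg)) as.integer(subseg),
                 overlap = overlap, band_hz = band_hz),
            class = "connectivity_config")
}

#' Cut a gesture epoch into consecutive 1-second windows
#'
#' Non-overlapping windows of `config$window_s` seconds in time order; a
#' trailing remainder shorter than one window is discarded. An epoch must
#' yield at least two windows (two network layers).
#'
#' @param epoch A `gesture_epoch`.
#' @param config A [connectivity_config()].
#' @return List of channels x samples matrices.
#' @export
window_epoch <- function(epoch, config = connectivity_config()) {
  stopifnot(inherits(epoch, "gesture_epoch"))
  wlen <- round(config$window_s * epoch$fs)
  n_win <- ncol(epoch$data) %/% wlen
  if (n_win < 2L)
    stopf("epoch too short: %d full window(s), need >= 2", n_win)
  lapply(seq_len(n_win), function(r)
    epoch$data[, ((r - 1L) * wlen + 1L):(r * wlen), drop = FALSE])
}

# Welch cross-spectral density tensor for a channels x samples block.
# Returns freqs and S (N x N x nfreq complex), using Hann-tapered
# sub-segments with the configured overlap.
welch_cross_spectra <- function(X, fs, subseg, overlap) {
  n <- ncol(X)
  if (subseg > n) stopf("sub-segment longer than window")
  step <- max(1L, round(subseg * (1 - overlap)))
  starts <- seq(1L, n - subseg + 1L, by = step)
  if (length(starts) < 2L)
    stopf("window has fewer than 2 sub-segments for spectral estimation")
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0L, subseg - 1L) / (subseg - 1L))
  nch <- nrow(X)
  nfreq <- subseg %/% 2L + 1L
  S <- array(0 + 0i, dim = c(nch, nch, nfreq))
  for (s0 in starts) {
    seg <- X[, s0:(s0 + subseg - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)            # detrend (constant) per sub-segment
    seg <- seg * matrix(win, nch, subseg, byrow = TRUE)
    F <- t(stats::mvfft(t(seg)))[, seq_len(nfreq), drop = FALSE]
    for (f in seq_len(nfreq))
      S[, , f] <- S[, , f] + tcrossprod(F[, f], Conj(F[, f]))
  }
  S <- S / length(starts)
  list(freqs = (seq_len(nfreq) - 1L) * fs / subseg, S = S)
}

#' Coherence adjacency matrix of one window
#'
#' Magnitude-squared coherence `C_ij(f) = |S_ij(f)|^2 / (S_ii(f) S_jj(f))`
#' from Welch-averaged cross-spectra, averaged over the aggregation band.
#' Symmetric, entries in \[0, 1\], diagonal forced to 1. Zero-variance
#' channels have undefined coherence; their rows/columns are set to 0 with a
#' warning.
#'
#' @param window Channels x samples matrix (one 1-s window).
#' @param fs Sampling rate (Hz).
#' @param config A [connectivity_config()].
#' @return N x N weighted adjacency matrix.
#' @export
coherence_matrix <- function(window, fs, config = connectivity_config()) {
  subseg <- config$subseg %||% max(8L, round(0.4 * ncol(window)))
  cs <- welch_cross_spectra(window, fs, subseg, config$overlap)
  in_band <- which(cs$freqs >= config$band_hz[1L] &
                     cs$freqs <= config$band_hz[2L])
  if (!length(in_band)) stopf("aggregation band contains no frequency bins")
  nch <- nrow(window)
  C <- matrix(0, nch, nch)
  for (f in in_band) {
    Sf <- cs$S[, , f]
    p <- Re(diag(Sf))
    denom <- tcrossprod(p)
    Cf <- Mod(Sf)^2 / denom
    Cf[denom <= 0] <- NA_real_
    C <- C + Cf
  }
  C <- C / length(in_band)
  dead <- which(apply(is.na(C), 1L, any) | apply(window, 1L, stats::sd) == 0)
  if (length(dead)) {
    warning(sprintf("zero-variance channel(s): %s; coherence set to 0",
                    paste(rownames(window)[dead] %||% dead, collapse = ", ")))
    C[dead, ] <- 0; C[, dead] <- 0
  }
  C <- (C + t(C)) / 2
  C[C > 1] <- 1; C[C < 0] <- 0
  diag(C) <- 1
  dimnames(C) <- list(rownames(window), rownames(window))
  C
}

#' Build the per-epoch adjacency tensor
#'
#' Applies [coherence_matrix()] to every 1-s window of the epoch and stacks
#' the resulting N x N layers in time order: layer `r` is window `r`.
#'
#' @param epoch A `gesture_epoch`.
#' @param config A [connectivity_config()].
#' @return An `adjacency_tensor`: N x N x T array with attributes `labels`,
#'   `window_s`, `label`, `hand`.
#' @export
build_tensor <- function(epoch, config = connectivity_config()) {
  windows <- window_epoch(epoch, config)
  layers <- lapply(windows, coherence_matrix, fs = epoch$fs, config = config)
  tens <- array(unlist(layers),
                dim = c(nrow(epoch$data), nrow(epoch$data), length(layers)))
  adjacency_tensor(tens, labels = epoch$labels, window_s = config$window_s,
                   label = epoch$label, hand = epoch$hand)
}

#' @param values N x N x T array of weights in \[0, 1\], each layer symmetric
#'   with unit diagonal.
#' @param labels Channel labels.
#' @param window_s Layer duration (s).
#' @param label,hand Epoch provenance.
#' @rdname build_tensor
#' @export
adjacency_tensor <- function(values, labels = NULL, window_s = 1,
                             label = NA_character_, hand = NA_character_) {
  stopifnot(length(dim(values)) == 3L, dim(values)[1L] == dim(values)[2L])
  if (dim(values)[3L] < 2L) stopf("adjacency tensor needs T >= 2 layers")
  structure(values, labels = labels, window_s = window_s,
            epoch_label = label, epoch_hand = hand,
            class = "adjacency_tensor")
}
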