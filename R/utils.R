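# Internal helpers shared across modules.

# Derive a 32-bit sub-seed from a master seed and a counter, so that every
# epoch / fold / repetition consumes an independent, reproducible stream.
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(counter) * 104729) %% 2147483647L)
}

# Zero-phase filtering: odd-symmetric reflection padding at both ends, one
# forward and one backward pass with zero initial state. The symmetric
# construction keeps symmetric inputs exactly symmetric, and the padding
# absorbs edge transients (signal::filtfilt pads only one end with zeros,
# which breaks both properties for narrow high-pass filters).
filtfilt_padded <- function(filt, x) {
  n <- length(x)
  npad <- min(n - 1L, 1000L)
  xp <- if (npad >= 1L) {
    c(2 * x[1L] - x[seq(npad + 1L, 2L)], x,
      2 * x[n] - x[seq(n - 1L, n - npad)])
  } else x
  fwd <- function(z) as.numeric(signal::filter(filt, z))
  y1 <- rev(fwd(rev(fwd(xp))))            # forward then backward
  y2 <- fwd(rev(fwd(rev(xp))))            # backward then forward
  y <- (y1 + y2) / 2                      # exactly time-reversal symmetric
  y[seq(npad + 1L, npad + n)]
}

# Apply a filter channel-wise to a channels x samples matrix.
filter_rows <- function(filt, data) {
  out <- t(apply(data, 1L, function(ch) filtfilt_padded(filt, ch)))
  dimnames(out) <- dimnames(data)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
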