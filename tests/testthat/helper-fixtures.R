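# Shared fixtures, all generated in code.

fixture_recording <- function(n_ch = 4, n_samp = 1000, fs = 500, seed = 42) {
  withr::with_seed(seed,
    recording(matrix(stats::rnorm(n_ch * n_samp), n_ch, n_samp), fs = fs))
}

fixture_epoch <- function(n_ch = 4, dur_s = 3, fs = 500, seed = 42,
                          label = "Suturing", hand = "dominant") {
  rec <- fixture_recording(n_ch, round(dur_s * fs), fs, seed)
  structure(list(label = label, hand = hand, data = rec$data, fs = fs,
                 labels = rec$labels, subject = "s1", session = "a"),
            class = "gesture_epoch")
}

# 12-channel montage matching generator channel names ch1..ch12.
fixture_montage <- function(n = 12) synthetic_montage(n)

# Tiny 5-channel montage with hand-placed positions for Laplacian checks.
toy_montage5 <- function() {
  montage(data.frame(
    name = paste0("ch", 1:5),
    x = c(0, 1, -1, 0, 0), y = c(0, 0, 0, 1, -1), z = c(0, 0, 0, 0, 0),
    cortex = c("motor", "motor", "cognition", "cognition", "perception"),
    hemisphere = c("left", "right", "left", "right", "left"),
    stringsAsFactors = FALSE))
}

# Minimal single-record EDF writer for read_recording("edf") round trips.
write_test_edf <- function(path, data, fs, labels) {
  ns <- nrow(data); nsamp <- ncol(data)
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeBin(charToRaw(pad(s, w)), con)
  wr("0", 8); wr("test patient", 80); wr("test recording", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 + ns * 256, 8); wr("", 44); wr(1, 8); wr(format(nsamp / fs), 8)
  wr(ns, 4)
  for (l in labels) wr(l, 16)
  for (i in 1:ns) wr("", 80)
  for (i in 1:ns) wr("uV", 8)
  pmin_ <- floor(apply(data, 1, min)); pmax_ <- ceiling(apply(data, 1, max))
  pmax_ <- pmax(pmax_, pmin_ + 1)
  for (i in 1:ns) wr(pmin_[i], 8)
  for (i in 1:ns) wr(pmax_[i], 8)
  for (i in 1:ns) wr(-32768, 8)
  for (i in 1:ns) wr(32767, 8)
  for (i in 1:ns) wr("", 80)
  for (i in 1:ns) wr(nsamp, 8)
  for (i in 1:ns) wr("", 32)
  for (i in 1:ns) {
    dig <- round((data[i, ] - pmin_[i]) / (pmax_[i] - pmin_[i]) *
                   (32767 + 32768) - 32768)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
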