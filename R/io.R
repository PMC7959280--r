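#' Gesture label vocabularies
#'
#' The nine surgical gesture classes annotated in robot-assisted radical
#' prostatectomy recordings, and the subsets performed by the dominant
#' (8 classes) and non-dominant (6 classes) hand. These vocabularies define
#' the classifier output spaces; annotation labels outside them are rejected.
#'
#' @return Character vector of gesture labels.
#' @export
gesture_vocabulary <- function() {
  c("Bipolar Cautery", "Monopolar Cautery", "Blunt Dissection",
    "Tissue Grasping", "Retraction", "Suturing", "Needle Insertion",
    "Surgical Thread Grasping", "Idle")
}

#' @param hand `"dominant"` or `"non-dominant"`.
#' @rdname gesture_vocabulary
#' @export
hand_vocabulary <- function(hand = c("dominant", "non-dominant")) {
  hand <- match.arg(hand)
  if (hand == "dominant") {
    c("Bipolar Cautery", "Monopolar Cautery", "Blunt Dissection",
      "Retraction", "Suturing", "Needle Insertion",
      "Surgical Thread Grasping", "Idle")
  } else {
    c("Tissue Grasping", "Retraction", "Suturing", "Needle Insertion",
      "Surgical Thread Grasping", "Idle")
  }
}

#' Construct a multichannel EEG recording
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param labels Channel names; defaults to rownames of `data`.
#' @return An object of class `eeg_recording` with fields `data`, `fs`,
#'   `labels`.
#' @export
recording <- function(data, fs, labels = rownames(data)) {
  data <- as.matrix(data)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  labels <- as.character(labels)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stopf("sampling rate must be a single positive number")
  if (length(labels) != nrow(data))
    stopf("number of labels (%d) must equal number of channels (%d)",
          length(labels), nrow(data))
  if (anyDuplicated(labels))
    stopf("duplicate labels: %s",
          paste(unique(labels[duplicated(labels)]), collapse = ", "))
  rownames(data) <- labels
  structure(list(data = data, fs = as.numeric(fs), labels = labels),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Read an EEG recording from disk
#'
#' Supports EDF (via a minimal reader of the 16-bit EDF specification) and a
#' plain matrix-text format: a header row of channel labels followed by one
#' column per channel (samples as rows), with the sampling rate in a `.fs`
#' sidecar file or supplied explicitly.
#'
#' @param path File path.
#' @param format `"matrix-text"` or `"edf"`. Default guesses from extension.
#' @param fs Sampling rate in Hz, required for matrix-text when no sidecar
#'   `<path>.fs` file exists.
#' @return An [recording()] object. No resampling is performed.
#' @export
read_recording <- function(path, format = c("auto", "matrix-text", "edf"),
                           fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "matrix-text"
  }
  if (format == "edf") return(read_edf(path))
  sidecar <- paste0(path, ".fs")
  if (is.null(fs)) {
    if (!file.exists(sidecar)) stopf("missing fs: supply `fs` or sidecar %s", sidecar)
    fs <- as.numeric(readLines(sidecar, n = 1L))
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  recording(t(as.matrix(tab)), fs = fs, labels = colnames(tab))
}

#' Write an EEG recording as matrix-text
#'
#' Tab-separated text, one column per channel with a label header, plus a
#' `<path>.fs` sidecar holding the sampling rate. Round-trips exactly through
#' [read_recording()].
#'
#' @param rec An [recording()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  tab <- as.data.frame(t(rec$data), check.names = FALSE)
  colnames(tab) <- rec$labels
  utils::write.table(format(tab, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(format(rec$fs, digits = 17), paste0(path, ".fs"))
  invisible(path)
}

# Minimal EDF reader: header + 16-bit samples, physical scaling per channel.
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  hdr(8); hdr(80); hdr(80); hdr(8); hdr(8)  # version, patient, recording, date, time
  n_header <- as.integer(hdr(8)); hdr(44)
  n_records <- as.integer(hdr(8))
  rec_dur <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  labels <- vapply(seq_len(ns), function(i) hdr(16), "")
  for (i in seq_len(ns)) hdr(80)  # transducer
  for (i in seq_len(ns)) hdr(8)   # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(hdr(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(hdr(8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(hdr(8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(hdr(8)), 0)
  for (i in seq_len(ns)) hdr(80)  # prefiltering
  nsamp <- vapply(seq_len(ns), function(i) as.integer(hdr(8)), 0L)
  for (i in seq_len(ns)) hdr(32)  # reserved
  if (length(unique(nsamp)) != 1L)
    stopf("EDF channels with differing samples per record are not supported")
  if (rec_dur <= 0) stopf("missing fs: EDF record duration is not positive")
  fs <- nsamp[1L] / rec_dur
  data <- matrix(0, nrow = ns, ncol = nsamp[1L] * n_records)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = nsamp[i], size = 2L,
                     signed = TRUE, endian = "little")
      idx <- ((r - 1L) * nsamp[i] + 1L):(r * nsamp[i])
      data[i, idx] <- phys_min[i] + (raw - dig_min[i]) * scale[i]
    }
  }
  recording(data, fs = fs, labels = labels)
}

#' Read a gesture annotation table
#'
#' CSV with header columns `label`, `hand`, `start_s`, `end_s`. Labels must
#' belong to the nine-gesture vocabulary, hands to
#' \{dominant, non-dominant\}, and every interval must satisfy start < end.
#'
#' @param path CSV path.
#' @return A `data.frame` with validated columns.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_annotations(tab)
}

#' @param tab A data.frame with columns label, hand, start_s, end_s.
#' @rdname read_annotations
#' @export
validate_annotations <- function(tab) {
  need <- c("label", "hand", "start_s", "end_s")
  if (!all(need %in% names(tab)))
    stopf("annotations need columns: %s", paste(need, collapse = ", "))
  tab$label <- as.character(tab$label)
  tab$hand <- as.character(tab$hand)
  tab$start_s <- as.numeric(tab$start_s)
  tab$end_s <- as.numeric(tab$end_s)
  bad <- setdiff(unique(tab$label), gesture_vocabulary())
  if (length(bad))
    stopf("unknown gesture label(s): %s", paste(bad, collapse = ", "))
  badh <- setdiff(unique(tab$hand), c("dominant", "non-dominant"))
  if (length(badh))
    stopf("unknown hand(s): %s", paste(badh, collapse = ", "))
  if (nrow(tab) && any(tab$start_s >= tab$end_s))
    stopf("annotation with start >= end at row(s) %s",
          paste(which(tab$start_s >= tab$end_s), collapse = ", "))
  tab[need]
}

#' @param annotations Annotation data.frame.
#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(validate_annotations(annotations), path, row.names = FALSE)
  invisible(path)
}

#' Extract gesture epochs from a recording
#'
#' Slices the recording at each annotated interval. Intervals are half-open
#' `[start, end)` in seconds; the sample range is `floor(start * fs) + 1` to
#' `floor(end * fs)`. Annotations shorter than `min_duration_s` (default 2 s,
#' the minimum for two 1-s network layers) are skipped with a message.
#'
#' @param rec An [recording()].
#' @param annotations Annotation data.frame (see [read_annotations()]).
#' @param min_duration_s Minimum epoch duration in seconds.
#' @param subject,session Provenance identifiers stored on each epoch.
#' @return List of `gesture_epoch` objects (label, hand, data, fs, labels,
#'   subject, session).
#' @export
extract_epochs <- function(rec, annotations, min_duration_s = 2,
                           subject = NA_character_, session = NA_character_) {
  stopifnot(inherits(rec, "eeg_recording"))
  annotations <- validate_annotations(annotations)
  dur_s <- ncol(rec$data) / rec$fs
  if (nrow(annotations) && any(annotations$end_s > dur_s + 1e-9))
    stopf("annotation exceeds recording length (%.3f s)", dur_s)
  epochs <- list()
  n_skipped <- 0L
  for (k in seq_len(nrow(annotations))) {
    row <- annotations[k, ]
    if (row$end_s - row$start_s < min_duration_s) {
      n_skipped <- n_skipped + 1L
      next
    }
    i0 <- floor(row$start_s * rec$fs) + 1L
    i1 <- floor(row$end_s * rec$fs)
    epochs[[length(epochs) + 1L]] <- structure(
      list(label = row$label, hand = row$hand,
           data = rec$data[, i0:i1, drop = FALSE],
           fs = rec$fs, labels = rec$labels,
           subject = subject, session = session),
      class = "gesture_epoch")
  }
  if (n_skipped)
    message(sprintf("extract_epochs: skipped %d annotation(s) shorter than %g s",
                    n_skipped, min_duration_s))
  epochs
}

#' @export
print.gesture_epoch <- function(x, ...) {
  cat(sprintf("<gesture_epoch> %s (%s hand), %d ch x %.2f s @ %g Hz\n",
              x$label, x$hand, nrow(x$data), ncol(x$data) / x$fs, x$fs))
  invisible(x)
}

#' Write a feature table to CSV
#'
#' One row per gesture epoch: 60 named feature columns plus `label`, `hand`
#' and `subject`. Round-trips through [read_feature_table()].
#'
#' @param features Feature data.frame from [extract_feature_table()].
#' @param path Output CSV path.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
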