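#' EEG montage with cortical-system mapping
#'
#' A montage records, for every electrode of a 128-channel cap: its name, a
#' 3-D position (arbitrary units, used only for Laplacian neighbourhoods and
#' artifact topographies), the functional cortex it is assigned to
#' (`motor`, `cognition`, `perception`, or `other`), and its hemisphere
#' (`left`, `right`, `midline`); plus the lists of excluded and reference
#' channels that are dropped before analysis.
#'
#' The default montage has 119 analysis channels partitioned into motor (70),
#' cognition (37) and perception (12) systems, with 2 mastoid references and
#' 7 excluded occipito-central electrodes (I1, Iz, I2, CPz, PO5, PO6, Oz).
#' Published electrode coordinates for the cap are not available, so positions
#' are generated on a unit sphere (upper hemisphere, Fibonacci lattice); the
#' cortex-system counts, not the exact geometry, drive every computation.
#'
#' @param n_motor,n_cognition,n_perception Channel counts per functional
#'   cortex, split left/right/midline internally.
#' @return Object of class `eeg_montage`: list with `channels` (data.frame:
#'   name, x, y, z, cortex, hemisphere), `excluded`, `reference`.
#' @export
default_montage <- function(n_motor = 70L, n_cognition = 37L,
                            n_perception = 12L) {
  split3 <- function(n) {
    # left/right as equal as possible, remainder (<= ~10%) on the midline
    side <- n %/% 2L - max(1L, n %/% 12L) %/% 2L
    mid <- n - 2L * side
    c(left = side, right = side, midline = mid)
  }
  specs <- list(motor = split3(n_motor), cognition = split3(n_cognition),
                perception = split3(n_perception))
  rows <- list()
  for (cx in names(specs)) {
    counts <- specs[[cx]]
    prefix <- toupper(substr(cx, 1L, 2L))
    k <- 0L
    for (hemi in names(counts)) {
      n <- counts[[hemi]]
      if (n == 0L) next
      idx <- seq_len(n)
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("%s%02d%s", prefix, k + idx,
                       c(left = "L", right = "R", midline = "Z")[hemi]),
        cortex = cx, hemisphere = hemi, stringsAsFactors = FALSE)
      k <- k + n
    }
  }
  channels <- do.call(rbind, rows)
  excluded <- c("I1", "Iz", "I2", "CPz", "PO5", "PO6", "Oz")
  extra <- data.frame(name = excluded, cortex = "other",
                      hemisphere = "midline", stringsAsFactors = FALSE)
  channels <- rbind(channels, extra)
  pos <- sphere_positions(nrow(channels))
  # deterministic hemisphere-consistent positions: mirror x for left/right
  pos[channels$hemisphere == "left", 1L] <- -abs(pos[channels$hemisphere == "left", 1L])
  pos[channels$hemisphere == "right", 1L] <- abs(pos[channels$hemisphere == "right", 1L])
  pos[channels$hemisphere == "midline", 1L] <- 0
  channels$x <- pos[, 1L]; channels$y <- pos[, 2L]; channels$z <- pos[, 3L]
  montage(channels[c("name", "x", "y", "z", "cortex", "hemisphere")],
          excluded = excluded, reference = c("M1", "M2"))
}

# Fibonacci lattice on the upper unit hemisphere: deterministic, roughly
# uniform electrode-like layout.
sphere_positions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- (1 + sqrt(5)) / 2
  z <- i / n                     # upper hemisphere only
  r <- sqrt(pmax(0, 1 - z^2))
  theta <- 2 * pi * i / phi
  cbind(r * cos(theta), r * sin(theta), z)
}

#' @param channels data.frame with columns name, x, y, z, cortex, hemisphere.
#' @param excluded,reference Character vectors of channel names dropped from
#'   analysis.
#' @rdname default_montage
#' @export
montage <- function(channels, excluded = character(), reference = character()) {
  need <- c("name", "x", "y", "z", "cortex", "hemisphere")
  if (!all(need %in% names(channels)))
    stopf("montage channels need columns: %s", paste(need, collapse = ", "))
  channels <- as.data.frame(channels)[need]
  channels$name <- as.character(channels$name)
  if (anyDuplicated(channels$name))
    stopf("duplicate channel names in montage")
  bad_cx <- setdiff(unique(channels$cortex),
                    c("motor", "cognition", "perception", "other"))
  if (length(bad_cx)) stopf("unknown cortex: %s", paste(bad_cx, collapse = ", "))
  bad_h <- setdiff(unique(channels$hemisphere), c("left", "right", "midline"))
  if (length(bad_h)) stopf("unknown hemisphere: %s", paste(bad_h, collapse = ", "))
  analysis <- setdiff(channels$name[channels$cortex != "other"],
                      c(excluded, reference))
  if (any(excluded %in% analysis))
    stopf("analysis channel present in excluded list")
  structure(list(channels = channels, excluded = as.character(excluded),
                 reference = as.character(reference)),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  sizes <- table(x$channels$cortex[analysis_mask(x)])
  cat(sprintf("<eeg_montage> %d analysis channels (%s); %d excluded, %d reference\n",
              sum(analysis_mask(x)),
              paste(names(sizes), sizes, sep = "=", collapse = ", "),
              length(x$excluded), length(x$reference)))
  invisible(x)
}

analysis_mask <- function(mont) {
  with(mont, channels$cortex != "other" &
         !(channels$name %in% c(excluded, reference)))
}

#' Analysis channels of a montage
#'
#' @param mont An `eeg_montage`.
#' @return Character vector of channel names mapped to a functional cortex and
#'   not excluded.
#' @export
analysis_channels <- function(mont) {
  mont$channels$name[analysis_mask(mont)]
}

#' Load / save a montage as JSON
#'
#' The JSON layout mirrors the montage structure: a `channels` array of
#' records (name, x, y, z, cortex, hemisphere) plus `excluded` and
#' `reference` name lists. A channel may appear once only; mapping a channel
#' to two cortices or listing an analysis channel as excluded is an error.
#'
#' @param path JSON file path.
#' @return An `eeg_montage`.
#' @export
load_montage <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  ch <- as.data.frame(obj$channels)
  montage(ch, excluded = obj$excluded %||% character(),
          reference = obj$reference %||% character())
}

#' @param mont An `eeg_montage`.
#' @rdname load_montage
#' @export
write_montage <- function(mont, path) {
  stopifnot(inherits(mont, "eeg_montage"))
  jsonlite::write_json(
    list(channels = mont$channels, excluded = mont$excluded,
         reference = mont$reference),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Cortex x hemisphere scope masks for feature aggregation
#'
#' Each per-scope network feature is an average over the channels of one
#' functional cortex restricted to one hemisphere scope: `left`, `right`, or
#' `whole` (the full cortex including midline electrodes). This yields the
#' nine scopes \{motor, cognition, perception\} x \{left, right, whole\}.
#'
#' @param mont An `eeg_montage`.
#' @param labels Channel-label order of the analysis data; masks are indices
#'   into this vector. Defaults to [analysis_channels()].
#' @return Named list of scope entries, each with `cortex`, `scope`,
#'   `members` (integer channel indices) and `cortex_members` (indices of the
#'   whole cortex regardless of hemisphere).
#' @export
scope_masks <- function(mont, labels = analysis_channels(mont)) {
  ch <- mont$channels[analysis_mask(mont), ]
  idx <- match(labels, ch$name)
  if (anyNA(idx)) stopf("labels not present in montage: %s",
                        paste(labels[is.na(idx)], collapse = ", "))
  ch <- ch[idx, ]
  out <- list()
  for (cx in c("motor", "cognition", "perception")) {
    cortex_members <- which(ch$cortex == cx)
    for (sc in c("left", "right", "whole")) {
      members <- if (sc == "whole") cortex_members
                 else which(ch$cortex == cx & ch$hemisphere == sc)
      if (!length(members))
        stopf("empty scope %s.%s in montage", cx, sc)
      out[[paste(cx, sc, sep = ".")]] <-
        list(cortex = cx, scope = sc, members = members,
             cortex_members = cortex_members)
    }
  }
  out
}
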