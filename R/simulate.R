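#' Simulation configuration for synthetic surgical-EEG datasets
#'
#' The study's operating-room recordings are not public, so downstream stages
#' are validated on synthetic multichannel signals with *planted*,
#' class-conditional structure. Each gesture class plants (i) coherence:
#' channels in the same coupling group share a band-limited latent oscillator
#' mixed in with weight `coupling`, and (ii) spectral power: the class's
#' channels are scaled by `power_gain`. Epoch durations vary per class and
#' class counts may be imbalanced, mirroring real gesture annotation tables.
#'
#' @param classes List of class specs; each a list with fields `label`
#'   (gesture name), `hand`, `groups` (list of integer channel-index vectors;
#'   groups must be disjoint), `band` (length-2 Hz vector of the latent
#'   oscillator), `coupling` (in \[0, 1\]), `power_gain` (multiplicative,
#'   default 1), `n` (epoch count, >= 1), `duration_s` (length-2 min/max).
#' @param n_channels Number of channels generated.
#' @param fs Sampling rate in Hz (default 500).
#' @param noise_sd Standard deviation of the per-channel white noise floor.
#' @param gap_s Idle (unannotated, uncoupled) gap inserted between epochs.
#' @param seed Master seed; all randomness derives from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(classes, n_channels = 119L, fs = 500,
                              noise_sd = 1, gap_s = 0.5, seed = 1L) {
  stopifnot(length(classes) >= 1L)
  for (cl in classes) {
    if (is.null(cl$label) || is.null(cl$n))
      stopf("each class needs at least `label` and `n`")
    if (cl$n < 1L) stopf("class counts must be >= 1")
    cpl <- cl$coupling %||% 0
    if (cpl < 0 || cpl > 1) stopf("coupling strength must lie in [0, 1]")
    dur <- cl$duration_s %||% c(2, 4)
    if (dur[1L] < 2) stopf("minimum epoch duration is 2 s (two network layers)")
    groups <- cl$groups %||% list()
    if (length(groups) > 1L) {
      all_idx <- unlist(groups)
      if (anyDuplicated(all_idx))
        stopf("overlapping coupling groups in class %s", cl$label)
    }
    if (length(groups) && max(unlist(groups)) > n_channels)
      stopf("group channel index exceeds n_channels")
  }
  structure(list(classes = classes, n_channels = as.integer(n_channels),
                 fs = fs, noise_sd = noise_sd, gap_s = gap_s,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Band-limited Gaussian noise: white noise band-pass filtered (4th order
# Butterworth), unit variance. Band-limited rather than sinusoidal so that
# coherence is high in-band but < 1, as in real EEG rhythms.
band_noise <- function(n, band, fs) {
  x <- stats::rnorm(n + 200L)
  filt <- signal::butter(4, pmin(band / (fs / 2), 0.999), type = "pass")
  y <- signal::filter(filt, x)[-seq_len(200L)]
  s <- stats::sd(y)
  if (s == 0) y else y / s
}

#' Generate a labelled synthetic EEG dataset
#'
#' Lays the configured gesture epochs end-to-end, separated by uncoupled
#' noise gaps, and returns the continuous recording together with its
#' annotation table. Within an epoch of class `c`, channel `i` in coupling
#' group `g` is `coupling * latent_g + sqrt(1 - coupling^2) * noise_i`, with
#' `latent_g` a band-limited oscillator shared by the group, all scaled by
#' `noise_sd * power_gain`; ungrouped channels are pure noise. Deterministic
#' given `config$seed` (each epoch uses a counter-derived substream).
#'
#' @param config A [simulation_config()].
#' @return List with `recording` ([recording()]) and `annotations`
#'   (data.frame: label, hand, start_s, end_s).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  fs <- config$fs
  n_ch <- config$n_channels
  labels <- paste0("ch", seq_len(n_ch))

  # interleave classes so folds see all classes throughout the recording
  schedule <- do.call(rbind, lapply(seq_along(config$classes), function(ci) {
    cl <- config$classes[[ci]]
    data.frame(class_idx = ci, rep = seq_len(cl$n))
  }))
  schedule <- schedule[order(schedule$rep, schedule$class_idx), ]

  segments <- list()
  ann <- list()
  t_cursor <- 0
  gap_samples <- round(config$gap_s * fs)
  counter <- 0L
  for (k in seq_len(nrow(schedule))) {
    cl <- config$classes[[schedule$class_idx[k]]]
    counter <- counter + 1L
    sim <- withr::with_seed(derive_seed(config$seed, counter), {
      dur <- cl$duration_s %||% c(2, 4)
      dur_s <- stats::runif(1, dur[1L], dur[2L])
      n <- round(dur_s * fs)
      X <- matrix(stats::rnorm(n_ch * n), n_ch, n)
      cpl <- cl$coupling %||% 0
      band <- cl$band %||% c(8, 12)
      for (g in cl$groups %||% list()) {
        latent <- band_noise(n, band, fs)
        X[g, ] <- cpl * matrix(latent, length(g), n, byrow = TRUE) +
          sqrt(1 - cpl^2) * X[g, , drop = FALSE]
      }
      X <- X * config$noise_sd * (cl$power_gain %||% 1)
      gap <- if (gap_samples > 0L) {
        matrix(stats::rnorm(n_ch * gap_samples), n_ch, gap_samples) *
          config$noise_sd
      }
      list(X = X, gap = gap, n = n)
    })
    if (!is.null(sim$gap)) {
      segments[[length(segments) + 1L]] <- sim$gap
      t_cursor <- t_cursor + gap_samples / fs
    }
    segments[[length(segments) + 1L]] <- sim$X
    ann[[length(ann) + 1L]] <- data.frame(
      label = cl$label, hand = cl$hand %||% "dominant",
      start_s = t_cursor, end_s = t_cursor + sim$n / fs,
      stringsAsFactors = FALSE)
    t_cursor <- t_cursor + sim$n / fs
  }
  rec <- recording(do.call(cbind, segments), fs = fs, labels = labels)
  list(recording = rec, annotations = do.call(rbind, ann))
}

#' Ground-truth partition for a simulated class
#'
#' Returns the planted community structure of one class as an N x T partition
#' matrix: channels in the same coupling group share a label, every ungrouped
#' channel is a singleton, and the assignment is constant across layers (so
#' planted flexibility is 0 for every node).
#'
#' @param config A [simulation_config()].
#' @param class_label Label of the class.
#' @param n_layers Number of 1-s layers T (columns).
#' @return Integer N x T matrix of community labels.
#' @export
planted_partition <- function(config, class_label, n_layers = 2L) {
  stopifnot(inherits(config, "simulation_config"))
  hit <- Filter(function(cl) cl$label == class_label, config$classes)
  if (!length(hit)) stopf("no class with label %s", class_label)
  cl <- hit[[1L]]
  lab <- integer(config$n_channels)
  g_id <- 0L
  for (g in cl$groups %||% list()) {
    g_id <- g_id + 1L
    lab[g] <- g_id
  }
  free <- which(lab == 0L)
  lab[free] <- g_id + seq_along(free)
  partition_matrix(matrix(lab, config$n_channels, n_layers))
}

#' Simple strong-effect multi-class configuration
#'
#' Convenience builder used by examples and end-to-end validation: `k`
#' gesture classes over `n_channels` channels, each class coupling a
#' different pair of channel blocks in a different frequency band and with a
#' distinct power gain. With `coupling = 0` and unit gains all classes are
#' statistically identical (null configuration).
#'
#' @param k Number of classes (2..8); labels taken from the dominant-hand
#'   gesture vocabulary.
#' @param n_channels Channels (>= 8).
#' @param n_per_class Epoch count per class; scalar or length-k (imbalanced).
#' @param coupling Shared-oscillator mixing weight in \[0,1\].
#' @param power_spread Multiplicative spacing of per-class power gains
#'   (1 = no power effect).
#' @param hand Hand annotation for all classes.
#' @param duration_s Length-2 min/max epoch duration (s).
#' @param seed Master seed.
#' @inheritParams simulation_config
#' @export
demo_config <- function(k = 6L, n_channels = 12L, n_per_class = 20L,
                        coupling = 0.9, power_spread = 1.15,
                        hand = "dominant", duration_s = c(2, 4),
                        fs = 500, seed = 1L) {
  stopifnot(k >= 2L, k <= 8L, n_channels >= 8L)
  labels <- hand_vocabulary(hand)[seq_len(k)]
  n_per_class <- rep_len(n_per_class, k)
  half <- floor(n_channels / 2)
  bands <- list(c(4, 8), c(8, 12), c(12, 18), c(18, 25),
                c(25, 35), c(35, 45), c(6, 10), c(15, 22))
  classes <- lapply(seq_len(k), function(i) {
    # rotate the block boundary so each class couples a different bipartition
    shift <- (i - 1L) %% max(1L, n_channels - 3L)
    idx <- ((seq_len(n_channels) - 1L + shift) %% n_channels) + 1L
    list(label = labels[i], hand = hand,
         groups = list(idx[seq_len(half)], idx[(half + 1L):n_channels]),
         band = bands[[i]], coupling = coupling,
         power_gain = power_spread^(i - 1L),
         n = n_per_class[i], duration_s = duration_s)
  })
  simulation_config(classes, n_channels = n_channels, fs = fs, seed = seed)
}
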