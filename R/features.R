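#' Node flexibility from a partition matrix
#'
#' Fraction of successive layer transitions in which a node changes its
#' community: `f_i = 1 - (1/(T-1)) * sum_{r=1}^{T-1} delta(A_{i,r},
#' A_{i,r+1})`. A node whose assignment never changes has flexibility 0; one
#' that changes at every transition has 1.
#'
#' @param A A [partition_matrix()] (N x T, T >= 2).
#' @return Numeric vector of per-node flexibilities in \[0, 1\].
#' @export
flexibility <- function(A) {
  A <- as.matrix(A)
  T_ <- ncol(A)
  if (T_ < 2L) stopf("flexibility needs T >= 2 layers")
  same <- A[, -T_, drop = FALSE] == A[, -1L, drop = FALSE]
  1 - rowSums(same) / (T_ - 1L)
}

#' Integration of a channel scope
#'
#' Mean allegiance of the scope's channels to channels *outside their
#' cortex*: for members i, the average over i of `mean_{j not in cortex}
#' P_ij`. High integration means the cortex's activity is absorbed into
#' communities dominated by other systems.
#'
#' @param P A [module_allegiance()] matrix.
#' @param scope A scope entry from [scope_masks()] (fields `members`,
#'   `cortex_members`).
#' @return Scalar in \[0, 1\].
#' @export
integration <- function(P, scope) {
  outside <- setdiff(seq_len(nrow(P)), scope$cortex_members)
  if (!length(outside)) stopf("integration needs a non-empty cortex complement")
  mean(P[scope$members, outside, drop = FALSE])
}

#' Recruitment of a channel scope
#'
#' Mean allegiance of the scope's channels to the *other members of the same
#' scope*: average over members i of `mean_{j != i in scope} P_ij`. High
#' recruitment means the scope's channels are consistently co-assigned.
#'
#' @inheritParams integration
#' @return Scalar in \[0, 1\].
#' @export
recruitment <- function(P, scope) {
  m <- scope$members
  if (length(m) < 2L) stopf("recruitment needs at least 2 scope members")
  sub <- P[m, m, drop = FALSE]
  (sum(sub) - sum(diag(sub))) / (length(m) * (length(m) - 1L))
}

#' Spectral power per functional cortex
#'
#' Short-time power spectral density with a 1-second Kaiser moving window
#' (shape `beta`, default 14) and 50% overlap. Per channel, segment
#' periodograms are window-gain corrected (divide by the window energy) and
#' the power inside `band_hz` is summed, then averaged over segments. The
#' cortex features are the means over each cortex's channels, hemispheres
#' pooled.
#'
#' @param epoch A `gesture_epoch` (>= 1 s long).
#' @param mont An `eeg_montage` covering the epoch's channels.
#' @param band_hz Band over which power is accumulated; default the analysis
#'   passband up to Nyquist.
#' @param beta Kaiser window shape parameter.
#' @return Named vector `c(power.motor, power.cognition, power.perception)`
#'   (uV^2).
#' @export
psd_power <- function(epoch, mont, band_hz = NULL, beta = 14) {
  stopifnot(inherits(epoch, "gesture_epoch"))
  fs <- epoch$fs
  if (is.null(band_hz)) band_hz <- c(0.2, fs / 2)
  nwin <- round(fs)
  if (ncol(epoch$data) < nwin) stopf("epoch shorter than 1 s")
  ch_power <- channel_band_power(epoch$data, fs, nwin, band_hz, beta)
  masks <- scope_masks(mont, labels = epoch$labels)
  out <- vapply(c("motor", "cognition", "perception"), function(cx)
    mean(ch_power[masks[[paste0(cx, ".whole")]]$members]), 0)
  names(out) <- paste0("power.", c("motor", "cognition", "perception"))
  out
}

# Window-gain-corrected short-time band power per channel.
channel_band_power <- function(X, fs, nwin, band_hz, beta) {
  step <- max(1L, nwin %/% 2L)
  starts <- seq(1L, ncol(X) - nwin + 1L, by = step)
  win <- as.numeric(signal::kaiser(nwin, beta))
  wnorm <- nwin * sum(win^2)
  freqs <- (seq_len(nwin) - 1L) * fs / nwin
  in_band <- pmin(freqs, fs - freqs) >= band_hz[1L] &
    pmin(freqs, fs - freqs) <= band_hz[2L]
  acc <- numeric(nrow(X))
  for (s0 in starts) {
    seg <- X[, s0:(s0 + nwin - 1L), drop = FALSE] *
      matrix(win, nrow(X), nwin, byrow = TRUE)
    F <- t(stats::mvfft(t(seg)))
    acc <- acc + rowSums(Mod(F[, in_band, drop = FALSE])^2) / wnorm
  }
  acc / length(starts)
}

#' Canonical feature names
#'
#' The 60 feature names in canonical order: six per-scope families
#' (flexibility, integration, recruitment, search_information, strength,
#' pairwise_diffusion_efficiency) over the nine scopes
#' \{motor, cognition, perception\} x \{left, right, whole\}, three
#' whole-network features (transitivity, global_efficiency,
#' mean_global_diffusion_efficiency), and three cortex powers.
#'
#' @return Character vector of length 60.
#' @export
feature_names <- function() {
  scopes <- as.vector(t(outer(c("motor", "cognition", "perception"),
                              c("left", "right", "whole"), paste, sep = ".")))
  fams <- c("flexibility", "integration", "recruitment", "search_information",
            "strength", "pairwise_diffusion_efficiency")
  c(as.vector(t(outer(fams, scopes, paste, sep = "."))),
    "transitivity", "global_efficiency", "mean_global_diffusion_efficiency",
    paste0("power.", c("motor", "cognition", "perception")))
}

# Mean over ordered member pairs of a pairwise matrix, non-finite entries
# excluded (their count is returned for logging upstream).
scope_pair_mean <- function(M, members) {
  sub <- M[members, members, drop = FALSE]
  vals <- sub[row(sub) != col(sub)]
  fin <- is.finite(vals)
  list(mean = if (any(fin)) mean(vals[fin]) else 0,
       n_excluded = sum(!fin))
}

#' Assemble the 60-dimensional feature vector of one gesture epoch
#'
#' Combines the epoch's adjacency tensor (layer-wise graph metrics, averaged
#' over the T layers), partition matrix (flexibility), module-allegiance
#' matrix (integration, recruitment) and raw signal (spectral power) into the
#' named 60-feature vector. Disconnected pairs (infinite search information)
#' are excluded from scope means with a message; any remaining non-finite
#' feature is an error naming the feature.
#'
#' @param epoch A `gesture_epoch`.
#' @param tens The epoch's `adjacency_tensor`.
#' @param A The epoch's consensus [partition_matrix()].
#' @param P The epoch's [module_allegiance()] matrix.
#' @param mont An `eeg_montage` covering the epoch's channels.
#' @param aggregate Temporal aggregation of per-layer graph metrics:
#'   `"mean"` (default) or `"median"`.
#' @return Named numeric vector of length 60 (attributes `label`, `hand`).
#' @export
assemble_features <- function(epoch, tens, A, P, mont,
                              aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") mean else stats::median
  masks <- scope_masks(mont, labels = epoch$labels)
  T_ <- dim(tens)[3L]
  flex <- flexibility(A)

  feats <- numeric(0)
  for (nm in names(masks))
    feats[paste0("flexibility.", nm)] <- mean(flex[masks[[nm]]$members])
  for (nm in names(masks))
    feats[paste0("integration.", nm)] <- integration(P, masks[[nm]])
  for (nm in names(masks))
    feats[paste0("recruitment.", nm)] <- recruitment(P, masks[[nm]])

  # per-layer graph metrics
  layer_vals <- lapply(seq_len(T_), function(r) {
    W <- tens[, , r]
    si_pairs <- lapply(masks, function(m) {
      pr <- expand.grid(from = m$members, to = m$members)
      pr <- as.matrix(pr[pr$from != pr$to, , drop = FALSE])
      si <- search_information(W, pr)
      fin <- is.finite(si)
      list(mean = if (any(fin)) mean(si[fin]) else 0,
           n_excluded = sum(!fin))
    })
    s <- node_strength(W)
    Ediff <- diffusion_efficiency(W)
    list(
      si = vapply(si_pairs, function(x) x$mean, 0),
      si_excluded = sum(vapply(si_pairs, function(x) x$n_excluded, 0)),
      strength = vapply(masks, function(m) mean(s[m$members]), 0),
      ediff = vapply(masks, function(m)
        scope_pair_mean(Ediff, m$members)$mean, 0),
      transitivity = transitivity_weighted(W),
      geff = global_efficiency(W),
      gdiff = {
        off <- Ediff[row(Ediff) != col(Ediff)]
        mean(off)
      })
  })
  n_excl <- sum(vapply(layer_vals, function(x) x$si_excluded, 0))
  if (n_excl > 0)
    message(sprintf("assemble_features: %d disconnected pair(s) excluded from search information", n_excl))

  pull <- function(field) {
    m <- do.call(rbind, lapply(layer_vals, function(x) x[[field]]))
    apply(m, 2L, agg)
  }
  si_m <- pull("si"); st_m <- pull("strength"); ed_m <- pull("ediff")
  for (nm in names(masks))
    feats[paste0("search_information.", nm)] <- si_m[nm]
  for (nm in names(masks))
    feats[paste0("strength.", nm)] <- st_m[nm]
  for (nm in names(masks))
    feats[paste0("pairwise_diffusion_efficiency.", nm)] <- ed_m[nm]
  feats["transitivity"] <- agg(vapply(layer_vals, function(x) x$transitivity, 0))
  feats["global_efficiency"] <- agg(vapply(layer_vals, function(x) x$geff, 0))
  feats["mean_global_diffusion_efficiency"] <-
    agg(vapply(layer_vals, function(x) x$gdiff, 0))
  feats <- c(feats, psd_power(epoch, mont))

  feats <- feats[feature_names()]
  if (anyNA(feats) || any(!is.finite(feats)))
    stopf("non-finite feature(s): %s",
          paste(feature_names()[!is.finite(feats)], collapse = ", "))
  attr(feats, "label") <- epoch$label
  attr(feats, "hand") <- epoch$hand
  feats
}

#' Extract the feature table of a set of gesture epochs
#'
#' Runs the full per-epoch pipeline — adjacency tensor, multilayer community
#' ensemble, consensus partition, module allegiance, feature assembly — and
#' returns one row per epoch with the 60 canonical features plus `label`,
#' `hand` and `subject`.
#'
#' @param epochs List of `gesture_epoch` objects.
#' @param mont An `eeg_montage` covering the epochs' channels.
#' @param conn_config A [connectivity_config()].
#' @param comm_config A [community_config()]; epoch k uses a counter-derived
#'   sub-seed of `comm_config$seed` so the table is reproducible.
#' @param progress Emit a message every 25 epochs.
#' @return data.frame: 60 feature columns + `label`, `hand`, `subject`.
#' @export
extract_feature_table <- function(epochs, mont,
                                  conn_config = connectivity_config(),
                                  comm_config = community_config(),
                                  progress = FALSE) {
  rows <- vector("list", length(epochs))
  for (k in seq_along(epochs)) {
    ep <- epochs[[k]]
    cfg <- comm_config
    cfg$seed <- derive_seed(comm_config$seed, k)
    tens <- build_tensor(ep, conn_config)
    runs <- louvain_ensemble(tens, cfg)
    A <- consensus_partition(runs, cfg)
    P <- module_allegiance(runs)
    f <- assemble_features(ep, tens, A, P, mont)
    rows[[k]] <- data.frame(as.list(f), check.names = FALSE,
                            label = ep$label, hand = ep$hand,
                            subject = ep$subject, stringsAsFactors = FALSE)
    if (progress && k %% 25L == 0L)
      message(sprintf("extracted %d / %d epochs", k, length(epochs)))
  }
  do.call(rbind, rows)
}

#' Montage for synthetic recordings
#'
#' Maps the generator's `ch1..chN` channels onto the three functional
#' cortices with left/right hemispheres, proportionally to the full-cap
#' sizes (motor 70 : cognition 37 : perception 12), so synthetic data can
#' flow through the scope-based feature extractor.
#'
#' @param n_channels Number of synthetic channels (>= 6).
#' @return An `eeg_montage`.
#' @export
synthetic_montage <- function(n_channels) {
  stopifnot(n_channels >= 12L)
  n_per <- max(4L, round(n_channels * 12 / 119))
  n_cog <- max(4L, round(n_channels * 37 / 119))
  n_mot <- n_channels - n_cog - n_per
  cortex <- rep(c("motor", "cognition", "perception"),
                c(n_mot, n_cog, n_per))
  hemi <- unlist(lapply(c(n_mot, n_cog, n_per), function(n)
    rep(c("left", "right"), length.out = n)))
  pos <- sphere_positions(n_channels)
  montage(data.frame(name = paste0("ch", seq_len(n_channels)),
                     x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
                     cortex = cortex, hemisphere = hemi,
                     stringsAsFactors = FALSE))
}
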