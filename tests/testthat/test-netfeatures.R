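test_that("flexibility follows the successive-layer change fraction", {
  expect_equal(flexibility(matrix(2, 3, 10)), rep(0, 3))
  alternating <- matrix(rep(c(1, 2), 5), 1, 10)
  expect_equal(flexibility(alternating), 1)
  one_change <- matrix(c(1, 1, 2), 1, 3)
  expect_equal(flexibility(one_change), 0.5)
  expect_error(flexibility(matrix(1, 3, 1)), "T >= 2")
  withr::with_seed(8, A <- matrix(sample(1:3, 24, TRUE), 4, 6))
  expect_equal(flexibility(A), oracle_flexibility(A))
})

test_that("integration and recruitment match direct definitions", {
  scope <- list(cortex = "motor", scope = "whole", members = 1:2,
                cortex_members = 1:2)
  ones <- matrix(1, 4, 4)
  expect_equal(integration(ones, scope), 1)
  expect_equal(recruitment(ones, scope), 1)

  block <- matrix(0, 4, 4)
  block[1:2, 1:2] <- 1; block[3:4, 3:4] <- 1
  expect_equal(integration(block, scope), 0)
  expect_equal(recruitment(block, scope), 1)

  P <- matrix(c(1, .8, .3, .1,
                .8, 1, .2, .4,
                .3, .2, 1, .6,
                .1, .4, .6, 1), 4, 4)
  expect_equal(integration(P, scope), mean(c(.3, .1, .2, .4)))
  expect_equal(integration(P, scope), oracle_integration(P, 1:2, 1:2))
  expect_equal(recruitment(P, scope), .8)
  expect_equal(recruitment(P, scope), oracle_recruitment(P, 1:2))
  expect_error(recruitment(P, list(members = 1, cortex_members = 1)),
               "at least 2")
})

test_that("search information covers closed forms and the path-enumeration oracle", {
  # two nodes, one edge: the only step has probability 1
  W2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(search_information(W2, cbind(1, 2)), 0)
  # equal two-edge star: 1 bit
  W3 <- matrix(0, 3, 3)
  W3[1, 2] <- W3[2, 1] <- 1; W3[1, 3] <- W3[3, 1] <- 1
  expect_equal(search_information(W3, cbind(1, 2)), 1)
  # 5-node weighted graphs vs exhaustive enumeration
  for (s in 1:3) {
    W <- random_weighted_graph(5, density = 0.5, seed = 40 + s)
    pairs <- as.matrix(expand.grid(1:5, 1:5))
    pairs <- pairs[pairs[, 1] != pairs[, 2], ]
    si <- search_information(W, pairs)
    si_oracle <- vapply(seq_len(nrow(pairs)), function(k)
      oracle_search_information(W, pairs[k, 1], pairs[k, 2]), 0)
    expect_equal(si, si_oracle, tolerance = 1e-9)
  }
  # disconnected pair
  W4 <- matrix(0, 4, 4); W4[1, 2] <- W4[2, 1] <- 1; W4[3, 4] <- W4[4, 3] <- 1
  expect_equal(search_information(W4, cbind(1, 3)), Inf)
})

test_that("strength sums incident weights", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.2; W[1, 3] <- W[3, 1] <- 0.3
  expect_equal(node_strength(W), c(0.5, 0.2, 0.3))
  expect_equal(node_strength(matrix(0, 4, 4)), rep(0, 4))
  # diagonal never counts
  diag(W) <- 1
  expect_equal(node_strength(W)[1], 0.5)
})

test_that("MFPT and diffusion efficiency match absorbing-chain solutions", {
  W2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(mean_first_passage_time(W2)[1, 2], 1)
  expect_equal(diffusion_efficiency(W2)[1, 2], 1)

  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(mean_first_passage_time(tri)[1, 2], 2)
  expect_equal(diffusion_efficiency(tri)[1, 2], 0.5)

  for (s in 1:3) {
    W <- random_weighted_graph(6, seed = 50 + s)
    M <- mean_first_passage_time(W)
    for (target in c(1, 4)) {
      expect_equal(M[, target], oracle_mfpt(W, target), tolerance = 1e-9)
    }
  }
  # disconnected: zero efficiency
  W4 <- matrix(0, 4, 4); W4[1, 2] <- W4[2, 1] <- 1; W4[3, 4] <- W4[4, 3] <- 1
  expect_equal(diffusion_efficiency(W4)[1, 3], 0)
})

test_that("weighted transitivity spans closed forms, the oracle and scale-invariance", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(transitivity_weighted(tri), 1)
  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 1] <- 1
  path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(transitivity_weighted(path3), 0)
  W <- random_weighted_graph(4, seed = 60)
  expect_equal(transitivity_weighted(W), oracle_transitivity(W),
               tolerance = 1e-9)
  expect_equal(transitivity_weighted(3.7 * W), transitivity_weighted(W),
               tolerance = 1e-12)
  expect_error(transitivity_weighted(matrix(0, 2, 2)), "3 nodes")
})

test_that("global efficiency spans closed forms, the oracle and linear scaling", {
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  expect_equal(global_efficiency(K4), 1)
  iso <- matrix(0, 2, 2)
  expect_equal(global_efficiency(iso), 0)
  for (s in 1:3) {
    W <- random_weighted_graph(6, seed = 70 + s)
    expect_equal(global_efficiency(W), oracle_global_efficiency(W),
                 tolerance = 1e-9)
    expect_equal(global_efficiency(2.5 * W), 2.5 * global_efficiency(W),
                 tolerance = 1e-9)
    # strength scales linearly too; SI is scale-free
    expect_equal(node_strength(2.5 * W), 2.5 * node_strength(W))
    pairs <- cbind(c(1, 2), c(3, 5))
    expect_equal(search_information(2.5 * W, pairs),
                 search_information(W, pairs), tolerance = 1e-9)
  }
})

channel_band_power_for_test <- function(ep) {
  masks <- scope_masks(fixture_montage(12), labels = ep$labels)
  pw <- psd_power(ep, fixture_montage(12))
  # recover per-channel power of channel 1 from the motor mean: all other
  # motor channels are zero, so power.motor = p1 / |motor|
  n <- length(masks$motor.whole$members)
  c(unname(pw["power.motor"]) * n)
}

test_that("spectral power obeys Parseval scaling and cortex pooling", {
  mont <- fixture_montage(12)
  fs <- 250
  ep <- fixture_epoch(n_ch = 12, dur_s = 4, fs = fs)
  ep$labels <- paste0("ch", 1:12)
  rownames(ep$data) <- ep$labels

  zero <- ep; zero$data[] <- 0
  expect_equal(unname(psd_power(zero, mont)), c(0, 0, 0))

  # pure 10 Hz tone of amplitude a -> power a^2/2 within 5%
  a <- 2
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  tone_ep <- ep
  tone_ep$data[] <- 0
  tone_ep$data[1, ] <- a * sin(2 * pi * 10 * t)
  p <- channel_band_power_for_test(tone_ep)
  expect_equal(p[1], a^2 / 2, tolerance = 0.05)

  # doubling amplitude quadruples power
  dbl <- tone_ep; dbl$data[1, ] <- 2 * dbl$data[1, ]
  expect_equal(channel_band_power_for_test(dbl)[1], 4 * p[1],
               tolerance = 1e-9)

  # cortex features average member channels (hemispheres pooled)
  pw <- psd_power(tone_ep, mont)
  masks <- scope_masks(mont, labels = ep$labels)
  expect_equal(unname(pw["power.motor"]),
               p[1] / length(masks$motor.whole$members), tolerance = 1e-6)
})

test_that("feature assembly emits the canonical 60-vector with invariances", {
  cfg <- demo_config(k = 2, n_channels = 12, n_per_class = 1, seed = 17)
  ds <- generate_dataset(cfg)
  ep <- extract_epochs(ds$recording, ds$annotations)[[1]]
  mont <- fixture_montage(12)
  tens <- build_tensor(ep)
  cc <- community_config(repetitions = 5, seed = 2)
  runs <- louvain_ensemble(tens, cc)
  A <- consensus_partition(runs, cc)
  P <- module_allegiance(runs)
  f <- assemble_features(ep, tens, A, P, mont)

  expect_length(f, 60L)
  expect_identical(names(f), feature_names())
  expect_true(all(is.finite(f)))
  # 57 network + 3 PSD; 9 per per-scope family
  expect_equal(sum(!startsWith(names(f), "power.")), 57L)
  expect_equal(sum(startsWith(names(f), "power.")), 3L)
  for (fam in c("flexibility", "integration", "recruitment",
                "search_information", "strength",
                "pairwise_diffusion_efficiency"))
    expect_equal(sum(startsWith(names(f), paste0(fam, "."))), 9L)
  # bounded families
  bounded <- f[grep("^(flexibility|integration|recruitment)\\.|^transitivity$|^global_efficiency$",
                    names(f))]
  expect_true(all(bounded >= 0 & bounded <= 1))

  # permutation invariance: permute channels + montage together
  perm <- withr::with_seed(1, sample(12))
  ep2 <- ep
  ep2$data <- ep$data[perm, ]
  ep2$labels <- ep$labels[perm]
  rownames(ep2$data) <- ep2$labels
  tens2 <- adjacency_tensor(tens[perm, perm, , drop = FALSE],
                            labels = ep2$labels)
  A2 <- partition_matrix(unclass(A)[perm, , drop = FALSE])
  P2 <- structure(unclass(P)[perm, perm], class = "module_allegiance")
  f2 <- assemble_features(ep2, tens2, A2, P2, mont)
  expect_equal(f2, f, tolerance = 1e-9)
})

test_that("feature extraction pipeline returns one labelled row per epoch", {
  cfg <- demo_config(k = 2, n_channels = 12, n_per_class = 2, seed = 19)
  ds <- generate_dataset(cfg)
  eps <- extract_epochs(ds$recording, ds$annotations)
  feats <- extract_feature_table(eps, fixture_montage(12),
                                 comm_config = community_config(
                                   repetitions = 5, seed = 3))
  expect_equal(nrow(feats), length(eps))
  expect_equal(ncol(feats), 63L)   # 60 features + label, hand, subject
  expect_setequal(unique(feats$label),
                  vapply(eps, function(e) e$label, ""))
})
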