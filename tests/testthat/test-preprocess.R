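tone <- function(freq, fs, dur_s, amp = 1) {
  amp * sin(2 * pi * freq * seq(0, dur_s - 1 / fs, by = 1 / fs))
}
rms <- function(x) sqrt(mean(x^2))

test_that("DC removal zeroes channel means and is idempotent", {
  rec <- recording(rbind(rep(5, 100), c(1:100)), fs = 100)
  out <- remove_dc(rec)
  expect_equal(out$data[1, ], rep(0, 100))
  expect_equal(rowMeans(out$data), c(0, 0), ignore_attr = TRUE)
  expect_equal(remove_dc(out)$data, out$data)
  expect_equal(remove_dc(recording(matrix(c(1, 2, 3), 1), fs = 1))$data[1, ],
               c(-1, 0, 1))
})

test_that("notch filter suppresses the line frequency and spares the passband", {
  fs <- 500
  rec60 <- recording(matrix(tone(60, fs, 10), 1), fs = fs)
  out60 <- notch_filter(rec60)
  mid <- 1000:4000
  expect_lt(rms(out60$data[1, mid]), 0.05 * rms(rec60$data[1, mid]))

  rec10 <- recording(matrix(tone(10, fs, 10), 1), fs = fs)
  out10 <- notch_filter(rec10)
  expect_equal(rms(out10$data[1, mid]), rms(rec10$data[1, mid]),
               tolerance = 0.01)

  zero <- recording(matrix(0, 2, 1000), fs = fs)
  expect_equal(notch_filter(zero)$data, zero$data)
  expect_error(notch_filter(recording(matrix(0, 1, 100), fs = 100)),
               "Nyquist")
})

test_that("band-pass removes DC and drift but passes oscillations", {
  # settling of the 0.2 Hz high-pass takes ~10 s; assert on the steady state
  fsd <- 100
  recDC <- recording(matrix(rep(10, 60 * fsd), 1), fs = fsd)
  outDC <- bandpass_filter(recDC)
  expect_lt(max(abs(outDC$data[1, 2500:3500])), 0.1)

  fs <- 500
  rec10 <- recording(matrix(tone(10, fs, 10), 1), fs = fs)
  out10 <- bandpass_filter(rec10)
  mid <- 1000:4000
  expect_equal(rms(out10$data[1, mid]), rms(rec10$data[1, mid]),
               tolerance = 0.01)

  # 0.02 Hz drift, one decade below the 0.2 Hz edge: >= 24 dB down
  fs2 <- 50
  drift <- recording(matrix(tone(0.02, fs2, 400), 1), fs = fs2)
  outd <- bandpass_filter(drift)
  mid2 <- 5000:15000
  expect_lt(rms(outd$data[1, mid2]) / rms(drift$data[1, mid2]), 10^(-24 / 20))

  expect_error(bandpass_filter(rec10, preprocess_config(band_hz = c(0, 250))),
               "0 < low < high")
})

test_that("filters are zero-phase: a symmetric pulse stays symmetric", {
  fs <- 500
  n <- 2001
  x <- exp(-((seq_len(n) - 1001)^2) / (2 * 40^2))
  rec <- recording(matrix(x, 1), fs = fs)
  for (out in list(notch_filter(rec), bandpass_filter(rec))) {
    y <- out$data[1, ]
    expect_lt(max(abs(y - rev(y))), 1e-6)
  }
})

test_that("preprocessing chain is deterministic and shape-preserving", {
  rec <- fixture_recording(5, 2000, fs = 500)
  mont <- toy_montage5()
  out1 <- preprocess_recording(rec, mont,
                               config = preprocess_config(laplacian_k = 2))
  out2 <- preprocess_recording(rec, mont,
                               config = preprocess_config(laplacian_k = 2))
  expect_identical(out1$data, out2$data)
  expect_identical(out1$labels, rec$labels)
  expect_identical(dim(out1$data), dim(rec$data))
})

test_that("topographic PCA removes a planted rank-1 artifact", {
  fs <- 250
  n <- fs * 20
  n_ch <- 24
  withr::with_seed(3, {
    clean <- matrix(stats::rnorm(n_ch * n), n_ch, n)
    # spread topography: projecting out one spatial direction costs each
    # channel only ~1/n_ch of its clean variance
    topo <- sample(c(-1, 1), n_ch, TRUE) * stats::runif(n_ch, 0.8, 1.2)
    burst <- numeric(n)
    art_idx <- (5 * fs):(8 * fs)
    burst[art_idx] <- 30 * sin(2 * pi * 2 * seq_along(art_idx) / fs)
    mixed <- clean + topo %o% burst
  })
  rec <- recording(mixed, fs = fs)
  res <- spatial_pca_artifact_removal(
    rec, data.frame(start_s = 5, end_s = 8),
    preprocess_config(artifact_cor_threshold = 0.9,
                      artifact_max_components = 2))
  expect_lte(res$n_removed, 2L)
  expect_gte(res$n_removed, 1L)
  cors <- vapply(1:n_ch, function(i)
    stats::cor(res$recording$data[i, ], clean[i, ]), 0)
  expect_true(all(cors > 0.95))

  # no marked intervals: identity
  res0 <- spatial_pca_artifact_removal(rec, NULL)
  expect_identical(res0$recording$data, rec$data)
  expect_equal(res0$n_removed, 0L)
  expect_error(spatial_pca_artifact_removal(
    rec, data.frame(start_s = 19, end_s = 25)), "outside")
})

test_that("surface Laplacian removes common-mode and follows the neighbour rule", {
  mont <- toy_montage5()
  fs <- 100
  common <- matrix(rep(tone(5, fs, 2), each = 5), 5)
  rec <- recording(common, fs = fs, labels = paste0("ch", 1:5))
  out <- surface_laplacian(rec, mont, preprocess_config(laplacian_k = 4))
  expect_lt(max(abs(out$data)), 1e-10)

  # one active channel among silent ones: k = 2 nearest neighbours
  act <- matrix(0, 5, 200)
  act[1, ] <- tone(5, fs, 2)
  rec2 <- recording(act, fs = fs, labels = paste0("ch", 1:5))
  out2 <- surface_laplacian(rec2, mont, preprocess_config(laplacian_k = 2))
  # ch1 at origin: its neighbours are silent -> unchanged
  expect_equal(out2$data[1, ], act[1, ])
  # every other channel has ch1 (origin) among its 2 nearest -> -1/2 of it
  for (i in 2:5) expect_equal(out2$data[i, ], -act[1, ] / 2)
  expect_error(surface_laplacian(rec2, mont,
                                 preprocess_config(laplacian_k = 5)),
               "below channel count")
})
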