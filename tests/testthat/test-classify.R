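# Separable 3-class feature fixture: class means far apart relative to noise.
separable_features <- function(n_per = 30, p = 8, gap = 10, seed = 1,
                               labels = c("Suturing", "Retraction", "Idle")) {
  withr::with_seed(seed, {
    rows <- lapply(seq_along(labels), function(k) {
      X <- matrix(stats::rnorm(n_per * p), n_per, p)
      X[, 1:2] <- X[, 1:2] + gap * k
      X
    })
  })
  X <- do.call(rbind, rows)
  colnames(X) <- paste0("f", seq_len(p))
  data.frame(X, label = rep(labels, each = n_per), hand = "dominant",
             stringsAsFactors = FALSE)
}

test_that("SMOTE balances classes with convex synthetic points only", {
  withr::with_seed(2, {
    X <- rbind(matrix(stats::rnorm(100 * 3), 100, 3),
               matrix(stats::rnorm(20 * 3, mean = 5), 20, 3))
  })
  y <- rep(c("maj", "min"), c(100, 20))
  out <- smote_oversample(X, y, seed = 7)
  expect_equal(unname(table(out$y)["min"]), 100, ignore_attr = TRUE)
  expect_equal(unname(table(out$y)["maj"]), 100, ignore_attr = TRUE)
  # original rows untouched, in order
  expect_identical(out$X[1:120, ], X)
  expect_false(any(out$synthetic[1:120]))
  # each synthetic row is a convex combination of two original minority rows
  Xmin <- X[101:120, ]
  syn <- out$X[out$synthetic, , drop = FALSE]
  on_segment <- apply(syn, 1, function(z) {
    for (a in 1:20) for (b in 1:20) {
      d <- Xmin[b, ] - Xmin[a, ]
      if (sum(d^2) == 0) next
      u <- sum((z - Xmin[a, ]) * d) / sum(d^2)
      if (u > -1e-9 && u < 1 + 1e-9 &&
          sqrt(sum((Xmin[a, ] + u * d - z)^2)) < 1e-8) return(TRUE)
    }
    FALSE
  })
  expect_true(all(on_segment))
  # determinism
  out2 <- smote_oversample(X, y, seed = 7)
  expect_identical(out$X, out2$X)
  expect_error(smote_oversample(X[1:101, ], y[1:101]), ">= 2 samples")
  expect_warning(smote_oversample(X[c(1:100, 101:103), ],
                                  y[c(1:100, 101:103)]), "k reduced")
})

test_that("ANOVA F-scores rank features by class separation", {
  feats <- separable_features(n_per = 20, gap = 6, seed = 3)
  X <- as.matrix(feats[paste0("f", 1:8)])
  f <- anova_f_scores(X, feats$label)
  expect_true(all(which(rank(-f) <= 2) %in% 1:2))
  # constant feature -> F = 0, ranks last
  X2 <- cbind(X, const = 1)
  f2 <- anova_f_scores(X2, feats$label)
  expect_equal(unname(f2["const"]), 0)
  expect_equal(which.min(f2), c(const = 9L))
  # two-class F equals the squared pooled-variance t statistic
  two <- feats$label != "Idle"
  f_two <- anova_f_scores(X[two, ], feats$label[two])
  t_stat <- vapply(1:8, function(j)
    stats::t.test(X[two, j] ~ feats$label[two], var.equal = TRUE)$statistic,
    0)
  expect_equal(unname(f_two), unname(t_stat^2), tolerance = 1e-9)
  # selecting all features is the identity
  expect_setequal(select_top_features(f, 8), 1:8)
  expect_length(select_top_features(f, 3), 3)
})

test_that("stratified folds partition the data with class balance", {
  y <- rep(c("a", "b", "c"), c(40, 20, 10))
  folds <- stratified_folds(y, 10, seed = 4)
  expect_setequal(folds, 1:10)
  expect_length(folds, 70)
  for (f in 1:10) expect_equal(sum(folds == f & y == "a"), 4)
  expect_error(stratified_folds(rep(c("a", "b"), c(30, 5)), 10),
               "too small")
})

test_that("metrics match hand-computed values from a fixed confusion matrix", {
  # 3x3 confusion (rows = truth): hand-computed macro metrics
  truth <- rep(c("a", "b", "c"), c(10, 10, 10))
  pred <- c(rep("a", 8), "b", "c",
            rep("b", 7), "a", "a", "c",
            rep("c", 9), "a")
  m <- gesturenet:::classification_metrics(truth, pred, c("a", "b", "c"))
  expect_equal(m$accuracy, 24 / 30)
  expect_equal(m$precision_macro, mean(c(8 / 11, 7 / 8, 9 / 11)))
  expect_equal(m$sensitivity_macro, mean(c(8 / 10, 7 / 10, 9 / 10)))
  expect_equal(unname(rowSums(m$confusion)), c(10, 10, 10))
})

test_that("cross-validation is exhaustive, deterministic and solves separable data", {
  feats <- separable_features()
  rep1 <- cross_validate(feats, classifier_spec("ET"), seed = 5)
  expect_equal(rep1$accuracy, 1.0)
  expect_length(rep1$fold_accuracy, 10L)
  expect_equal(unname(rowSums(rep1$confusion)), rep(1, 3), tolerance = 1e-9)
  # each instance lands in exactly one test fold
  folds <- stratified_folds(feats$label, 10, seed = 5)
  expect_length(folds, nrow(feats))
  expect_setequal(folds, 1:10)
  # determinism of the full report
  rep2 <- cross_validate(feats, classifier_spec("ET"), seed = 5)
  expect_identical(rep1, rep2)
  # KNN (distance-based, all 8 dims standardized) is near-perfect too
  expect_gte(cross_validate(feats, classifier_spec("KNN"),
                            seed = 5)$accuracy, 0.9)
})

test_that("hand filtering restricts rows to the hand's vocabulary", {
  feats <- separable_features(labels = c("Tissue Grasping", "Retraction",
                                         "Blunt Dissection"))
  feats$hand <- ifelse(feats$label == "Blunt Dissection", "dominant",
                       "non-dominant")
  rep_ <- cross_validate(feats, classifier_spec("ET"), seed = 6,
                         hand = "non-dominant", n_folds = 10)
  expect_setequal(rep_$classes, c("Tissue Grasping", "Retraction"))
})

test_that("paired comparisons reproduce textbook t-test results", {
  same <- compare_classifiers(c(.9, .8, .85), c(.9, .8, .85))
  expect_equal(same$improvement, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  # differences 1, 2, 3 percentage points
  cmp <- compare_classifiers(c(.91, .92, .93), c(.90, .90, .90),
                             n_comparisons = 1)
  expect_equal(cmp$improvement, 2, tolerance = 1e-9)
  expect_equal(cmp$t, 2 / (1 / sqrt(3)), tolerance = 1e-3)   # 3.464
  expect_equal(cmp$p_value, 0.0742, tolerance = 1e-2)
  expect_true(cmp$conf_int[1] <= 2 && 2 <= cmp$conf_int[2])

  # Bonferroni: m * p, capped at 1
  cmp6 <- compare_classifiers(c(.91, .92, .93), c(.90, .90, .90),
                              n_comparisons = 6)
  expect_equal(cmp6$p_adjusted, min(1, 6 * cmp6$p_value))
  expect_error(compare_classifiers(1:3 / 10, 1:4 / 10), "length")
})

test_that("accuracy-by-feature-count grids reduce and tabulate correctly", {
  feats <- separable_features(n_per = 20)
  specs <- list(classifier_spec("ET"), classifier_spec("KNN"))
  curve <- accuracy_vs_nfeatures(feats, specs, grid = c(2, 8), seed = 8)
  expect_equal(nrow(curve), 4L)
  expect_setequal(curve$classifier, c("ET", "KNN"))
  # grid of one value reduces to a single cross_validate call
  single <- accuracy_vs_nfeatures(feats, list(classifier_spec("ET")),
                                  grid = 8, seed = 8)
  direct <- cross_validate(feats, classifier_spec("ET"), n_selected = 8,
                           seed = 8)
  expect_equal(single$accuracy, mean(direct$fold_accuracy))
})
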