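#' Classifier specification
#'
#' The four evaluated model families with their fixed hyperparameters:
#' `KNN` (5 neighbours, uniform weights), and three tree ensembles with 350
#' trees, Gini split criterion, minimum split size 2 and minimum leaf size 1:
#' `BAG` (bagged unpruned trees on bootstrap replicas, all features at every
#' split), `RF` (bootstrap replicas, random feature subset per split), and
#' `ET` (whole training sample, random feature subset and random split
#' points).
#'
#' @param name `"KNN"`, `"BAG"`, `"RF"` or `"ET"`.
#' @param n_trees Ensemble size.
#' @param knn_k Neighbour count for KNN.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(name = c("KNN", "BAG", "RF", "ET"),
                            n_trees = 350L, knn_k = 5L) {
  name <- match.arg(name)
  if (n_trees < 1L) stopf("tree count must be >= 1")
  structure(list(name = name, n_trees = as.integer(n_trees),
                 knn_k = as.integer(knn_k)),
            class = "classifier_spec")
}

# Fit + predict one train/test split under a spec. Features are scaled by
# the training means/sds for KNN (distance-based); trees are scale-free.
fit_predict <- function(spec, X_train, y_train, X_test, seed) {
  y_train <- factor(y_train)
  if (spec$name == "KNN") {
    mu <- colMeans(X_train)
    sdv <- apply(X_train, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    Xtr <- sweep(sweep(X_train, 2L, mu), 2L, sdv, "/")
    Xte <- sweep(sweep(X_test, 2L, mu), 2L, sdv, "/")
    pred <- withr::with_seed(seed,
      class::knn(Xtr, Xte, cl = y_train, k = spec$knn_k))
    return(factor(as.character(pred), levels = levels(y_train)))
  }
  p <- ncol(X_train)
  args <- list(
    x = as.data.frame(X_train), y = y_train,
    num.trees = spec$n_trees,
    min.node.size = 2L, min.bucket = 1L,
    num.threads = 1L, seed = seed, verbose = FALSE)
  args <- switch(spec$name,
    BAG = c(args, list(splitrule = "gini", mtry = p, replace = TRUE)),
    RF = c(args, list(splitrule = "gini", mtry = max(1L, floor(sqrt(p))),
                      replace = TRUE)),
    ET = c(args, list(mtry = max(1L, floor(sqrt(p))), replace = FALSE,
                      sample.fraction = 1, splitrule = "extratrees",
                      num.random.splits = 1L)))
  fit <- do.call(ranger::ranger, args)
  pred <- stats::predict(fit, data = as.data.frame(X_test),
                         seed = seed, num.threads = 1L)$predictions
  factor(as.character(pred), levels = levels(y_train))
}

#' SMOTE oversampling
#'
#' Synthetic minority oversampling: every class is brought up to the
#' majority-class count by adding convex combinations `x + u * (x_nn - x)`,
#' `u ~ U(0, 1)`, where `x_nn` is one of the `k` nearest same-class
#' neighbours of a randomly chosen minority sample. Original rows are kept
#' unchanged. Applied to training data only — never to test folds.
#'
#' @param X Numeric matrix (samples x features).
#' @param y Class labels (length `nrow(X)`); every class needs >= 2 samples.
#' @param k Neighbour count; reduced with a warning for classes of size <= k.
#' @param seed Seed making the synthesis deterministic.
#' @return List with balanced `X`, `y`, and `synthetic` (logical row flags).
#' @export
smote_oversample <- function(X, y, k = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.character(y)
  counts <- table(y)
  if (any(counts < 2L))
    stopf("SMOTE requires >= 2 samples per class (violated by: %s)",
          paste(names(counts)[counts < 2L], collapse = ", "))
  target <- max(counts)
  new_rows <- list()
  new_y <- character()
  withr::with_seed(as.integer(seed), {
    for (cls in names(counts)) {
      deficit <- target - counts[[cls]]
      if (deficit == 0L) next
      idx <- which(y == cls)
      k_use <- min(k, length(idx) - 1L)
      if (k_use < k)
        warning(sprintf("class %s has %d samples; k reduced to %d",
                        cls, length(idx), k_use))
      Xc <- X[idx, , drop = FALSE]
      D <- as.matrix(stats::dist(Xc))
      diag(D) <- Inf
      nn <- apply(D, 1L, function(d) order(d)[seq_len(k_use)],
                  simplify = FALSE)
      base <- sample(length(idx), deficit, replace = TRUE)
      for (b in base) {
        pick <- nn[[b]][sample.int(k_use, 1L)]
        u <- stats::runif(1)
        new_rows[[length(new_rows) + 1L]] <-
          Xc[b, ] + u * (Xc[pick, ] - Xc[b, ])
        new_y <- c(new_y, cls)
      }
    }
  })
  if (length(new_rows)) {
    Xs <- rbind(X, do.call(rbind, new_rows))
    ys <- c(y, new_y)
  } else {
    Xs <- X; ys <- y
  }
  list(X = Xs, y = ys,
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, length(new_y))))
}

#' ANOVA F-scores for feature selection
#'
#' One-way ANOVA F statistic per feature: between-class mean square over
#' within-class mean square. A feature that is constant within every class
#' but differs between classes scores `Inf` (ranks first); a globally
#' constant feature scores 0 (ranks last). Selection keeps the `n_selected`
#' largest scores.
#'
#' @param X Numeric matrix (samples x features).
#' @param y Class labels; >= 2 classes with >= 2 samples each.
#' @return Named numeric vector of F values (one per column of `X`).
#' @export
anova_f_scores <- function(X, y) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2L) stopf("ANOVA F needs >= 2 classes")
  n <- nrow(X)
  g <- nlevels(y)
  grand <- colMeans(X)
  ss_between <- numeric(ncol(X))
  ss_within <- numeric(ncol(X))
  for (lev in levels(y)) {
    idx <- y == lev
    m <- colMeans(X[idx, , drop = FALSE])
    ss_between <- ss_between + sum(idx) * (m - grand)^2
    ss_within <- ss_within +
      colSums((X[idx, , drop = FALSE] -
                 matrix(m, sum(idx), ncol(X), byrow = TRUE))^2)
  }
  msb <- ss_between / (g - 1L)
  msw <- ss_within / (n - g)
  f <- ifelse(msw == 0, ifelse(msb == 0, 0, Inf), msb / msw)
  names(f) <- colnames(X)
  f
}

#' @param scores Output of [anova_f_scores()].
#' @param n_selected Number of features to keep.
#' @rdname anova_f_scores
#' @export
select_top_features <- function(scores, n_selected) {
  n_selected <- min(n_selected, length(scores))
  order(scores, decreasing = TRUE)[seq_len(n_selected)]
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `n_folds` folds, keeping class proportions
#' as equal as possible across folds. Every class must have at least
#' `n_folds` samples.
#'
#' @param y Class labels.
#' @param n_folds Fold count.
#' @param seed Seed for the within-class shuffling.
#' @return Integer vector of fold ids in `1..n_folds`.
#' @export
stratified_folds <- function(y, n_folds = 10L, seed = 1L) {
  y <- as.character(y)
  counts <- table(y)
  if (any(counts < n_folds))
    stopf("class too small to stratify into %d folds: %s", n_folds,
          paste(names(counts)[counts < n_folds], collapse = ", "))
  fold <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (cls in names(counts)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

# Macro-averaged precision/sensitivity and confusion matrix from label pairs.
classification_metrics <- function(truth, pred, levels) {
  truth <- factor(truth, levels = levels)
  pred <- factor(pred, levels = levels)
  cm <- table(truth = truth, pred = pred)
  tp <- diag(cm)
  prec <- tp / pmax(colSums(cm), 1L)
  sens <- tp / pmax(rowSums(cm), 1L)
  list(accuracy = sum(tp) / sum(cm),
       precision_macro = mean(prec),
       sensitivity_macro = mean(sens),
       precision_weighted = sum(prec * rowSums(cm)) / sum(cm),
       sensitivity_weighted = sum(sens * rowSums(cm)) / sum(cm),
       confusion = cm)
}

#' Cross-validated gesture classification
#'
#' The full evaluation protocol: stratified 10-fold cross-validation where,
#' inside each training fold only, SMOTE balances the class counts, ANOVA
#' F-scores are computed on the oversampled training data, the top
#' `n_selected` features are kept, and the classifier is fitted; the
#' untouched test fold is then predicted. Test rows never reach the
#' oversampler or the F statistics (no leakage). Deterministic given `seed`.
#'
#' @param features Feature table (data.frame from [extract_feature_table()]
#'   or [read_feature_table()]): feature columns + `label` (+ optionally
#'   `hand`).
#' @param spec A [classifier_spec()].
#' @param n_selected Number of features kept per fold (default: all).
#' @param n_folds Fold count.
#' @param seed Master seed (folds, SMOTE, classifier).
#' @param hand Restrict to one hand's gesture vocabulary (`NULL` = use all
#'   rows as-is).
#' @param folds Optional precomputed fold assignment (overrides `seed`-based
#'   stratification).
#' @return A `cv_report`: per-fold accuracies, macro/weighted precision and
#'   sensitivity, pooled row-normalized confusion matrix, per-fold selected
#'   features, SMOTE digests, and the configuration.
#' @export
cross_validate <- function(features, spec, n_selected = NULL, n_folds = 10L,
                           seed = 1L, hand = NULL, folds = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (!is.null(hand)) {
    features <- features[features$hand == hand &
                           features$label %in% hand_vocabulary(hand), ]
  }
  meta <- intersect(c("label", "hand", "subject"), names(features))
  X <- as.matrix(features[setdiff(names(features), meta)])
  storage.mode(X) <- "double"
  y <- as.character(features$label)
  levels_ <- sort(unique(y))
  if (is.null(n_selected)) n_selected <- ncol(X)
  if (is.null(folds)) folds <- stratified_folds(y, n_folds, seed)
  n_folds <- max(folds)

  fold_acc <- numeric(n_folds)
  selected <- vector("list", n_folds)
  smote_digest <- numeric(n_folds)
  truth_all <- character(0)
  pred_all <- character(0)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    sm <- smote_oversample(X[tr, , drop = FALSE], y[tr],
                           seed = derive_seed(seed, f))
    scores <- anova_f_scores(sm$X, sm$y)
    keep <- select_top_features(scores, n_selected)
    selected[[f]] <- colnames(X)[keep]
    smote_digest[f] <- sum(sm$X) + length(sm$y)
    pred <- fit_predict(spec, sm$X[, keep, drop = FALSE], sm$y,
                        X[!tr, keep, drop = FALSE],
                        seed = derive_seed(seed, 5000L + f))
    fold_acc[f] <- mean(as.character(pred) == y[!tr])
    truth_all <- c(truth_all, y[!tr])
    pred_all <- c(pred_all, as.character(pred))
  }
  met <- classification_metrics(truth_all, pred_all, levels_)
  cm_norm <- met$confusion / pmax(rowSums(met$confusion), 1L)
  structure(list(
    classifier = spec$name,
    fold_accuracy = fold_acc,
    accuracy = met$accuracy,
    precision_macro = met$precision_macro,
    sensitivity_macro = met$sensitivity_macro,
    precision_weighted = met$precision_weighted,
    sensitivity_weighted = met$sensitivity_weighted,
    confusion = as.matrix(cm_norm),
    confusion_counts = as.matrix(met$confusion),
    selected_features = selected,
    smote_digest = smote_digest,
    n_selected = n_selected, n_folds = n_folds, seed = seed,
    classes = levels_),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s, %d-fold, %d features: accuracy %.1f%% (sd %.3f), precision %.1f%%, sensitivity %.1f%%\n",
              x$classifier, x$n_folds, x$n_selected, 100 * x$accuracy,
              stats::sd(x$fold_accuracy), 100 * x$precision_macro,
              100 * x$sensitivity_macro))
  invisible(x)
}

#' Paired comparison of two classifiers
#'
#' Paired t-test on matched accuracy vectors (same folds and feature counts)
#' with a 95% confidence interval of the mean difference and Bonferroni
#' adjustment over `n_comparisons` tests. Improvement is reported in
#' percentage points (`a` minus `b`).
#'
#' @param acc_a,acc_b Equal-length paired accuracy vectors (fractions).
#' @param n_comparisons Bonferroni multiplier m; adjusted p = min(1, m p).
#' @param label Comparison label carried into the result.
#' @return A `comparison_result` list: improvement, conf_int, p_value,
#'   p_adjusted, t, df, degenerate flag.
#' @export
compare_classifiers <- function(acc_a, acc_b, n_comparisons = 6L,
                                label = "A versus B") {
  if (length(acc_a) != length(acc_b))
    stopf("paired accuracy vectors differ in length")
  d <- (acc_a - acc_b) * 100
  if (stats::sd(d) == 0) {
    improvement <- mean(d)
    return(structure(list(label = label, improvement = improvement,
                          conf_int = c(improvement, improvement),
                          t = if (improvement == 0) 0 else Inf,
                          df = length(d) - 1L,
                          p_value = if (improvement == 0) 1 else 0,
                          p_adjusted = if (improvement == 0) 1 else 0,
                          degenerate = TRUE),
                     class = "comparison_result"))
  }
  tt <- stats::t.test(d)
  structure(list(label = label, improvement = mean(d),
                 conf_int = as.numeric(tt$conf.int),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 p_adjusted = min(1, n_comparisons * tt$p.value),
                 degenerate = FALSE),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison> %s: improvement %.2f%% (CI %.2f-%.2f%%), p = %.3g (adj %.3g)\n",
              x$label, x$improvement, x$conf_int[1L], x$conf_int[2L],
              x$p_value, x$p_adjusted))
  invisible(x)
}

#' Accuracy as a function of selected feature count
#'
#' Runs [cross_validate()] over a grid of `n_selected` values for each
#' classifier spec and tabulates mean fold accuracy with its standard error.
#'
#' @param features Feature table.
#' @param specs List of [classifier_spec()] objects.
#' @param grid Integer vector of feature counts (subset of 1..60).
#' @param n_folds,seed,hand Passed to [cross_validate()].
#' @return data.frame: classifier, n_selected, accuracy, se, plus a
#'   `fold_accuracy` list-column for paired testing.
#' @export
accuracy_vs_nfeatures <- function(features, specs, grid = c(5, 15, 30, 60),
                                  n_folds = 10L, seed = 1L, hand = NULL) {
  rows <- list()
  for (spec in specs) {
    for (n_sel in grid) {
      rep_ <- cross_validate(features, spec, n_selected = n_sel,
                             n_folds = n_folds, seed = seed, hand = hand)
      rows[[length(rows) + 1L]] <- data.frame(
        classifier = spec$name, n_selected = n_sel,
        accuracy = mean(rep_$fold_accuracy),
        se = stats::sd(rep_$fold_accuracy) / sqrt(length(rep_$fold_accuracy)),
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$fold_accuracy <- list(rep_$fold_accuracy)
    }
  }
  do.call(rbind, rows)
}
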