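#' Community-detection configuration
#'
#' Parameters of multilayer modularity optimization and consensus
#' clustering. The multilayer quality function couples the per-layer
#' Newman–Girvan modularity (resolution `gamma`) through inter-layer links of
#' strength `omega` between copies of the same node; `categorical` topology
#' couples every pair of layers, `ordinal` only consecutive ones.
#'
#' @param gamma Resolution parameter (> 0) of the per-layer null model.
#' @param omega Inter-layer coupling strength (>= 0).
#' @param topology `"categorical"` (all layer pairs) or `"ordinal"`
#'   (consecutive layers).
#' @param repetitions Number of seeded optimization restarts feeding the
#'   consensus stage.
#' @param consensus_max_iter Iteration cap of the consensus algorithm.
#' @param null_permutations Node-permutation surrogates used to derive the
#'   consensus co-assignment threshold.
#' @param seed Master seed; restart `r` uses a counter-derived sub-seed.
#' @return A `community_config` list.
#' @export
community_config <- function(gamma = 1, omega = 1,
                             topology = c("categorical", "ordinal"),
                             repetitions = 100L, consensus_max_iter = 20L,
                             null_permutations = 20L, seed = 1L) {
  topology <- match.arg(topology)
  if (gamma <= 0) stopf("gamma must be > 0")
  if (omega < 0) stopf("omega must be >= 0")
  if (repetitions < 1L) stopf("repetitions must be >= 1")
  structure(list(gamma = gamma, omega = omega, topology = topology,
                 repetitions = as.integer(repetitions),
                 consensus_max_iter = as.integer(consensus_max_iter),
                 null_permutations = as.integer(null_permutations),
                 seed = as.integer(seed)),
            class = "community_config")
}

#' Partition matrix
#'
#' N x T integer community assignments (node i, layer r). Labels are
#' canonicalized to be contiguous from 1 in order of first appearance
#' (column-major), making partitions comparable across runs.
#'
#' @param assignments Integer N x T matrix.
#' @return A `partition_matrix`.
#' @export
partition_matrix <- function(assignments) {
  assignments <- as.matrix(assignments)
  if (anyNA(assignments)) stopf("every node must be assigned in every layer")
  v <- as.integer(factor(as.vector(assignments),
                         levels = unique(as.vector(assignments))))
  structure(matrix(v, nrow(assignments), ncol(assignments),
                   dimnames = dimnames(assignments)),
            class = "partition_matrix")
}

# ---- supra-modularity matrix -------------------------------------------

# Flatten an N x N x T stack into the (N T) x (N T) multilayer modularity
# matrix B: intra-layer blocks hold Gamma_l - gamma * k_l k_l' / (2 m_l)
# (self-loops removed first), inter-layer blocks omega * I for coupled layer
# pairs. Returns B and the normalization 2*mu (total intra-layer weight plus
# total coupling weight, both counted in ordered pairs).
supra_modularity_matrix <- function(tens, gamma = 1, omega = 1,
                                    topology = "categorical") {
  if (is.matrix(tens)) tens <- array(tens, c(nrow(tens), ncol(tens), 1L))
  N <- dim(tens)[1L]; T_ <- dim(tens)[3L]
  B <- matrix(0, N * T_, N * T_)
  twomu <- 0
  for (l in seq_len(T_)) {
    A <- tens[, , l]
    diag(A) <- 0
    k <- rowSums(A)
    twom <- sum(k)
    block <- if (twom > 0) A - gamma * tcrossprod(k) / twom else A
    idx <- ((l - 1L) * N + 1L):(l * N)
    B[idx, idx] <- block
    twomu <- twomu + twom
  }
  if (T_ > 1L && omega > 0) {
    pairs <- if (topology == "categorical") {
      t(utils::combn(T_, 2L))
    } else {
      cbind(seq_len(T_ - 1L), 2L:T_)
    }
    for (p in seq_len(nrow(pairs))) {
      i1 <- (pairs[p, 1L] - 1L) * N; i2 <- (pairs[p, 2L] - 1L) * N
      d <- cbind(i1 + seq_len(N), i2 + seq_len(N))
      B[d] <- B[d] + omega
      B[d[, c(2L, 1L)]] <- B[d[, c(2L, 1L)]] + omega
    }
    twomu <- twomu + 2 * omega * N * nrow(pairs)
  }
  list(B = B, twomu = twomu, N = N, T_ = T_)
}

#' Multilayer modularity of a partition
#'
#' Scores a partition against the multilayer quality function
#' `Q = (1/2mu) * sum_{ijlr} [ (Gamma_ijl - gamma k_il k_jl / (2 m_l)) d_lr
#' + d_ij omega_lr ] d(g_il, g_jr)`, with a Newman–Girvan null per layer
#' (strengths `k`, total weight `m`) and inter-layer coupling per the
#' configured topology. Reduces to standard Newman–Girvan modularity for a
#' single layer.
#'
#' @param tens An `adjacency_tensor`, N x N x T array, or N x N matrix
#'   (single layer).
#' @param partition A [partition_matrix()] (or N x T matrix) matching the
#'   tensor dimensions.
#' @param config A [community_config()].
#' @return Scalar modularity Q.
#' @export
multilayer_modularity <- function(tens, partition,
                                  config = community_config()) {
  sup <- supra_modularity_matrix(tens, config$gamma, config$omega,
                                 config$topology)
  partition <- as.matrix(partition)
  if (nrow(partition) != sup$N || ncol(partition) != sup$T_)
    stopf("partition is %d x %d but tensor needs %d x %d",
          nrow(partition), ncol(partition), sup$N, sup$T_)
  comm <- as.vector(partition)
  same <- outer(comm, comm, "==")
  sum(sup$B[same]) / sup$twomu
}

# ---- greedy (Louvain-like) optimization --------------------------------

# One local-move phase on a (possibly aggregated) modularity matrix: nodes
# are swept in random order and moved to the community with the largest
# positive gain until no move improves. Ties favour the current community.
louvain_one_level <- function(B, comm) {
  n <- nrow(B)
  repeat {
    moved <- FALSE
    for (u in sample.int(n)) {
      w <- B[u, ]
      links <- rowsum(w, comm)           # ordered by sorted community id
      ids <- as.integer(rownames(links))
      own <- match(comm[u], ids)
      links[own] <- links[own] - B[u, u] # exclude self-weight from own comm
      best <- which.max(links)
      if (links[best] > links[own] + 1e-12 && ids[best] != comm[u]) {
        comm[u] <- ids[best]
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  comm
}

# Full greedy optimization of sum_{same community} B[u,v]: local moves,
# then aggregation of communities into super-nodes, repeated until the
# partition stabilizes.
louvain_on_matrix <- function(B) {
  n <- nrow(B)
  membership <- seq_len(n)           # community of each original node
  repeat {
    comm0 <- seq_len(nrow(B))
    comm <- louvain_one_level(B, comm0)
    ids <- sort(unique(comm))
    if (length(ids) == nrow(B)) break          # no merge happened
    relabel <- match(comm, ids)
    membership <- relabel[membership]
    B <- as.matrix(rowsum(t(rowsum(B, relabel)), relabel))
    if (nrow(B) == 1L) break
  }
  membership
}

#' Multilayer Louvain-like community detection
#'
#' Greedy optimization of the multilayer modularity (see
#' [multilayer_modularity()]) over the supra-adjacency representation: every
#' (node, layer) copy is a vertex, intra-layer blocks carry the
#' Newman–Girvan-corrected weights and inter-layer links carry `omega`.
#' Node sweep order is randomized from `seed`; a given seed is fully
#' reproducible. With `omega = 0` layers are optimized independently.
#'
#' @inheritParams multilayer_modularity
#' @param seed Integer seed for the sweep order.
#' @return A [partition_matrix()] with attributes `Q` (achieved modularity)
#'   and `config`.
#' @export
louvain_multilayer <- function(tens, config = community_config(),
                               seed = config$seed) {
  if (config$omega == 0 && !is.matrix(tens) && dim(tens)[3L] > 1L) {
    # decoupled layers: optimize each independently with the same seed,
    # exactly reproducing single-layer runs
    cols <- lapply(seq_len(dim(tens)[3L]), function(l) {
      sup_l <- supra_modularity_matrix(tens[, , l], config$gamma, 0)
      withr::with_seed(as.integer(seed), louvain_on_matrix(sup_l$B))
    })
    part <- partition_matrix(do.call(cbind, cols))
    attr(part, "Q") <- multilayer_modularity(tens, part, config)
    attr(part, "config") <- config
    return(part)
  }
  sup <- supra_modularity_matrix(tens, config$gamma, config$omega,
                                 config$topology)
  membership <- withr::with_seed(as.integer(seed),
                                 louvain_on_matrix(sup$B))
  part <- partition_matrix(matrix(membership, sup$N, sup$T_))
  attr(part, "Q") <- multilayer_modularity(
    tens, part, config)
  attr(part, "config") <- config
  part
}

#' Repeated seeded optimization runs
#'
#' Runs [louvain_multilayer()] `config$repetitions` times with
#' counter-derived sub-seeds of `config$seed`; the near-degenerate modularity
#' landscape makes single runs unstable, and the run ensemble feeds
#' [consensus_partition()] and [module_allegiance()].
#'
#' @inheritParams multilayer_modularity
#' @return List of [partition_matrix()] objects.
#' @export
louvain_ensemble <- function(tens, config = community_config()) {
  lapply(seq_len(config$repetitions), function(r)
    louvain_multilayer(tens, config, seed = derive_seed(config$seed, r)))
}

# Co-assignment (agreement) matrix of one layer across runs.
coassignment <- function(partitions, layer) {
  N <- nrow(partitions[[1L]])
  P <- matrix(0, N, N)
  for (p in partitions) {
    lab <- p[, layer]
    P <- P + outer(lab, lab, "==")
  }
  P / length(partitions)
}

#' Consensus partition over optimization runs
#'
#' For each layer: the across-run co-assignment matrix is computed,
#' entries below a permutation-null threshold (the maximum co-assignment
#' observed among node-permuted surrogate runs) are zeroed, and the
#' thresholded agreement matrix is re-clustered by modularity optimization.
#' This repeats until all re-clustering restarts agree or
#' `consensus_max_iter` is reached (then the last iterate is returned with a
#' `converged = FALSE` attribute).
#'
#' @param partitions List of [partition_matrix()] objects of identical shape.
#' @param config A [community_config()].
#' @return Representative [partition_matrix()] with attribute `converged`.
#' @export
consensus_partition <- function(partitions, config = community_config()) {
  stopifnot(length(partitions) >= 1L)
  shp <- dim(partitions[[1L]])
  if (!all(vapply(partitions, function(p) identical(dim(p), shp), TRUE)))
    stopf("partitions must share one shape")
  N <- shp[1L]; T_ <- shp[2L]
  n_restart <- min(10L, config$repetitions)
  out <- matrix(0L, N, T_)
  converged <- TRUE
  for (r in seq_len(T_)) {
    runs <- partitions
    iter <- 0L
    repeat {
      iter <- iter + 1L
      D <- coassignment(runs, if (iter == 1L) r else 1L)
      thr <- coassignment_null_threshold(runs, if (iter == 1L) r else 1L,
                                         config)
      Dt <- D
      Dt[Dt < thr] <- 0
      diag(Dt) <- 0
      if (all(Dt == 0)) {            # fully fragmented: keep majority labels
        out[, r] <- apply(vapply(runs, function(p)
          p[, if (iter == 1L) r else 1L], integer(N)), 1L,
          function(x) as.integer(names(which.max(table(x)))))
        break
      }
      sup <- supra_modularity_matrix(Dt, gamma = config$gamma, omega = 0)
      reclustered <- lapply(seq_len(n_restart), function(b)
        partition_matrix(matrix(withr::with_seed(
          derive_seed(config$seed, 1000L * r + 31L * iter + b),
          louvain_on_matrix(sup$B)), N, 1L)))
      agree <- all(vapply(reclustered[-1L], function(p)
        identical(unclass(p), unclass(reclustered[[1L]])), TRUE))
      if (agree) {
        out[, r] <- reclustered[[1L]][, 1L]
        break
      }
      if (iter >= config$consensus_max_iter) {
        warning("consensus did not converge; returning last iterate")
        converged <- FALSE
        out[, r] <- reclustered[[1L]][, 1L]
        break
      }
      runs <- reclustered
    }
  }
  res <- partition_matrix(out)
  attr(res, "converged") <- converged
  res
}

# Null threshold: maximum co-assignment entry among surrogate run sets in
# which each run's node labels are randomly permuted across nodes
# (community sizes preserved, structure destroyed).
coassignment_null_threshold <- function(partitions, layer, config) {
  N <- nrow(partitions[[1L]])
  withr::with_seed(derive_seed(config$seed, 777L + layer), {
    vals <- vapply(seq_len(config$null_permutations), function(b) {
      P <- matrix(0, N, N)
      for (p in partitions) {
        lab <- p[sample.int(N), layer]
        P <- P + outer(lab, lab, "==")
      }
      P <- P / length(partitions)
      diag(P) <- 0
      max(P)
    }, 0)
    max(vals)
  })
}

#' Module-allegiance matrix
#'
#' `P_ij` = fraction of (run, layer) slices in which nodes i and j are
#' assigned to the same community. Pass a list of runs for run-and-layer
#' averaging (default use), a single partition for layer-only averaging, or
#' single-layer partitions for run-only averaging.
#'
#' @param partitions A [partition_matrix()] or list of them (equal shapes).
#' @return N x N symmetric `module_allegiance` matrix, unit diagonal,
#'   entries in \[0, 1\].
#' @export
module_allegiance <- function(partitions) {
  if (inherits(partitions, "partition_matrix")) partitions <- list(partitions)
  stopifnot(length(partitions) >= 1L)
  shp <- dim(partitions[[1L]])
  if (!all(vapply(partitions, function(p) identical(dim(p), shp), TRUE)))
    stopf("partitions must share one shape")
  N <- shp[1L]
  P <- matrix(0, N, N)
  n_slices <- 0L
  for (p in partitions) {
    for (r in seq_len(ncol(p))) {
      lab <- p[, r]
      P <- P + outer(lab, lab, "==")
      n_slices <- n_slices + 1L
    }
  }
  P <- P / n_slices
  diag(P) <- 1
  structure(P, class = "module_allegiance")
}
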