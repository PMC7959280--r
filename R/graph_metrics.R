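# Weighted-graph communication metrics on a single connectivity layer.
# All functions take an N x N symmetric non-negative weight matrix; the
# diagonal is ignored (self-loops removed). Path-based metrics use the
# connection-length transform L_ij = 1/w_ij for nonzero weights.

layer_graph <- function(W) {
  diag(W) <- 0
  igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Node strength
#'
#' Total communication weight of each node: `s_i = sum_{j != i} w_ij`.
#'
#' @param W N x N symmetric weight matrix (one layer).
#' @return Numeric vector of strengths.
#' @export
node_strength <- function(W) {
  diag(W) <- 0
  rowSums(W)
}

#' Search information between node pairs
#'
#' The information (bits) a random walker needs to follow the shortest path
#' from i to j: `SI(i -> j) = -log2( sum over shortest paths of
#' prod_{(u -> v)} w_uv / s_u )`, with shortest paths taken under the length
#' transform `L = 1/w`. When several shortest paths tie, their probability
#' masses add (the degenerate-tie generalization of the single-path formula).
#' Unreachable pairs give `Inf`.
#'
#' @param W N x N symmetric weight matrix.
#' @param pairs 2-column integer matrix of ordered (from, to) pairs; default
#'   all ordered pairs.
#' @return Numeric vector of SI values (bits), one per row of `pairs`.
#' @export
search_information <- function(W, pairs = NULL) {
  diag(W) <- 0
  n <- nrow(W)
  if (is.null(pairs)) {
    pairs <- as.matrix(expand.grid(from = seq_len(n), to = seq_len(n)))
    pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  }
  g <- layer_graph(W)
  len <- 1 / igraph::E(g)$weight
  s <- node_strength(W)
  out <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    if (i == j) stopf("search information requires i != j")
    sp <- suppressWarnings(
      igraph::all_shortest_paths(g, from = i, to = j, weights = len))
    if (!length(sp$vpaths)) {
      out[k] <- Inf
      next
    }
    mass <- sum(vapply(sp$vpaths, function(v) {
      v <- as.integer(v)
      prod(W[cbind(v[-length(v)], v[-1L])] / s[v[-length(v)]])
    }, 0))
    out[k] <- -log2(mass)
  }
  out
}

#' Mean first passage times of the network random walk
#'
#' Expected number of steps for a random walker (transition probabilities
#' `p_uv = w_uv / s_u`) starting at i to first reach j, computed per
#' connected component from the fundamental matrix
#' `Z = (I - P + 1 pi')^{-1}` as `MFPT(i,j) = (Z_jj - Z_ij) / pi_j`.
#' Pairs in different components (or involving isolated nodes) are `Inf`.
#'
#' @param W N x N symmetric weight matrix.
#' @return N x N matrix of MFPTs (0 on the diagonal).
#' @export
mean_first_passage_time <- function(W) {
  diag(W) <- 0
  n <- nrow(W)
  M <- matrix(Inf, n, n)
  diag(M) <- 0
  comp <- igraph::components(layer_graph(W))$membership
  for (c_id in unique(comp)) {
    idx <- which(comp == c_id)
    if (length(idx) < 2L) next
    Wc <- W[idx, idx, drop = FALSE]
    s <- rowSums(Wc)
    P <- Wc / s
    pi_ <- s / sum(s)
    Z <- solve(diag(length(idx)) - P + matrix(pi_, length(idx),
                                              length(idx), byrow = TRUE))
    mf <- (matrix(diag(Z), length(idx), length(idx), byrow = TRUE) - Z) /
      matrix(pi_, length(idx), length(idx), byrow = TRUE)
    diag(mf) <- 0
    M[idx, idx] <- mf
  }
  M
}

#' Diffusion efficiency
#'
#' Inverse mean first passage time, `E_diff(i,j) = 1 / MFPT(i,j)`, with the
#' convention `1/Inf = 0` for unreachable pairs.
#'
#' @inheritParams mean_first_passage_time
#' @return N x N matrix (0 on the diagonal and for unreachable pairs).
#' @export
diffusion_efficiency <- function(W) {
  M <- mean_first_passage_time(W)
  E <- 1 / M
  E[!is.finite(E)] <- 0
  diag(E) <- 0
  E
}

#' Weighted transitivity
#'
#' Ratio of observed to maximum possible closed triplets, weighted with the
#' geometric-mean convention: with normalized weights `what = w / max(w)`,
#' `T = sum_i (R^3)_ii / sum_i k_i (k_i - 1)` where `R = what^(1/3)` and
#' `k_i` counts nonzero neighbours. Lies in \[0, 1\]; invariant to uniform
#' weight scaling.
#'
#' @param W N x N symmetric weight matrix, N >= 3.
#' @return Scalar transitivity.
#' @export
transitivity_weighted <- function(W) {
  diag(W) <- 0
  if (nrow(W) < 3L) stopf("transitivity needs at least 3 nodes")
  mx <- max(W)
  if (mx == 0) return(0)
  R <- (W / mx)^(1 / 3)
  numer <- sum(diag(R %*% R %*% R))
  k <- rowSums(W > 0)
  denom <- sum(k * (k - 1))
  if (denom == 0) return(0)
  numer / denom
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over ordered node pairs, with lengths
#' `L_ij = 1/w_ij`; unreachable pairs contribute 0.
#'
#' @param W N x N symmetric weight matrix, N >= 2.
#' @return Scalar efficiency (in \[0, 1\] for weights in \[0, 1\]).
#' @export
global_efficiency <- function(W) {
  diag(W) <- 0
  if (nrow(W) < 2L) stopf("global efficiency needs at least 2 nodes")
  g <- layer_graph(W)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (nrow(W) * (nrow(W) - 1))
}
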