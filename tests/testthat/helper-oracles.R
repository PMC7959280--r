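# Independent brute-force oracles. These re-derive every quantity from its
# definition with naive loops, never calling the package implementations.

# Welch magnitude-squared coherence via literal DFT transcription.
oracle_coherence <- function(X, fs, subseg, overlap, band_hz) {
  n <- ncol(X); nch <- nrow(X)
  step <- round(subseg * (1 - overlap))
  starts <- seq(1, n - subseg + 1, by = step)
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(subseg - 1)) / (subseg - 1))
  dft <- function(x) {    # naive DFT
    N <- length(x)
    vapply(0:(N - 1), function(k)
      sum(x * exp(-2i * pi * k * (0:(N - 1)) / N)), complex(1))
  }
  nfreq <- subseg %/% 2 + 1
  S <- array(0i, c(nch, nch, nfreq))
  for (s0 in starts) {
    Fm <- matrix(0i, nch, nfreq)
    for (c_ in 1:nch) {
      seg <- X[c_, s0:(s0 + subseg - 1)]
      seg <- (seg - mean(seg)) * hann
      Fm[c_, ] <- dft(seg)[1:nfreq]
    }
    for (i in 1:nch) for (j in 1:nch)
      S[i, j, ] <- S[i, j, ] + Fm[i, ] * Conj(Fm[j, ])
  }
  S <- S / length(starts)
  freqs <- (0:(nfreq - 1)) * fs / subseg
  in_band <- which(freqs >= band_hz[1] & freqs <= band_hz[2])
  C <- matrix(0, nch, nch)
  for (i in 1:nch) for (j in 1:nch) {
    vals <- vapply(in_band, function(f)
      Mod(S[i, j, f])^2 / (Re(S[i, i, f]) * Re(S[j, j, f])), 0)
    C[i, j] <- mean(vals)
  }
  diag(C) <- 1
  C
}

# Newman-Girvan modularity of a single-layer partition, direct double loop.
oracle_modularity_single <- function(A, comm, gamma = 1) {
  diag(A) <- 0
  k <- rowSums(A); twom <- sum(k)
  q <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(A)))
    if (comm[i] == comm[j]) q <- q + A[i, j] - gamma * k[i] * k[j] / twom
  q / twom
}

# Multilayer modularity, direct quadruple loop over the defining sum.
oracle_modularity_multi <- function(tens, part, gamma = 1, omega = 1,
                                    topology = "categorical") {
  N <- dim(tens)[1]; T_ <- dim(tens)[3]
  q <- 0; twomu <- 0
  for (l in 1:T_) {
    A <- tens[, , l]; diag(A) <- 0
    k <- rowSums(A); twom <- sum(k)
    twomu <- twomu + twom
    for (i in 1:N) for (j in 1:N)
      if (part[i, l] == part[j, l])
        q <- q + A[i, j] - gamma * k[i] * k[j] / twom
  }
  if (T_ > 1) {
    for (l in 1:T_) for (r in 1:T_) {
      if (l == r) next
      coupled <- if (topology == "categorical") TRUE else abs(l - r) == 1
      if (!coupled) next
      twomu <- twomu + N * omega
      for (i in 1:N) if (part[i, l] == part[i, r]) q <- q + omega
    }
  }
  q / twomu
}

# All set partitions of 1..n (restricted growth strings).
enumerate_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, m) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (v in 1:(m + 1)) rec(c(prefix, v), max(m, v))
  }
  rec(integer(0), 0L)
  out
}

# Exhaustive single-layer modularity maximum.
oracle_best_modularity <- function(A, gamma = 1) {
  parts <- enumerate_partitions(nrow(A))
  max(vapply(parts, function(p) oracle_modularity_single(A, p, gamma), 0))
}

oracle_flexibility <- function(A) {
  T_ <- ncol(A)
  vapply(seq_len(nrow(A)), function(i) {
    same <- 0
    for (r in 1:(T_ - 1)) if (A[i, r] == A[i, r + 1]) same <- same + 1
    1 - same / (T_ - 1)
  }, 0)
}

oracle_integration <- function(P, members, cortex_members) {
  outside <- setdiff(seq_len(nrow(P)), cortex_members)
  mean(vapply(members, function(i) mean(P[i, outside]), 0))
}

oracle_recruitment <- function(P, members) {
  mean(vapply(members, function(i)
    mean(P[i, setdiff(members, i)]), 0))
}

# All simple paths i -> j; SI from the probability mass of the shortest ones.
oracle_search_information <- function(W, i, j) {
  diag(W) <- 0
  n <- nrow(W)
  s <- rowSums(W)
  paths <- list()
  walk <- function(path, len) {
    u <- path[length(path)]
    if (u == j) {
      paths[[length(paths) + 1]] <<- list(path = path, len = len)
      return()
    }
    for (v in setdiff(which(W[u, ] > 0), path))
      walk(c(path, v), len + 1 / W[u, v])
  }
  walk(i, 0)
  if (!length(paths)) return(Inf)
  lens <- vapply(paths, function(p) p$len, 0)
  best <- which(abs(lens - min(lens)) < 1e-12)
  mass <- sum(vapply(paths[best], function(p) {
    v <- p$path
    prod(W[cbind(v[-length(v)], v[-1])] / s[v[-length(v)]])
  }, 0))
  -log2(mass)
}

# MFPT by solving the absorbing-chain system for one target.
oracle_mfpt <- function(W, target) {
  diag(W) <- 0
  n <- nrow(W)
  P <- W / rowSums(W)
  keep <- setdiff(seq_len(n), target)
  h <- solve(diag(n - 1) - P[keep, keep, drop = FALSE], rep(1, n - 1))
  out <- numeric(n)
  out[keep] <- h
  out
}

# Monte-Carlo random walk MFPT (vectorized over walkers).
mc_mfpt <- function(W, from, to, n_walk = 1e5, seed = 1) {
  diag(W) <- 0
  P <- W / rowSums(W)
  withr::with_seed(seed, {
    state <- rep(from, n_walk)
    steps <- rep(0L, n_walk)
    active <- rep(TRUE, n_walk)
    for (t in 1:10000) {
      if (!any(active)) break
      idx <- which(active)
      nxt <- vapply(state[idx], function(u)
        sample.int(nrow(W), 1, prob = P[u, ]), 0L)
      state[idx] <- nxt
      steps[idx] <- steps[idx] + 1L
      active[idx] <- nxt != to
    }
    mean(steps)
  })
}

oracle_transitivity <- function(W) {
  diag(W) <- 0
  what <- W / max(W)
  n <- nrow(W)
  num <- 0
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    if (i != j && j != k && k != i)
      num <- num + (what[i, j] * what[j, k] * what[k, i])^(1 / 3)
  deg <- rowSums(W > 0)
  num / sum(deg * (deg - 1))
}

# All-pairs shortest paths by Floyd-Warshall on L = 1/w.
oracle_global_efficiency <- function(W) {
  diag(W) <- 0
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  D[W > 0] <- 1 / W[W > 0]
  diag(D) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_distance_matrix <- function(W) {
  diag(W) <- 0
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  D[W > 0] <- 1 / W[W > 0]
  diag(D) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# Random symmetric weighted graph with guaranteed connectivity.
random_weighted_graph <- function(n, density = 0.6, seed = 1) {
  withr::with_seed(seed, {
    W <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (stats::runif(1) < density) W[i, j] <- W[j, i] <- stats::runif(1, 0.1, 1)
    # ring to keep it connected
    for (i in 1:n) {
      j <- i %% n + 1
      if (W[i, j] == 0) W[i, j] <- W[j, i] <- stats::runif(1, 0.1, 1)
    }
    W
  })
}
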