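# Brute-force oracles, independent of the package implementations.

# all-pairs shortest paths by Floyd-Warshall on a length matrix
# (0 length = no edge)
oracle_floyd_warshall <- function(L) {
  N <- nrow(L)
  D <- ifelse(L > 0, L, Inf)
  diag(D) <- 0
  for (k in seq_len(N))
    for (i in seq_len(N))
      for (j in seq_len(N))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# binary clustering coefficient by enumerating all node triples
oracle_clustering_binary <- function(A) {
  N <- nrow(A)
  out <- numeric(N)
  for (i in seq_len(N)) {
    nb <- which(A[i, ] != 0)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (a in seq_len(k - 1))
      for (b in (a + 1):k)
        if (A[nb[a], nb[b]] != 0) tri <- tri + 1
    out[i] <- 2 * tri / (k * (k - 1))
  }
  out
}

# binary local efficiency straight from the definition: global efficiency
# (via the Floyd-Warshall oracle) of each node's induced neighbor subgraph
oracle_local_efficiency_binary <- function(A) {
  N <- nrow(A)
  out <- numeric(N)
  for (i in seq_len(N)) {
    nb <- which(A[i, ] != 0)
    if (length(nb) < 2) next
    sub <- A[nb, nb, drop = FALSE]
    D <- oracle_floyd_warshall(sub)
    inv <- 1 / D
    inv[!is.finite(inv)] <- 0
    diag(inv) <- 0
    n <- length(nb)
    out[i] <- sum(inv) / (n * (n - 1))
  }
  out
}

# matching index by explicit set arithmetic
oracle_matching_index <- function(A) {
  N <- nrow(A)
  M <- matrix(0, N, N)
  for (i in seq_len(N))
    for (j in seq_len(N)) {
      if (i == j) next
      gi <- setdiff(which(A[i, ] != 0), j)
      gj <- setdiff(which(A[j, ] != 0), i)
      denom <- length(gi) + length(gj)
      if (denom > 0)
        M[i, j] <- 2 * length(intersect(gi, gj)) / denom
    }
  M
}

# naive leave-one-out correlation stack
oracle_jackknife <- function(x) {
  T_ <- nrow(x); N <- ncol(x)
  stack <- array(0, c(N, N, T_))
  for (t in seq_len(T_)) {
    r <- stats::cor(x[-t, , drop = FALSE])
    diag(r) <- 1
    stack[, , t] <- r
  }
  stack
}

# random symmetric zero-diagonal weight matrix
random_weights <- function(N, density = 0.5, negative = FALSE) {
  W <- matrix(0, N, N)
  ut <- which(upper.tri(W))
  on <- sample(ut, round(density * length(ut)))
  W[on] <- if (negative) stats::runif(length(on), -1, 1)
           else stats::runif(length(on), 0.05, 1)
  W + t(W)
}

# reference two-state switching simulation shared across state-method tests
two_state_sim <- function(seed, n_regions = 5, n_timepoints = 2000,
                          persist = 0.98) {
  A <- matrix((1 - persist), 2, 2)
  diag(A) <- persist
  cov1 <- diag(n_regions)
  cov2 <- matrix(0.8, n_regions, n_regions) + 0.2 * diag(n_regions)
  simulate_state_switching(n_regions, n_timepoints, A,
                           list(cov1, cov2), seed = seed)
}
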