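#' Undirected weighted graph container
#'
#' Wraps an N x N symmetric weight matrix with zero diagonal. All metric
#' functions in the package operate on this class. Only undirected graphs
#' are supported.
#'
#' @param weights N x N numeric matrix; must be symmetric within 1e-10.
#'   The diagonal is zeroed.
#' @param binary Logical; declare the graph binary (entries then must be
#'   0/1). Auto-detected when missing.
#' @return An object of class `connectivity_graph`.
#' @export
connectivity_graph <- function(weights, binary = NULL) {
  W <- as.matrix(weights)
  if (nrow(W) != ncol(W)) stop("adjacency matrix must be square")
  if (!isSymmetric(unname(W), tol = 1e-10))
    stop("adjacency matrix must be symmetric (within 1e-10)")
  W <- (W + t(W)) / 2
  diag(W) <- 0
  isbin <- all(W %in% c(0, 1))
  if (is.null(binary)) binary <- isbin
  if (binary && !isbin) stop("binary = TRUE but weights are not all 0/1")
  structure(list(weights = W, directed = FALSE, binary = binary),
            class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  N <- nrow(x$weights)
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat("connectivity_graph:", N, "nodes,", ne, "edges,",
      if (x$binary) "binary" else "weighted", "\n")
  invisible(x)
}

as_graph <- function(g) {
  if (inherits(g, "connectivity_graph")) g else connectivity_graph(g)
}

#' Handle negative edge weights
#'
#' Negative connectivity values have no unique graph-theoretic
#' interpretation; choose absolute value, zeroing, or keeping them --
#' itself a classic forking path.
#'
#' @param g A [connectivity_graph] or matrix.
#' @param mode `"abs"`, `"zero"`, or `"keep"`.
#' @return A [connectivity_graph].
#' @export
handle_negative <- function(g, mode = c("abs", "zero", "keep")) {
  mode <- match.arg(mode)
  g <- as_graph(g)
  W <- switch(mode, abs = abs(g$weights),
              zero = pmax(g$weights, 0),
              keep = g$weights)
  connectivity_graph(W)
}

#' Proportional (density) thresholding
#'
#' Keeps the `ceiling(density * E)` largest-weight edges of the
#' `E = N(N-1)/2` possible undirected edges and zeroes the rest. Ties are
#' broken lexicographically by (row, column), making universes
#' deterministic.
#'
#' @param g A [connectivity_graph] with nonnegative weights (apply
#'   [handle_negative()] first).
#' @param density Fraction of possible edges to keep, in (0, 1].
#' @return A [connectivity_graph].
#' @export
threshold_density <- function(g, density) {
  g <- as_graph(g)
  if (any(g$weights < 0))
    stop("threshold_density needs nonnegative weights; ",
         "apply handle_negative() first")
  if (!is.numeric(density) || density <= 0 || density > 1)
    stop("density must lie in (0, 1]")
  N <- nrow(g$weights)
  ut <- which(upper.tri(g$weights))
  E <- length(ut)
  keep_n <- ceiling(density * E)
  w <- g$weights[ut]
  ri <- ((ut - 1L) %% N) + 1L
  ci <- ((ut - 1L) %/% N) + 1L
  ord <- order(-w, ri, ci)  # descending weight, ties by (i, j) lexicographic
  keep <- ut[ord[seq_len(keep_n)]]
  W <- matrix(0, N, N)
  W[keep] <- g$weights[keep]
  W <- W + t(W)
  connectivity_graph(W)
}

#' Binarize a graph
#'
#' @param g A [connectivity_graph] with nonnegative weights.
#' @return A binary [connectivity_graph] (nonzero -> 1).
#' @export
binarize <- function(g) {
  g <- as_graph(g)
  if (any(g$weights < 0)) stop("binarize needs nonnegative weights")
  connectivity_graph((g$weights != 0) * 1, binary = TRUE)
}

#' Node degree and strength
#'
#' @param g A [connectivity_graph].
#' @return List with `degree` (nonzero-neighbor counts) and `strength`
#'   (row sums of weights).
#' @export
degree_strength <- function(g) {
  g <- as_graph(g)
  list(degree = rowSums(g$weights != 0), strength = rowSums(g$weights))
}

#' Local clustering coefficient
#'
#' Binary graphs: fraction of a node's neighbor pairs that are themselves
#' connected. Weighted graphs: Onnela's variant, the mean geometric mean of
#' triangle weights normalized by the largest weight. Nodes with fewer than
#' two neighbors score 0.
#'
#' @param g A [connectivity_graph] with nonnegative weights.
#' @return Length-N vector in \[0, 1\].
#' @export
clustering_coefficient <- function(g) {
  g <- as_graph(g)
  W <- g$weights
  if (any(W < 0)) stop("clustering_coefficient needs nonnegative weights")
  k <- rowSums(W != 0)
  denom <- k * (k - 1)
  if (g$binary) {
    tri <- diag(W %*% W %*% W)
  } else {
    mx <- max(W)
    if (mx == 0) return(rep(0, nrow(W)))
    Wn <- (W / mx)^(1 / 3)
    tri <- diag(Wn %*% Wn %*% Wn)
  }
  out <- ifelse(denom > 0, tri / denom, 0)
  pmin(pmax(out, 0), 1)
}

#' All-pairs shortest path distances
#'
#' Edge lengths are the inverse weights `1/w` (1 for binary edges);
#' distances come from Dijkstra's algorithm per source. Disconnected pairs
#' are `Inf`; the diagonal is 0.
#'
#' @param g A [connectivity_graph] with nonnegative weights.
#' @return N x N distance matrix.
#' @export
shortest_paths_fc <- function(g) {
  g <- as_graph(g)
  W <- g$weights
  if (any(W < 0)) stop("shortest paths need nonnegative weights")
  L <- ifelse(W > 0, 1 / W, 0)
  ig <- igraph::graph_from_adjacency_matrix(L, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  D <- igraph::distances(ig, algorithm = "dijkstra")
  dimnames(D) <- NULL
  D
}

#' Characteristic path length
#'
#' Mean shortest-path distance over connected (finite) off-diagonal pairs;
#' the fraction of disconnected pairs is reported alongside.
#'
#' @param D Distance matrix from [shortest_paths_fc()].
#' @return List with `L` (mean finite distance) and
#'   `disconnected_fraction`.
#' @export
characteristic_path_length <- function(D) {
  off <- D[row(D) != col(D)]
  fin <- off[is.finite(off)]
  if (length(fin) == 0L) stop("all node pairs are disconnected")
  list(L = mean(fin), disconnected_fraction = mean(!is.finite(off)))
}

#' Global efficiency
#'
#' Mean inverse shortest-path distance over ordered node pairs;
#' disconnected pairs contribute 0. Lies in \[0, 1\] for binary graphs.
#'
#' @param g A [connectivity_graph], or a distance matrix from
#'   [shortest_paths_fc()].
#' @return Scalar efficiency.
#' @export
global_efficiency <- function(g) {
  D <- if (is.matrix(g)) g else shortest_paths_fc(g)
  N <- nrow(D)
  if (N < 2L) return(0)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (N * (N - 1))
}

#' Local efficiency
#'
#' Binary graphs: global efficiency of the subgraph induced by each node's
#' neighbors. Weighted graphs: the Rubinov-Sporns cube-root form, where
#' neighbor connection weights and inverse subgraph distances (computed on
#' cube-root-transformed lengths) enter via their geometric mean. Nodes
#' with fewer than two neighbors score 0.
#'
#' @param g A [connectivity_graph] with nonnegative weights.
#' @return Length-N vector.
#' @export
local_efficiency <- function(g) {
  g <- as_graph(g)
  W <- g$weights
  N <- nrow(W)
  out <- numeric(N)
  for (u in seq_len(N)) {
    nb <- which(W[u, ] != 0)
    if (length(nb) < 2L) next
    sub <- W[nb, nb, drop = FALSE]
    if (g$binary) {
      out[u] <- global_efficiency(connectivity_graph(sub, binary = TRUE))
    } else {
      # lengths on cube-root weights; inverse distances within the subgraph
      Lsub <- ifelse(sub > 0, 1 / sub^(1 / 3), 0)
      ig <- igraph::graph_from_adjacency_matrix(Lsub, mode = "undirected",
                                                weighted = TRUE,
                                                diag = FALSE)
      D <- igraph::distances(ig, algorithm = "dijkstra")
      e <- 1 / D
      e[!is.finite(e)] <- 0
      diag(e) <- 0
      sw <- W[u, nb]^(1 / 3)
      numer <- sum(outer(sw, sw) * e)
      k <- length(nb)
      out[u] <- numer / (k * (k - 1))
    }
  }
  out
}

#' Matching index
#'
#' Normalized overlap of two nodes' neighborhoods excluding their mutual
#' connection: `M_ij = 2 |G*(i) n G*(j)| / (|G*(i)| + |G*(j)|)` with
#' `G*(i) = neighbors(i) \\ {j}`. Defined for binary graphs; 0 where the
#' denominator vanishes.
#'
#' @param g A binary [connectivity_graph] (use [binarize()] first).
#' @return N x N symmetric matrix in \[0, 1\] with zero diagonal.
#' @export
matching_index <- function(g) {
  g <- as_graph(g)
  if (!g$binary) stop("matching_index requires a binary graph; binarize() first")
  A <- g$weights
  N <- nrow(A)
  M <- matrix(0, N, N)
  for (i in seq_len(N - 1L)) {
    for (j in (i + 1L):N) {
      gi <- A[i, ]; gj <- A[j, ]
      gi[j] <- 0; gj[i] <- 0
      inter <- sum(gi * gj)
      denom <- sum(gi) + sum(gj)
      if (denom > 0) M[i, j] <- M[j, i] <- 2 * inter / denom
    }
  }
  M
}

#' Newman modularity of a given partition
#'
#' `Q = (1/2m) sum_ij (W_ij - gamma s_i s_j / 2m) delta(c_i, c_j)` with
#' node strengths s and total weight 2m, at resolution gamma.
#'
#' @param g A [connectivity_graph] with nonnegative weights.
#' @param partition Integer community label per node.
#' @param gamma Resolution parameter (default 1).
#' @return Scalar Q.
#' @export
modularity_q <- function(g, partition, gamma = 1) {
  g <- as_graph(g)
  W <- g$weights
  if (any(W < 0)) stop("modularity needs nonnegative weights")
  N <- nrow(W)
  if (length(partition) != N) stop("partition must cover all nodes")
  two_m <- sum(W)
  if (two_m == 0) stop("graph has no edges (total weight 0)")
  s <- rowSums(W)
  same <- outer(partition, partition, "==")
  sum((W - gamma * outer(s, s) / two_m) * same) / two_m
}

#' Louvain community detection
#'
#' Seeded wrapper around igraph's Louvain implementation (local moving +
#' aggregation) at resolution gamma; the returned Q is recomputed with
#' [modularity_q()] on the returned partition, so the two always agree.
#'
#' @param g A [connectivity_graph] with nonnegative weights.
#' @param gamma Resolution parameter.
#' @param seed Integer seed (Louvain's sweep order is randomized).
#' @return List with `partition` (integer labels) and `Q`.
#' @export
louvain <- function(g, gamma = 1, seed = NULL) {
  g <- as_graph(g)
  W <- g$weights
  if (any(W < 0)) stop("louvain needs nonnegative weights")
  ig <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  part <- with_seed(seed, {
    cl <- igraph::cluster_louvain(ig, resolution = gamma)
    as.integer(igraph::membership(cl))
  })
  list(partition = part, Q = modularity_q(g, part, gamma = gamma))
}
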