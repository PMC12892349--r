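#' State-clustering result container
#'
#' @param labels Integer state labels in 1..K per labeled frame/window
#'   (NA marks frames excluded from labeling, e.g. subthreshold CAP
#'   frames).
#' @param centroids List of K state patterns (N x N matrices or length-N
#'   vectors, per method).
#' @param K Number of states.
#' @param time_index 1-based sample indices the labels refer to.
#' @param method Producing method name.
#' @return An object of class `state_result`.
#' @export
state_result <- function(labels, centroids, K, time_index, method) {
  K <- as.integer(K)
  lb <- labels[!is.na(labels)]
  if (length(lb) > 0 && (any(lb < 1L) || any(lb > K)))
    stop("labels must lie in 1..K")
  if (length(centroids) != K) stop("need exactly K centroids")
  structure(list(labels = as.integer(labels), centroids = centroids, K = K,
                 time_index = time_index, method = method),
            class = "state_result")
}

#' @export
print.state_result <- function(x, ...) {
  cat("state_result [", x$method, "]: K = ", x$K, ", ",
      length(x$labels), " frames labeled\n", sep = "")
  invisible(x)
}

# squared euclidean distance rows of x to rows of centers
dist2_to_centers <- function(x, centers) {
  outer(rowSums(x^2), rep(1, nrow(centers))) -
    2 * x %*% t(centers) +
    outer(rep(1, nrow(x)), rowSums(centers^2))
}

kmeanspp_centers <- function(x, K) {
  M <- nrow(x)
  idx <- integer(K)
  idx[1L] <- sample.int(M, 1L)
  if (K > 1L) {
    d2 <- rowSums(sweep(x, 2L, x[idx[1L], ])^2)
    for (k in 2:K) {
      p <- d2 / sum(d2)
      if (!all(is.finite(p)) || sum(d2) == 0)
        idx[k] <- sample.int(M, 1L)
      else
        idx[k] <- sample.int(M, 1L, prob = p)
      d2 <- pmin(d2, rowSums(sweep(x, 2L, x[idx[k], ])^2))
    }
  }
  x[idx, , drop = FALSE]
}

#' K-means with k-means++ initialization and restarts
#'
#' Shared clustering engine for all state-based methods: `n_init`
#' k-means++ initializations, Lloyd iterations via [stats::kmeans()], best
#' total within-cluster sum of squares kept. Deterministic per seed.
#'
#' @param features M x D numeric matrix (one row per object).
#' @param K Number of clusters (K <= M).
#' @param n_init Number of restarts.
#' @param seed Integer seed.
#' @return List with `labels` (1..K), `centroids` (K x D matrix),
#'   `inertia` (total within-cluster sum of squares).
#' @export
kmeans_fit <- function(features, K, n_init = 10, seed = NULL) {
  features <- as.matrix(features)
  M <- nrow(features)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (K > M) stop("K (", K, ") exceeds number of observations (", M, ")")
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_init)) {
      centers <- kmeanspp_centers(features, K)
      km <- suppressWarnings(stats::kmeans(features, centers = centers,
                                           iter.max = 100L,
                                           algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    list(labels = as.integer(best$cluster),
         centroids = unname(best$centers),
         inertia = best$tot.withinss)
  })
}

upper_tri_vec <- function(m) m[upper.tri(m)]

sym_from_upper <- function(v, N, diag_value = 1) {
  m <- matrix(0, N, N)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

#' Sliding-window clustering into connectivity states
#'
#' Sliding-window correlation matrices are vectorized (upper triangles) and
#' clustered with k-means; centroids are reshaped back into symmetric N x N
#' state matrices with unit diagonal.
#'
#' @param ts A [timeseries].
#' @param win A [window_spec].
#' @param K Number of states.
#' @param n_init K-means restarts.
#' @param seed Integer seed.
#' @return A [state_result] with one label per window.
#' @export
sliding_window_clustering <- function(ts, win, K, n_init = 10, seed = NULL) {
  cc <- sliding_window(ts, win)
  res <- states_from_continuous(cc, K, n_init = n_init, seed = seed)
  res$method <- "sliding_window_clustering"
  res
}

#' Cluster any time-resolved connectivity stack into states
#'
#' Vectorizes the upper triangle of every slice of a [dfc] and clusters the
#' slices with [kmeans_fit()], so every continuously varying method can
#' feed [state_summaries()].
#'
#' @param cc A [dfc].
#' @param K Number of states (K <= number of slices).
#' @param n_init K-means restarts.
#' @param seed Integer seed.
#' @return A [state_result]; centroids are symmetric N x N matrices with
#'   unit diagonal.
#' @export
states_from_continuous <- function(cc, K, n_init = 10, seed = NULL) {
  stopifnot(inherits(cc, "dfc"))
  d <- dim(cc$stack)
  N <- d[1L]; W <- d[3L]
  feats <- t(apply(cc$stack, 3L, upper_tri_vec))
  if (N == 2L) feats <- matrix(feats, nrow = W)
  fit <- kmeans_fit(feats, K, n_init = n_init, seed = seed)
  centroids <- lapply(seq_len(K), function(k)
    sym_from_upper(fit$centroids[k, ], N))
  state_result(fit$labels, centroids, K, time_index = cc$time_index,
               method = paste0("states_from_", cc$method))
}

#' Co-activation patterns (CAPs)
#'
#' Frames where the seed region's z-scored signal (or, with
#' `seed_region = "global"`, the mean absolute z across regions) exceeds
#' `threshold_z` are selected and their length-N activation vectors
#' clustered with k-means; the centroids are the co-activation patterns.
#' Labels are defined on selected frames only; all other frames are NA.
#'
#' @param ts A [timeseries].
#' @param seed_region Region index (1-based) or `"global"`.
#' @param threshold_z Selection threshold in z units (default 1).
#' @param K Number of patterns.
#' @param n_init K-means restarts.
#' @param seed Integer seed.
#' @return A [state_result] with length-N vector centroids; element
#'   `time_index` lists the selected frames.
#' @export
caps <- function(ts, seed_region = "global", threshold_z = 1, K = 2,
                 n_init = 10, seed = NULL) {
  ts <- as_timeseries(ts)
  z <- zscore0(ts$data)
  T_ <- nrow(z)
  score <- if (identical(seed_region, "global")) rowMeans(abs(z))
           else z[, seed_region]
  sel <- which(score > threshold_z)
  if (length(sel) < K)
    stop("only ", length(sel), " suprathreshold frames (threshold_z = ",
         threshold_z, "); need at least K = ", K)
  fit <- kmeans_fit(z[sel, , drop = FALSE], K, n_init = n_init, seed = seed)
  labels <- rep(NA_integer_, T_)
  labels[sel] <- fit$labels
  centroids <- lapply(seq_len(K), function(k) fit$centroids[k, ])
  res <- state_result(labels, centroids, K, time_index = seq_len(T_),
                      method = "caps")
  res$selected_frames <- sel
  res
}

#' LEiDA states: cluster leading eigenvectors
#'
#' K-means on the rows of an eigenvector series (see
#' [leida_eigenvectors()]); centroids are re-normalized to unit length with
#' the same majority-negative sign convention.
#'
#' @param ev T x N `eigenvector_series`.
#' @param K Number of states.
#' @param n_init K-means restarts.
#' @param seed Integer seed.
#' @return A [state_result] with unit-norm vector centroids.
#' @export
leida_states <- function(ev, K, n_init = 10, seed = NULL) {
  ev <- unclass(ev)
  if (nrow(ev) < K) stop("need at least K time points")
  fit <- kmeans_fit(ev, K, n_init = n_init, seed = seed)
  centroids <- lapply(seq_len(K), function(k)
    fix_eigvec_sign(fit$centroids[k, ]))
  state_result(fit$labels, centroids, K, time_index = seq_len(nrow(ev)),
               method = "leida")
}

#' Summary measures of a state time course
#'
#' Fractional occupancy (proportion of frames per state), mean dwell time
#' (average run length, in samples, or seconds when `tr` is given),
#' lag-1 transition probabilities (self-transitions included; rows of
#' states with no outgoing transition are set uniform and flagged), and the
#' number of label changes. NA labels (e.g. unselected CAP frames) are
#' dropped first.
#'
#' @param labels Integer labels in 1..K (NA allowed).
#' @param K Number of states.
#' @param tr Optional sampling interval; when given, dwell times are in
#'   seconds.
#' @return An object of class `state_summary`: list with
#'   `fractional_occupancy`, `mean_dwell`, `transition_probs`,
#'   `n_transitions`, `visited`, `uniform_rows`.
#' @export
state_summaries <- function(labels, K, tr = NULL) {
  if (inherits(labels, "state_result")) {
    if (is.null(tr)) tr <- NULL
    K <- labels$K
    labels <- labels$labels
  }
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0L) stop("no labeled frames")
  K <- as.integer(K)
  if (any(labels < 1L) || any(labels > K)) stop("labels must lie in 1..K")
  total <- length(labels)
  fo <- tabulate(labels, K) / total
  runs <- rle(labels)
  dwell <- vapply(seq_len(K), function(k) {
    rl <- runs$lengths[runs$values == k]
    if (length(rl) == 0L) 0 else mean(rl)
  }, 0)
  visited <- tabulate(labels, K) > 0L
  if (!is.null(tr)) dwell <- dwell * tr
  counts <- matrix(0, K, K)
  if (total > 1L)
    for (t in seq_len(total - 1L))
      counts[labels[t], labels[t + 1L]] <- counts[labels[t], labels[t + 1L]] + 1
  rs <- rowSums(counts)
  uniform_rows <- rs == 0
  P <- counts / ifelse(rs == 0, 1, rs)
  P[uniform_rows, ] <- 1 / K
  structure(list(fractional_occupancy = fo, mean_dwell = dwell,
                 transition_probs = P,
                 n_transitions = sum(diff(labels) != 0),
                 visited = visited, uniform_rows = uniform_rows),
            class = "state_summary")
}

#' @export
print.state_summary <- function(x, ...) {
  cat("state_summary: K =", length(x$fractional_occupancy), "\n")
  cat("  fractional occupancy:",
      paste(round(x$fractional_occupancy, 3), collapse = " "), "\n")
  cat("  mean dwell:", paste(round(x$mean_dwell, 3), collapse = " "), "\n")
  cat("  transitions:", x$n_transitions, "\n")
  invisible(x)
}

#' Match estimated states to reference states
#'
#' Finds the label permutation minimizing total centroid dissimilarity
#' (squared euclidean distance between flattened patterns) by exhaustive
#' assignment over permutations (states counts are small in practice).
#'
#' @param estimated,reference Lists of equal-shaped state patterns.
#' @return Integer permutation `p` such that estimated state k corresponds
#'   to reference state `p[k]`.
#' @export
match_states <- function(estimated, reference) {
  K <- length(estimated)
  if (length(reference) != K) stop("state counts differ")
  if (K > 8L) stop("exhaustive matching supported for K <= 8")
  cost <- matrix(0, K, K)
  for (a in seq_len(K))
    for (b in seq_len(K))
      cost[a, b] <- sum((as.numeric(estimated[[a]]) -
                           as.numeric(reference[[b]]))^2)
  perms <- permutations_of(K)
  scores <- vapply(perms, function(p)
    sum(cost[cbind(seq_len(K), p)]), 0)
  perms[[which.min(scores)]]
}

permutations_of <- function(K) {
  if (K == 1L) return(list(1L))
  sub <- permutations_of(K - 1L)
  out <- list()
  for (p in sub)
    for (pos in seq_len(K))
      out[[length(out) + 1L]] <- append(p, K, after = pos - 1L)
  out
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions (up to relabeling), ~0 for independent ones.
#' NA positions in either labeling are dropped pairwise.
#'
#' @param a,b Integer label vectors of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) != length(b)) stop("labelings must have equal length")
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
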