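#' Synthetic data with known ground truth
#'
#' Generators for (i) state-switching multivariate Gaussian time series
#' driven by a first-order Markov chain, (ii) phase-coupled sinusoidal
#' signals, and (iii) planted-partition modular graphs. Every estimator and
#' graph metric in the package can be validated against these without
#' external data. All randomness flows through the explicit `seed` argument;
#' the global RNG state is left untouched.
#'
#' @name synth
NULL

# run expr under a local RNG seeded with `seed`, restoring global state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# lower-triangular Cholesky with validation
chol_lower <- function(sigma, what = "covariance") {
  if (!isSymmetric(sigma, tol = 1e-10))
    stop(what, " matrix must be symmetric")
  ch <- tryCatch(chol(sigma), error = function(e)
    stop(what, " matrix is not positive definite"))
  t(ch)
}

#' Simulate a Markov state-switching Gaussian time series
#'
#' Hidden state labels follow a first-order Markov chain with the given
#' row-stochastic transition matrix (initial state uniform over states);
#' the observation at time t is drawn from a multivariate normal with the
#' active state's mean and covariance. This is the generative model assumed
#' by the Gaussian hidden Markov estimator and serves as ground truth for
#' all state-based methods.
#'
#' @param n_regions Number of regions N.
#' @param n_timepoints Number of time points T.
#' @param transition_matrix K x K row-stochastic matrix (rows sum to 1
#'   within 1e-12).
#' @param state_covariances List of K symmetric positive-definite N x N
#'   covariance matrices, one per state.
#' @param state_means Optional list of K length-N mean vectors; default all
#'   zero.
#' @param tr Sampling interval in seconds for the output series.
#' @param seed Integer seed; same seed reproduces the output exactly.
#' @return List with `ts` (a [timeseries]) and `labels` (length-T integer
#'   state indices in 1..K).
#' @examples
#' sim <- simulate_state_switching(3, 200,
#'   transition_matrix = matrix(c(.9, .1, .1, .9), 2, byrow = TRUE),
#'   state_covariances = list(diag(3), diag(3) * 2), seed = 1)
#' table(sim$labels)
#' @export
simulate_state_switching <- function(n_regions, n_timepoints,
                                     transition_matrix, state_covariances,
                                     state_means = NULL, tr = 1,
                                     seed = NULL) {
  A <- as.matrix(transition_matrix)
  K <- nrow(A)
  if (ncol(A) != K) stop("transition_matrix must be square")
  if (any(A < 0) || any(abs(rowSums(A) - 1) > 1e-12))
    stop("transition_matrix rows must be nonnegative and sum to 1")
  if (length(state_covariances) != K)
    stop("need one covariance per state (", K, ")")
  L <- lapply(state_covariances, function(s) {
    s <- as.matrix(s)
    if (nrow(s) != n_regions || ncol(s) != n_regions)
      stop("state covariances must be ", n_regions, " x ", n_regions)
    chol_lower(s)
  })
  if (is.null(state_means))
    state_means <- rep(list(numeric(n_regions)), K)
  if (length(state_means) != K) stop("need one mean vector per state")
  with_seed(seed, {
    labels <- integer(n_timepoints)
    labels[1L] <- sample.int(K, 1L)
    if (n_timepoints > 1L)
      for (t in 2:n_timepoints)
        labels[t] <- sample.int(K, 1L, prob = A[labels[t - 1L], ])
    x <- matrix(stats::rnorm(n_timepoints * n_regions), n_timepoints)
    out <- matrix(0, n_timepoints, n_regions)
    for (k in seq_len(K)) {
      idx <- which(labels == k)
      if (length(idx) > 0L)
        out[idx, ] <- x[idx, , drop = FALSE] %*% t(L[[k]]) +
          matrix(state_means[[k]], length(idx), n_regions, byrow = TRUE)
    }
    list(ts = timeseries(out, tr = tr), labels = labels)
  })
}

#' Simulate phase-coupled sinusoidal regions
#'
#' Region i is `sin(2 pi f t + lag_i) + noise`, sampled at interval `tr`.
#' Ground truth for phase synchronization and leading-eigenvector methods:
#' the instantaneous phase difference between regions i and j is
#' `lag_i - lag_j`.
#'
#' @param n_regions Number of regions N.
#' @param n_timepoints Number of time points T.
#' @param freq_hz Oscillation frequency in Hz; must be below Nyquist.
#' @param phase_lags Length-N vector of phase offsets in radians.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param tr Sampling interval in seconds.
#' @param seed Integer seed.
#' @return A [timeseries].
#' @export
simulate_phase_coupled <- function(n_regions, n_timepoints, freq_hz,
                                   phase_lags = numeric(n_regions),
                                   noise_sd = 0, tr = 1, seed = NULL) {
  if (freq_hz <= 0 || freq_hz >= 1 / (2 * tr))
    stop("freq_hz must lie in (0, Nyquist) = (0, ", 1 / (2 * tr), ") Hz")
  if (length(phase_lags) != n_regions)
    stop("phase_lags must have length n_regions")
  tt <- (seq_len(n_timepoints) - 1) * tr
  base <- outer(2 * pi * freq_hz * tt, phase_lags, "+")
  x <- sin(base)
  with_seed(seed, {
    if (noise_sd > 0)
      x <- x + matrix(stats::rnorm(length(x), sd = noise_sd), nrow(x))
    timeseries(x, tr = tr)
  })
}

#' Simulate a planted-partition modular graph
#'
#' Binary undirected graph on `n_nodes` nodes split into `n_modules`
#' near-equal modules; within-module edges appear with probability `p_in`,
#' between-module edges with `p_out < p_in`. Ground truth for modularity
#' and community detection.
#'
#' @param n_nodes Number of nodes.
#' @param n_modules Number of planted modules.
#' @param p_in Within-module edge probability.
#' @param p_out Between-module edge probability (strictly less than p_in).
#' @param seed Integer seed.
#' @return List with `graph` (a [connectivity_graph]) and `membership`
#'   (planted module index per node).
#' @export
simulate_modular_graph <- function(n_nodes, n_modules, p_in, p_out,
                                   seed = NULL) {
  if (!(p_out < p_in && p_in <= 1 && p_out >= 0))
    stop("need 0 <= p_out < p_in <= 1")
  membership <- sort(rep_len(seq_len(n_modules), n_nodes))
  with_seed(seed, {
    W <- matrix(0, n_nodes, n_nodes)
    for (i in seq_len(n_nodes - 1L)) {
      for (j in (i + 1L):n_nodes) {
        p <- if (membership[i] == membership[j]) p_in else p_out
        if (stats::runif(1) < p) W[i, j] <- W[j, i] <- 1
      }
    }
    list(graph = connectivity_graph(W, binary = TRUE),
         membership = membership)
  })
}
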