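#' Gaussian hidden Markov model parameters
#'
#' @param means K x N matrix of state means.
#' @param covariances List of K N x N covariance matrices (diagonal
#'   matrices for `cov_type = "diag"`).
#' @param transition K x K row-stochastic transition matrix.
#' @param initial Length-K initial state distribution.
#' @param cov_type `"diag"` or `"full"`.
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(means, covariances, transition, initial,
                       cov_type = "full") {
  means <- as.matrix(means)
  K <- nrow(means)
  transition <- as.matrix(transition)
  if (any(abs(rowSums(transition) - 1) > 1e-10))
    stop("transition rows must sum to 1")
  if (abs(sum(initial) - 1) > 1e-10) stop("initial must sum to 1")
  if (length(covariances) != K) stop("need one covariance per state")
  structure(list(means = means, covariances = covariances,
                 transition = transition, initial = initial,
                 cov_type = cov_type, K = K),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("hmm_params: K =", x$K, "states,", ncol(x$means), "regions,",
      x$cov_type, "covariance\n")
  invisible(x)
}

# T x K matrix of log N(x_t | mu_k, Sigma_k)
hmm_log_emissions <- function(x, means, covariances) {
  T_ <- nrow(x); K <- nrow(means); N <- ncol(x)
  logb <- matrix(0, T_, K)
  for (k in seq_len(K)) {
    S <- covariances[[k]]
    ch <- chol(S)
    logdet <- 2 * sum(log(diag(ch)))
    xc <- sweep(x, 2L, means[k, ])
    q <- rowSums((xc %*% chol2inv(ch)) * xc)
    logb[, k] <- -0.5 * (N * log(2 * pi) + logdet + q)
  }
  logb
}

# floor covariance eigenvalues / variances at eps to avoid collapse
regularize_cov <- function(S, cov_type, eps = 1e-6) {
  if (cov_type == "diag") {
    d <- pmax(diag(S), eps)
    diag(d, nrow = length(d))
  } else {
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    vals <- pmax(e$values, eps)
    e$vectors %*% (vals * t(e$vectors))
  }
}

#' Fit a Gaussian hidden Markov model (Baum-Welch EM)
#'
#' Expectation-maximization with scaled forward-backward recursions.
#' State means are initialized by k-means on the frames; the transition
#' matrix starts persistent (0.9 on the diagonal). Iteration stops at
#' `max_iter` or when the log-likelihood improves by less than `tol`.
#' Covariances whose eigenvalues fall below 1e-6 are floored there (a
#' warning is issued), preventing state collapse.
#'
#' @param ts A [timeseries] or T x N matrix of observations.
#' @param K Number of hidden states.
#' @param max_iter Maximum EM iterations.
#' @param tol Log-likelihood convergence threshold.
#' @param cov_type `"diag"` (default) or `"full"` emission covariances.
#' @param seed Integer seed (controls the k-means initialization).
#' @return List with `params` ([hmm_params]) and `log_likelihood`
#'   (per-iteration trace, non-decreasing up to numerical noise).
#' @export
hmm_fit <- function(ts, K, max_iter = 100, tol = 1e-4,
                    cov_type = c("diag", "full"), seed = NULL) {
  cov_type <- match.arg(cov_type)
  ts <- as_timeseries(ts)
  x <- ts$data
  T_ <- nrow(x); N <- ncol(x)
  K <- as.integer(K)
  if (T_ <= K) stop("need more time points than states")
  km <- kmeans_fit(x, K, n_init = 5, seed = seed)
  means <- km$centroids
  covariances <- lapply(seq_len(K), function(k) {
    idx <- which(km$labels == k)
    S <- if (length(idx) > 1L) {
      xc <- sweep(x[idx, , drop = FALSE], 2L, colMeans(x[idx, , drop = FALSE]))
      crossprod(xc) / length(idx)
    } else crossprod(sweep(x, 2L, colMeans(x))) / T_
    regularize_cov(S, cov_type)
  })
  A <- matrix(if (K > 1L) 0.1 / (K - 1L) else 0, K, K)
  diag(A) <- if (K > 1L) 0.9 else 1
  pi0 <- rep(1 / K, K)
  trace <- numeric(0)
  warned <- FALSE
  for (iter in seq_len(max_iter)) {
    logb <- hmm_log_emissions(x, means, covariances)
    shift <- apply(logb, 1L, max)
    b <- exp(logb - shift)
    # scaled forward
    alpha <- matrix(0, T_, K)
    cs <- numeric(T_)
    a1 <- pi0 * b[1L, ]
    cs[1L] <- sum(a1)
    alpha[1L, ] <- a1 / cs[1L]
    if (T_ > 1L) for (t in 2:T_) {
      at <- (alpha[t - 1L, ] %*% A) * b[t, ]
      cs[t] <- sum(at)
      alpha[t, ] <- at / cs[t]
    }
    ll <- sum(log(cs) + shift)
    trace <- c(trace, ll)
    # scaled backward
    beta <- matrix(0, T_, K)
    beta[T_, ] <- 1
    if (T_ > 1L) for (t in (T_ - 1L):1L)
      beta[t, ] <- (A %*% (b[t + 1L, ] * beta[t + 1L, ])) / cs[t + 1L]
    gamma <- alpha * beta
    gamma <- gamma / rowSums(gamma)
    # transition expectations
    xi_num <- matrix(0, K, K)
    if (T_ > 1L) for (t in seq_len(T_ - 1L)) {
      m <- outer(alpha[t, ], b[t + 1L, ] * beta[t + 1L, ]) * A / cs[t + 1L]
      xi_num <- xi_num + m
    }
    # M-step
    pi0 <- gamma[1L, ]
    if (K > 1L) {
      denom <- colSums(gamma[seq_len(T_ - 1L), , drop = FALSE])
      A <- xi_num / ifelse(denom == 0, 1, denom)
      zero <- rowSums(A) == 0
      A[zero, ] <- 1 / K
      A <- A / rowSums(A)
    }
    wsum <- colSums(gamma)
    means <- t(vapply(seq_len(K), function(k)
      colSums(x * gamma[, k]) / wsum[k], numeric(N)))
    for (k in seq_len(K)) {
      xc <- sweep(x, 2L, means[k, ])
      S <- crossprod(xc * gamma[, k], xc) / wsum[k]
      if (cov_type == "diag") S <- diag(pmax(diag(S), 0), N)
      mins <- min(eigen((S + t(S)) / 2, symmetric = TRUE,
                        only.values = TRUE)$values)
      if (mins < 1e-6) {
        if (!warned) {
          warning("covariance of state ", k,
                  " near-singular; eigenvalues floored at 1e-6")
          warned <- TRUE
        }
        S <- regularize_cov(S, cov_type)
      }
      covariances[[k]] <- S
    }
    if (iter > 1L && trace[iter] - trace[iter - 1L] < tol) break
  }
  list(params = hmm_params(means, covariances, A, pi0, cov_type),
       log_likelihood = trace)
}

#' Decode the most probable state path (Viterbi)
#'
#' @param params An [hmm_params] object.
#' @param ts A [timeseries] or T x N matrix; N must match the model.
#' @return Integer vector of length T with state labels in 1..K.
#' @export
hmm_decode <- function(params, ts) {
  stopifnot(inherits(params, "hmm_params"))
  ts <- as_timeseries(ts)
  x <- ts$data
  if (ncol(x) != ncol(params$means))
    stop("time series has ", ncol(x), " regions but the model expects ",
         ncol(params$means))
  T_ <- nrow(x); K <- params$K
  logb <- hmm_log_emissions(x, params$means, params$covariances)
  logA <- log(pmax(params$transition, 1e-300))
  delta <- matrix(-Inf, T_, K)
  psi <- matrix(0L, T_, K)
  delta[1L, ] <- log(pmax(params$initial, 1e-300)) + logb[1L, ]
  if (T_ > 1L) for (t in 2:T_) {
    for (k in seq_len(K)) {
      cand <- delta[t - 1L, ] + logA[, k]
      psi[t, k] <- which.max(cand)
      delta[t, k] <- cand[psi[t, k]] + logb[t, k]
    }
  }
  path <- integer(T_)
  path[T_] <- which.max(delta[T_, ])
  if (T_ > 1L) for (t in (T_ - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  path
}
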