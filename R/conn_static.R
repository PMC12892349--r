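#' Static functional connectivity: Pearson correlation
#'
#' One N x N correlation matrix for the whole recording, assuming
#' connectivity is constant over time.
#'
#' @param ts A [timeseries] or T x N matrix.
#' @return N x N symmetric matrix with unit diagonal, entries in \[-1, 1\].
#' @export
pearson_fc <- function(ts) {
  ts <- as_timeseries(ts)
  x <- ts$data
  s <- apply(x, 2L, stats::sd)
  if (any(s == 0))
    stop("region ", which(s == 0)[1L], " is constant; correlation undefined")
  r <- stats::cor(x)
  diag(r) <- 1
  label_matrix(r, ts$region_labels)
}

label_matrix <- function(m, labels) {
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

#' Static functional connectivity: partial correlation
#'
#' Partial correlation between each pair of regions conditioning on all
#' remaining regions, obtained from the (optionally shrinkage-regularized)
#' precision matrix P as `rho_ij = -P_ij / sqrt(P_ii P_jj)`. Shrinkage pulls
#' the sample covariance toward a scaled identity, `(1 - s) S + s mu I`
#' with `mu = mean(diag(S))`; `shrinkage = "auto"` picks s by a
#' Ledoit-Wolf-style estimate, useful when N approaches T.
#'
#' @param ts A [timeseries] or T x N matrix.
#' @param shrinkage Number in \[0, 1\] or `"auto"`.
#' @return N x N symmetric matrix; diagonal set to 1.
#' @export
partial_fc <- function(ts, shrinkage = 0) {
  ts <- as_timeseries(ts)
  x <- ts$data
  T_ <- nrow(x); N <- ncol(x)
  if (T_ <= 2) stop("partial correlation needs T > 2")
  S <- stats::cov(x)
  s <- if (identical(shrinkage, "auto")) ledoit_wolf_shrinkage(x, S)
       else shrinkage
  if (!is.numeric(s) || s < 0 || s > 1)
    stop("shrinkage must be in [0, 1] or \"auto\"")
  mu <- mean(diag(S))
  Ssh <- (1 - s) * S + s * mu * diag(N)
  P <- tryCatch(solve(Ssh), error = function(e)
    stop("covariance matrix is singular; increase shrinkage ",
         "(e.g. shrinkage = \"auto\")"))
  d <- sqrt(diag(P))
  rho <- -P / outer(d, d)
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  label_matrix(rho, ts$region_labels)
}

# Ledoit-Wolf style shrinkage intensity toward mu*I on centered data
ledoit_wolf_shrinkage <- function(x, S = stats::cov(x)) {
  T_ <- nrow(x); N <- ncol(x)
  xc <- sweep(x, 2L, colMeans(x))
  mu <- mean(diag(S))
  d2 <- sum((S - mu * diag(N))^2)
  b2 <- 0
  for (t in seq_len(T_)) {
    St <- tcrossprod(xc[t, ])
    b2 <- b2 + sum((St - S)^2)
  }
  b2 <- b2 / T_^2
  b2 <- min(b2, d2)
  if (d2 == 0) return(0)
  max(0, min(1, b2 / d2))
}

#' Static functional connectivity: mutual information
#'
#' Plug-in mutual information (in nats) from a joint histogram with
#' equal-frequency marginal bins. Ranks with ties broken by order of
#' appearance define the bins, so the estimate is invariant to strictly
#' monotone transforms of either signal. With B bins and T divisible by B,
#' a region paired with itself attains MI = log(B) exactly. Diagonal
#' entries hold the per-region binned entropy.
#'
#' @param ts A [timeseries] or T x N matrix.
#' @param n_bins Number of bins B >= 2, or `"auto"` = `ceiling(sqrt(T/5))`.
#' @return N x N symmetric nonnegative matrix in nats.
#' @export
mutual_information_fc <- function(ts, n_bins = "auto") {
  ts <- as_timeseries(ts)
  x <- ts$data
  T_ <- nrow(x); N <- ncol(x)
  B <- if (identical(n_bins, "auto")) max(2L, ceiling(sqrt(T_ / 5)))
       else as.integer(n_bins)
  if (B < 2L) stop("n_bins must be at least 2")
  if (T_ < B) stop("need at least as many time points as bins")
  # equal-frequency bin index per column via ranks
  bins <- apply(x, 2L, function(col)
    as.integer(floor((rank(col, ties.method = "first") - 1) * B / T_)) + 1L)
  ent <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log(p))
  }
  M <- matrix(0, N, N)
  H <- vapply(seq_len(N), function(i) ent(tabulate(bins[, i], B)), 0)
  for (i in seq_len(N)) {
    M[i, i] <- H[i]
    for (j in seq_len(N)) {
      if (j <= i) next
      joint <- tabulate((bins[, i] - 1L) * B + bins[, j], B * B)
      M[i, j] <- M[j, i] <- max(0, H[i] + H[j] - ent(joint))
    }
  }
  label_matrix(M, ts$region_labels)
}
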