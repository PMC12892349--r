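#' Sliding-window specification
#'
#' @param length Window length w in samples (2 <= w <= T).
#' @param step Step s in samples between consecutive window starts.
#' @param taper `"rect"` (uniform weights) or `"gaussian"`.
#' @param gaussian_sd Taper standard deviation sigma in samples (used iff
#'   `taper = "gaussian"`); weights are renormalized to sum 1.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(length, step = 1, taper = c("rect", "gaussian"),
                        gaussian_sd = NULL) {
  taper <- match.arg(taper)
  if (length < 2) stop("window length must be >= 2 samples")
  if (step < 1) stop("step must be >= 1 sample")
  if (taper == "gaussian" && (is.null(gaussian_sd) || gaussian_sd <= 0))
    stop("gaussian taper needs gaussian_sd > 0 (in samples)")
  structure(list(length = as.integer(length), step = as.integer(step),
                 taper = taper, gaussian_sd = gaussian_sd),
            class = "window_spec")
}

#' Time-resolved connectivity container
#'
#' An N x N x W array of connectivity slices with the 1-based sample index
#' each slice refers to (window centers for windowed methods, time points
#' otherwise), the producing method and its parameters.
#'
#' @param stack N x N x W numeric array.
#' @param time_index Strictly increasing numeric vector of length W.
#' @param method Method name.
#' @param params Named list of parameters used.
#' @return An object of class `dfc`.
#' @export
dfc <- function(stack, time_index, method, params = list()) {
  stopifnot(length(dim(stack)) == 3L, dim(stack)[1L] == dim(stack)[2L])
  W <- dim(stack)[3L]
  if (length(time_index) != W) stop("time_index length must equal W")
  if (W > 1L && any(diff(time_index) <= 0))
    stop("time_index must be strictly increasing")
  structure(list(stack = stack, time_index = time_index, method = method,
                 params = params), class = "dfc")
}

#' @export
print.dfc <- function(x, ...) {
  d <- dim(x$stack)
  cat("dfc [", x$method, "]: ", d[1], " x ", d[2], " regions, ",
      d[3], " slices\n", sep = "")
  invisible(x)
}

#' @export
dim.dfc <- function(x) dim(x$stack)

# weighted Pearson correlation of the rows in x with weights w (sum 1)
weighted_corr <- function(x, w) {
  mu <- colSums(x * w)
  xc <- sweep(x, 2L, mu)
  C <- crossprod(xc * sqrt(w))
  d <- sqrt(diag(C))
  r <- C / outer(d, d)
  r[!is.finite(r)] <- 0
  r <- (r + t(r)) / 2
  diag(r) <- 1
  pmin(pmax(r, -1), 1)
}

#' (Tapered) sliding-window correlation
#'
#' Pearson correlation within fully interior windows of length w moved in
#' steps of s, optionally weighted by a Gaussian taper. The number of
#' windows is `W = floor((T - w)/s) + 1`; slice k covers samples
#' `[(k-1) s + 1, (k-1) s + w]` and is stamped at the window center
#' `(k-1) s + (w + 1)/2` (1-based samples).
#'
#' @param ts A [timeseries] or T x N matrix.
#' @param win A [window_spec].
#' @return A [dfc] of W correlation slices.
#' @export
sliding_window <- function(ts, win) {
  ts <- as_timeseries(ts)
  x <- ts$data
  T_ <- nrow(x)
  w <- win$length; s <- win$step
  if (w > T_) stop("window length (", w, ") exceeds T (", T_, ")")
  W <- (T_ - w) %/% s + 1L
  wt <- if (win$taper == "gaussian") {
    g <- exp(-0.5 * ((seq_len(w) - (w + 1) / 2) / win$gaussian_sd)^2)
    g / sum(g)
  } else rep(1 / w, w)
  N <- ncol(x)
  stack <- array(0, c(N, N, W))
  for (k in seq_len(W)) {
    i0 <- (k - 1L) * s + 1L
    stack[, , k] <- weighted_corr(x[i0:(i0 + w - 1L), , drop = FALSE], wt)
  }
  dfc(stack, time_index = (seq_len(W) - 1L) * s + (w + 1) / 2,
      method = "sliding_window",
      params = list(length = w, step = s, taper = win$taper,
                    gaussian_sd = win$gaussian_sd))
}

#' Multiplication of temporal derivatives (MTD)
#'
#' First differences `dx_i(t) = x_i(t+1) - x_i(t)` are mean-centred per
#' region and scored pairwise as
#' `m_ij(t) = dx_i(t) dx_j(t) / (sd(dx_i) sd(dx_j))` (population sd), so the
#' temporal mean of the raw score equals the Pearson correlation of the two
#' difference series. A simple moving average over `smooth_w` points
#' (`smooth_w = 1` = raw) smooths the inherently noisy raw scores; only
#' fully interior averaging windows are kept, so `W = T - smooth_w`.
#'
#' @param ts A [timeseries] or T x N matrix.
#' @param smooth_w Moving-average width in samples (1 <= smooth_w <= T-1).
#' @return A [dfc]; slice t is stamped midway through its support.
#' @export
mtd <- function(ts, smooth_w = 1) {
  ts <- as_timeseries(ts)
  x <- ts$data
  T_ <- nrow(x); N <- ncol(x)
  if (T_ < 3) stop("mtd needs T >= 3")
  smooth_w <- as.integer(smooth_w)
  if (smooth_w < 1 || smooth_w > T_ - 1L)
    stop("smooth_w must be in [1, T-1]")
  dx <- diff(x)
  dx <- sweep(dx, 2L, colMeans(dx))
  s <- sqrt(colMeans(dx^2))
  if (any(s == 0)) stop("region ", which(s == 0)[1L],
                        " has constant differences")
  z <- sweep(dx, 2L, s, "/")
  Wraw <- T_ - 1L
  raw <- array(0, c(N, N, Wraw))
  for (t in seq_len(Wraw)) raw[, , t] <- tcrossprod(z[t, ])
  if (smooth_w == 1L) {
    out <- raw
    idx <- seq_len(Wraw) + 0.5
  } else {
    Wout <- Wraw - smooth_w + 1L
    out <- array(0, c(N, N, Wout))
    cum <- array(0, c(N, N))
    # moving average via running sums over slice index
    for (t in seq_len(Wraw)) {
      cum <- cum + raw[, , t]
      if (t >= smooth_w) {
        out[, , t - smooth_w + 1L] <- cum / smooth_w
        cum <- cum - raw[, , t - smooth_w + 1L]
      }
    }
    idx <- seq_len(Wout) + smooth_w / 2
  }
  dfc(out, time_index = idx, method = "mtd",
      params = list(smooth_w = smooth_w))
}

#' Jackknife correlation
#'
#' Slice t holds the Pearson correlation computed with sample t deleted
#' (`scaled = FALSE`), tracking each sample's influence on the correlation.
#' With `scaled = TRUE` each pair's leave-one-out series is z-scored across
#' t and sign-inverted, so samples whose removal lowers the correlation
#' score high; pairs whose leave-one-out series is constant yield zeros.
#'
#' @param ts A [timeseries] or T x N matrix.
#' @param scaled Logical; return the inverted z-scored series.
#' @return A [dfc] with W = T slices.
#' @export
jackknife_fc <- function(ts, scaled = FALSE) {
  ts <- as_timeseries(ts)
  x <- ts$data
  T_ <- nrow(x); N <- ncol(x)
  if (T_ < 3) stop("jackknife needs T >= 3")
  # leave-one-out moments from full-sample sums
  Sx <- colSums(x); Sxx <- colSums(x^2); Sxy <- crossprod(x)
  stack <- array(0, c(N, N, T_))
  for (t in seq_len(T_)) {
    n <- T_ - 1L
    sx <- Sx - x[t, ]
    sxx <- Sxx - x[t, ]^2
    sxy <- Sxy - tcrossprod(x[t, ])
    varx <- sxx / n - (sx / n)^2
    if (any(varx <= 1e-300))
      stop("region ", which(varx <= 1e-300)[1L],
           " becomes constant when deleting sample ", t)
    covm <- sxy / n - tcrossprod(sx / n)
    d <- sqrt(varx)
    r <- covm / outer(d, d)
    r <- pmin(pmax((r + t(r)) / 2, -1), 1)
    diag(r) <- 1
    stack[, , t] <- r
  }
  if (scaled) {
    for (i in seq_len(N)) {
      for (j in seq_len(N)) {
        v <- stack[i, j, ]
        sdv <- stats::sd(v)
        # a numerically constant leave-one-out series carries no signal
        stack[i, j, ] <- if (!is.finite(sdv) || sdv < 1e-10) rep(0, T_)
                         else -(v - mean(v)) / sdv
      }
    }
  }
  dfc(stack, time_index = seq_len(T_), method = "jackknife",
      params = list(scaled = scaled))
}

#' Edge time series (edge-centric connectivity)
#'
#' Per-time-point co-fluctuation `e_ij(t) = z_i(t) z_j(t)` on ddof = 0
#' z-scores. Its temporal mean reproduces the static Pearson correlation
#' exactly; the diagonal holds `z_i(t)^2`.
#'
#' @param ts A [timeseries] or T x N matrix.
#' @return A [dfc] with W = T slices.
#' @export
edge_timeseries <- function(ts) {
  ts <- as_timeseries(ts)
  z <- zscore0(ts$data)
  T_ <- nrow(z); N <- ncol(z)
  stack <- array(0, c(N, N, T_))
  for (t in seq_len(T_)) stack[, , t] <- tcrossprod(z[t, ])
  dfc(stack, time_index = seq_len(T_), method = "edge_timeseries")
}

#' Spatial-distance connectivity
#'
#' Instantaneous similarity from the distance between z-scored signals:
#' `d_ij(t) = |z_i(t) - z_j(t)|` mapped through `1/(1+d)` (reciprocal,
#' default) or `exp(-d)`. Values lie in (0, 1], diagonal = 1.
#'
#' @param ts A [timeseries] or T x N matrix.
#' @param kernel `"reciprocal"` or `"exp"`.
#' @return A [dfc] with W = T slices.
#' @export
spatial_distance_fc <- function(ts, kernel = c("reciprocal", "exp")) {
  kernel <- match.arg(kernel)
  ts <- as_timeseries(ts)
  z <- zscore0(ts$data)
  T_ <- nrow(z); N <- ncol(z)
  stack <- array(0, c(N, N, T_))
  for (t in seq_len(T_)) {
    d <- abs(outer(z[t, ], z[t, ], "-"))
    s <- if (kernel == "reciprocal") 1 / (1 + d) else exp(-d)
    diag(s) <- 1
    stack[, , t] <- s
  }
  dfc(stack, time_index = seq_len(T_), method = "spatial_distance",
      params = list(kernel = kernel))
}

# exact tridiagonal (Thomas) solve of (diag(a) + mu*L) b = rhs where L is
# the path-graph Laplacian; a = x^2, rhs = x*y
fls_solve_pair <- function(x, y, mu) {
  T_ <- length(x)
  diag_main <- x^2 + mu * c(1, rep(2, max(0, T_ - 2L)), if (T_ > 1L) 1)
  off <- rep(-mu, T_ - 1L)
  rhs <- x * y
  if (mu == 0 && any(x == 0))
    stop("flexible least squares with mu = 0 is singular when a ",
         "predictor value is 0")
  # Thomas algorithm
  cp <- numeric(T_ - 1L); dp <- numeric(T_)
  denom <- diag_main[1L]
  if (denom == 0) stop("singular flexible-least-squares system")
  if (T_ > 1L) cp[1L] <- off[1L] / denom
  dp[1L] <- rhs[1L] / denom
  if (T_ > 1L) {
    for (t in 2:T_) {
      denom <- diag_main[t] - off[t - 1L] * cp[t - 1L]
      if (denom == 0) stop("singular flexible-least-squares system")
      if (t < T_) cp[t] <- off[t] / denom
      dp[t] <- (rhs[t] - off[t - 1L] * dp[t - 1L]) / denom
    }
    for (t in (T_ - 1L):1L) dp[t] <- dp[t] - cp[t] * dp[t + 1L]
  }
  dp
}

#' Flexible least squares (time-varying regression coefficients)
#'
#' For each ordered region pair (i -> j) the coefficient path `beta_t`
#' minimizing `sum_t (x_j(t) - beta_t x_i(t))^2 +
#' mu sum_t (beta_(t+1) - beta_t)^2` is found exactly via the tridiagonal
#' normal equations. `mu = 0` gives the pointwise ratio, `mu -> Inf` the
#' (no-intercept) OLS slope. Slices are symmetrized by averaging the two
#' directed estimates unless `symmetrize = FALSE`.
#'
#' @param ts A [timeseries] or T x N matrix.
#' @param mu Smoothness penalty >= 0.
#' @param symmetrize Average beta(i->j) and beta(j->i) (default TRUE).
#' @return A [dfc] with W = T slices; diagonal = 1.
#' @export
flexible_least_squares <- function(ts, mu = 100, symmetrize = TRUE) {
  ts <- as_timeseries(ts)
  x <- ts$data
  T_ <- nrow(x); N <- ncol(x)
  if (mu < 0) stop("mu must be nonnegative")
  B <- array(0, c(N, N, T_))
  for (i in seq_len(N)) {
    B[i, i, ] <- 1
    for (j in seq_len(N)) {
      if (i == j) next
      B[i, j, ] <- fls_solve_pair(x[, i], x[, j], mu)
    }
  }
  if (symmetrize) {
    for (t in seq_len(T_)) B[, , t] <- (B[, , t] + t(B[, , t])) / 2
  }
  dfc(B, time_index = seq_len(T_), method = "flexible_least_squares",
      params = list(mu = mu, symmetrize = symmetrize))
}

# analytic signal via FFT (columnwise); returns complex matrix
analytic_signal <- function(x) {
  T_ <- nrow(x)
  h <- numeric(T_)
  if (T_ %% 2 == 0) {
    h[c(1L, T_ / 2 + 1L)] <- 1
    h[2:(T_ / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((T_ + 1L) / 2)] <- 2
  }
  X <- stats::mvfft(x) * h
  stats::mvfft(X, inverse = TRUE) / T_
}

instantaneous_phase <- function(ts, low_hz, high_hz) {
  filtered <- bandpass(ts, low_hz, high_hz)
  x <- sweep(filtered$data, 2L, colMeans(filtered$data))
  Arg(analytic_signal(x))
}

#' Instantaneous phase synchronization
#'
#' Columns are band-passed, the instantaneous phase `theta_i(t)` is taken
#' from the analytic signal, and the synchrony
#' `s_ij(t) = cos(theta_i(t) - theta_j(t))` is returned per time point.
#' The first and last 10% of samples are edge-affected by the filter and
#' Hilbert transform; their indices are listed in `params$edge_samples`.
#'
#' @param ts A [timeseries]; `tr` defines the sampling rate.
#' @param low_hz,high_hz Band edges in Hz.
#' @return A [dfc] with W = T slices; entries in \[-1, 1\], diagonal 1.
#' @export
phase_sync <- function(ts, low_hz, high_hz) {
  ts <- as_timeseries(ts)
  theta <- instantaneous_phase(ts, low_hz, high_hz)
  T_ <- nrow(theta); N <- ncol(theta)
  stack <- array(0, c(N, N, T_))
  for (t in seq_len(T_)) {
    s <- cos(outer(theta[t, ], theta[t, ], "-"))
    diag(s) <- 1
    stack[, , t] <- s
  }
  edge <- unique(c(seq_len(ceiling(T_ / 10)),
                   (T_ - ceiling(T_ / 10) + 1L):T_))
  dfc(stack, time_index = seq_len(T_), method = "phase_sync",
      params = list(low_hz = low_hz, high_hz = high_hz,
                    edge_samples = edge))
}

#' Leading eigenvector dynamics (LEiDA) eigenvector series
#'
#' Per time point the phase-coherence matrix
#' `C_ij(t) = cos(theta_i(t) - theta_j(t))` is built and its leading
#' eigenvector extracted, unit-norm, with the sign fixed so that the
#' majority of components are negative (ties: first component
#' non-positive). Cluster the rows with [leida_states()] to obtain
#' recurrent phase-locking states.
#'
#' @param ts A [timeseries].
#' @param low_hz,high_hz Band edges in Hz.
#' @return T x N matrix of leading eigenvectors (class
#'   `eigenvector_series`).
#' @export
leida_eigenvectors <- function(ts, low_hz, high_hz) {
  ts <- as_timeseries(ts)
  theta <- instantaneous_phase(ts, low_hz, high_hz)
  T_ <- nrow(theta); N <- ncol(theta)
  if (N < 2) stop("LEiDA needs at least 2 regions")
  V <- matrix(0, T_, N)
  for (t in seq_len(T_)) {
    C <- cos(outer(theta[t, ], theta[t, ], "-"))
    e <- eigen(C, symmetric = TRUE)
    v <- e$vectors[, 1L]
    V[t, ] <- fix_eigvec_sign(v)
  }
  structure(V, class = c("eigenvector_series", "matrix", "array"))
}

fix_eigvec_sign <- function(v) {
  neg <- sum(v < 0); pos <- sum(v > 0)
  if (neg < pos) v <- -v
  else if (neg == pos && v[1L] > 0) v <- -v
  v / sqrt(sum(v^2))
}

#' Temporal mean of a time-resolved connectivity stack
#'
#' @param cc A [dfc].
#' @return N x N matrix, the element-wise mean over slices.
#' @export
dfc_mean <- function(cc) {
  stopifnot(inherits(cc, "dfc"))
  apply(cc$stack, c(1L, 2L), mean)
}
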