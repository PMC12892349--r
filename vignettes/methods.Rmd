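---
title: "Methods: connectivity estimators, graph metrics, and the multiverse engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity estimators, graph metrics, and the multiverse engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfcverse)
```

This vignette documents the models implemented in `dfcverse`, the
conventions and numerical choices behind them, what the synthetic
generators do and do not emulate, and the package's known limitations.

## Data model and conventions

All estimators operate on a `timeseries`: a T × N matrix with rows as
time points and columns as regions, plus a sampling interval `tr` in
seconds. Orientation is fixed — nothing is auto-transposed, and files
whose first row contains a non-numeric token are read as having a header
of region labels. Indices reported in results (`time_index`, state
labels) are 1-based, following R convention.

Standardization defaults to the population variance convention
(`ddof = 0`). This is not cosmetic: with z-scores
$z_i(t) = (x_i(t) - \bar x_i)/\sigma_i$ and $\sigma_i$ the ddof-0
standard deviation, the temporal mean of the edge time series
$e_{ij}(t) = z_i(t)z_j(t)$ equals the Pearson correlation *exactly*,
$\tfrac1T\sum_t z_i(t) z_j(t) = r_{ij}$, which the tests assert at
1e-12. With `ddof = 1` the identity would hold only up to a factor
$(T-1)/T$.

Temporal filtering uses a 2nd-order Butterworth band-pass applied
forward and backward (`signal::filtfilt`), i.e. zero-phase, with column
means removed first. The filter family and order are this package's
choice; a second-order zero-phase Butterworth is the common default in
fMRI pipelines and yields a testable amplitude contract (≥ 95 %
retention in-band, ≤ 5 % out-of-band, measured away from the first and
last 10 % of samples where filter and Hilbert-transform edge effects
concentrate; windowed estimators flag those samples in
`params$edge_samples`).

## Static estimators

**Pearson correlation** is `stats::cor` with validation (constant
regions are an error, not NaN propagation).

**Partial correlation** inverts the (optionally regularized) covariance:
$\rho_{ij} = -P_{ij}/\sqrt{P_{ii}P_{jj}}$. Because N can approach T in
practice, the covariance can be shrunk toward a scaled identity,
$(1-s)\,S + s\,\mu I$ with $\mu = \operatorname{tr}(S)/N$; `shrinkage =
"auto"` picks $s$ with a Ledoit–Wolf-style plug-in estimate. At
`shrinkage = 0` the result equals pairwise correlation of the residuals
after regressing out all other regions, which the tests verify against
an explicit `lm`-residual oracle at 1e-8 for N ≤ 6.

**Mutual information** uses a joint histogram over equal-frequency
marginal bins, reported in nats, with the per-region binned entropy on
the diagonal. Bins are assigned by ranks (ties broken by order of
appearance), so the estimate is invariant under strictly monotone
transforms, and a region paired with itself attains exactly $\ln B$
when T is divisible by B — a clean closed-form test surface. The
default `"auto"` bin count is $\lceil\sqrt{T/5}\rceil$, a conservative
rule keeping ≥ 5 expected counts per marginal bin. A k-NN estimator
would have lower bias but no exact identities; binning was chosen
deliberately.

## Continuously varying estimators

**Sliding window.** Only fully interior windows are used: with length w
and step s there are $W = \lfloor (T-w)/s\rfloor + 1$ windows, window k
covering samples $[(k-1)s + 1, (k-1)s + w]$ and stamped at its center
$(k-1)s + (w+1)/2$. No padding means no edge artifacts and an exactly
countable contract. The Gaussian taper is parameterized by its standard
deviation σ in samples, weights renormalized to sum 1; as σ → ∞ the
taper converges to the rectangular window (tested at σ = 1e6 against
the rect path at 1e-6). With w = T the single slice *is* the static
Pearson matrix.

**Multiplication of temporal derivatives.** First differences are
mean-centred per region before the pairwise score
$m_{ij}(t) = \mathrm{d}x_i(t)\,\mathrm{d}x_j(t)/(\sigma_{\mathrm{d}x_i}\sigma_{\mathrm{d}x_j})$,
so the temporal mean of the raw score equals the Pearson correlation of
the differenced series exactly — the identity the tests use as oracle.
The moving-average smoother keeps fully interior windows
(`smooth_w = 1` returns raw scores; `smooth_w = T−1` returns the single
mean slice). The default is raw output; the appropriate smoothing width
is data-dependent and deliberately left to the user.

**Jackknife correlation** computes all leave-one-out correlations
$r_{-t}$ from full-sample sums in O(T·N²) rather than recomputing each
deletion, and is tested against the naive recomputation at 1e-10. The
`scaled` mode z-scores each pair's leave-one-out series across t and
inverts the sign, so samples whose removal lowers the correlation score
high. A numerically constant $r_{-t}$ series (spread < 1e-10, e.g. a
perfectly correlated pair) is mapped to zeros rather than amplifying
floating-point noise — a documented convention.

**Spatial distance** maps $d_{ij}(t) = |z_i(t) - z_j(t)|$ through
$1/(1+d)$ (default) or $e^{-d}$. The similarity transform of the
original method is not uniquely established, so the kernel is an
explicit argument; both keep values in (0, 1] with unit diagonal.

**Flexible least squares** solves, for each ordered pair,
$\min_\beta \sum_t (x_j(t) - \beta_t x_i(t))^2 + \mu \sum_t (\beta_{t+1}-\beta_t)^2$
*exactly* via the tridiagonal normal equations
$(\operatorname{diag}(x_i^2) + \mu L)\,\beta = x_i \odot x_j$ (L the
path-graph Laplacian), using the Thomas algorithm — no iterative
recursion, no convergence parameters. Limits anchor the tests: μ = 0
gives the pointwise ratio, μ → ∞ a constant path equal to the
no-intercept OLS slope; on tiny instances the returned path never loses
to a grid of constant paths. Slices are symmetrized by averaging the
two directed estimates (`symmetrize = FALSE` preserves directionality).

**Phase synchronization and LEiDA.** Columns are band-passed, the
analytic signal is formed by the standard FFT construction (zeroing
negative frequencies), and the instantaneous phase θ_i(t) taken as its
argument. Phase synchrony is $\cos(\theta_i - \theta_j)$. LEiDA builds
the instantaneous coherence matrix $C_{ij}(t) = \cos(\theta_i-\theta_j)$
and extracts its leading eigenvector, unit-norm, with the sign fixed so
that the majority of components are negative (exact ties: first
component non-positive) — eigenvectors are only defined up to sign, and
a deterministic convention is required for clustering and for
reproducibility.

## State-based methods

All clustering goes through one engine: k-means++ initialization with
`n_init` restarts (default 10) of Lloyd iterations via `stats::kmeans`,
best inertia kept, fully deterministic given a seed. Sliding-window
clustering and `states_from_continuous` vectorize the upper triangle of
each connectivity slice; CAPs selects frames where the seed region's
z-score (or the mean absolute z-score, `"global"`, the default) exceeds
`threshold_z` (default 1.0 z-units) and clusters the raw activation
vectors; LEiDA clusters the eigenvector series and re-normalizes
centroids under the same sign convention. Unselected CAP frames carry
the label `NA`.

The **Gaussian HMM** is fitted by Baum–Welch EM with scaled
forward–backward recursions: means initialized by k-means, transition
matrix initialized persistent (0.9 diagonal), uniform initial
distribution. Iteration stops after `max_iter` (default 100) or when
the log-likelihood gain drops below `tol` (default 1e-4); the trace is
non-decreasing (asserted at 1e-8, the numerical slack of the scaled
recursions). Covariances (diagonal by default; `"full"` available) are
floored at eigenvalue 1e-6 upon near-collapse, with a warning — the
standard guard against a state shrinking onto a single frame. Decoding
is exact Viterbi in log space. A quantized-emission HMM variant is out
of scope; the Gaussian model is the single implementation.

**State summaries** report fractional occupancy, mean dwell (average
run length, multiplied by `tr` when provided), lag-1 transition
probabilities (self-transitions included; rows without outgoing
transitions are set uniform and flagged in `uniform_rows`), and the
number of label changes. Unvisited states report dwell 0 with a
`visited` mask rather than NaN.

**State matching** for evaluation uses exhaustive minimum-cost
assignment over label permutations on centroid distances (K ≤ 8), which
is the Hungarian-assignment optimum at these sizes; recovery is scored
by the adjusted Rand index (cross-checked against `mclust`).

## Graph metrics

Graphs are symmetric, zero-diagonal weight matrices. Edge lengths for
path-based metrics are fixed as $l = 1/w$. Shortest paths are delegated
to `igraph` (Dijkstra); the test suite holds them to a hand-written
Floyd–Warshall oracle at 1e-10, together with triple-enumeration
clustering, induced-subgraph local efficiency, and set-arithmetic
matching oracles on random graphs of up to 12 nodes.

Density thresholding keeps exactly $\lceil d \cdot E\rceil$ largest
edges of the $E = N(N-1)/2$ possible, ties broken lexicographically by
(row, column) so that multiverse universes are bit-reproducible.
Disconnected pairs contribute 0 to efficiency and are excluded (but
counted and reported) in the characteristic path length — the natural
closed forms. Weighted local efficiency uses the Rubinov–Sporns
cube-root form; the binary case (where it reduces to the global
efficiency of each node's neighbor subgraph) is the oracle-tested one.
Modularity is the Newman form with resolution γ (default 1); Louvain is
the seeded `igraph` implementation, with Q always recomputed by this
package's `modularity_q` on the returned partition so the two cannot
disagree. Directed graphs, betweenness, rich-club, small-world indices,
and temporal network measures are out of scope.

## The multiverse engine

Forking paths are an ordered, named set of decisions with literal
(number/string/boolean) or call options. Universes are the cartesian
product in row-major declaration order (first decision slowest), 1-based
ids; exclusion rules are conjunctive partial assignments, OR-ed across
rules. Rendering replaces `{{decision}}` with the option's R literal —
numbers verbatim, strings quoted, booleans `TRUE`/`FALSE`, calls as
invocation snippets — and fails loudly on unresolved placeholders, as
does declaring a template that never uses a declared decision.

Generated scripts are standalone: each embeds its assignment as
literals, so any universe can be read and re-run in isolation.
Execution is per-universe `Rscript` subprocesses in separate working
directories; results travel as one JSON record per universe (written by
`save_universe_results()`), which makes parallelism trivial and keeps a
failing universe from taking its siblings down. The engine transports
confidence intervals attached by the universes but never computes any —
uncertainty quantification belongs to the producing analysis. The
specification curve sorts by outcome ascending with ties broken by
universe id, and draws the standard two panels: estimates (with CI
whiskers when present) above a decision-indicator matrix.

## Synthetic generators: what they emulate, and what not

`simulate_state_switching` is exactly the generative model assumed by
the Gaussian HMM — a first-order Markov chain (initial state uniform)
emitting multivariate normals per state (optionally with per-state
means). `simulate_phase_coupled` gives sinusoids with fixed phase lags
plus white noise, the cleanest ground truth for phase metrics.
`simulate_modular_graph` is a planted-partition model. None of them
emulate hemodynamics (no HRF convolution), scanner noise spectra
(1/f, drift), motion artifacts, or spatial autocorrelation between
parcels. Tests passing on these generators therefore establish
*correctness of the estimators under their own assumptions*, not
performance on real BOLD data.

Reference problem sizes used throughout the tests were chosen as the
smallest at which the asymptotic checks are stable: T = 2000 for state
recovery (transition-matrix error < 0.1, Viterbi accuracy > 0.95 in at
least 4 of 5 seeds), T = 5000 for covariance convergence (element-wise
error < 0.15), T = 10000 for transition-frequency convergence (< 0.05),
graphs of 6–12 nodes for brute-force oracles.

For the two-regime sliding-window clustering benchmark the chain
persistence is 0.98 (mean dwell 50 samples) with a 40-sample window:
window-based state methods are only identifiable when typical dwell
times exceed the window length, so the reference simulation respects
that regime and the test scores windows against their majority
ground-truth label (ARI > 0.8).

## Known limitations

* Clustering *raw* edge-time-series frames into states recovers
  amplitude regimes poorly: single-frame products $z_iz_j$ are so
  heavy-tailed that k-means isolates a handful of extreme frames
  instead of the generating covariance regimes (ARI ≈ 0.1 across every
  Gaussian two-regime design we simulated). `states_from_continuous`
  is therefore validated on windowed connectivity, where it recovers
  planted regimes reliably; applying it to unsmoothed edge time series
  is supported but the state labels should be interpreted as
  high-/low-co-fluctuation episodes rather than covariance states.
* The plug-in MI estimator is biased upward at small T
  (≈ (B−1)²/(2T) nats); the independence test bound (< 0.05 nats at
  T = 5000, B = 8) accounts for this.
* `partial_fc(shrinkage = 0)` requires T > N; use `"auto"` otherwise.
* Phase metrics assume the band-passed signal is narrowband enough for
  a meaningful instantaneous phase; the first/last 10 % of samples are
  edge-affected and flagged, not removed.
* Louvain's partition depends on the seeded sweep order (as in any
  Louvain implementation); Q and the partition are reproducible per
  seed but not canonical.
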