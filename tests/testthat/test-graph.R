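test_that("negative-weight handling implements all three modes", {
  W <- matrix(c(0, -0.5, 0.2, -0.5, 0, 0.8, 0.2, 0.8, 0), 3)
  g <- connectivity_graph(W)
  expect_equal(handle_negative(g, "abs")$weights[1, 2], 0.5)
  expect_equal(handle_negative(g, "zero")$weights[1, 2], 0)
  expect_equal(handle_negative(g, "keep")$weights, W)
  pos <- connectivity_graph(abs(W))
  expect_equal(handle_negative(pos, "abs")$weights,
               handle_negative(pos, "zero")$weights)
  expect_error(handle_negative(g, "flip"), "arg")
})

test_that("density thresholding keeps exactly the top edges", {
  W <- matrix(0, 4, 4)
  W[upper.tri(W)] <- c(0.9, 0.1, 0.5, 0.3, 0.8, 0.2)
  W <- W + t(W)
  g <- threshold_density(connectivity_graph(W), 0.5)
  kept <- sort(g$weights[upper.tri(g$weights)][g$weights[upper.tri(g$weights)] > 0],
               decreasing = TRUE)
  expect_equal(kept, c(0.9, 0.8, 0.5))
  expect_equal(threshold_density(connectivity_graph(W), 1)$weights, W)
  expect_error(threshold_density(connectivity_graph(W), 0), "density")
  expect_error(threshold_density(connectivity_graph(W), 1.2), "density")
})

test_that("realized density is minimal and matches a sort oracle", {
  set.seed(71)
  for (rep in 1:10) {
    W <- random_weights(6, density = runif(1, 0.3, 0.9))
    E <- 15
    d <- runif(1, 0.1, 1)
    g <- threshold_density(connectivity_graph(W), d)
    n_kept <- sum(g$weights[upper.tri(g$weights)] > 0)
    wanted <- ceiling(d * E)
    n_pos <- sum(W[upper.tri(W)] > 0)
    expect_equal(n_kept, min(wanted, n_pos))
    # kept edges are the largest ones
    thr <- sort(W[upper.tri(W)], decreasing = TRUE)[wanted]
    expect_true(all(g$weights[upper.tri(g$weights) & g$weights > 0] >= thr))
  }
})

test_that("binarize is idempotent and degree/strength behave", {
  W <- matrix(c(0, 0.5, 0.5, 0.5, 0, 0.5, 0.5, 0.5, 0), 3)
  b <- binarize(connectivity_graph(W))
  expect_true(all(b$weights %in% c(0, 1)))
  expect_equal(binarize(b)$weights, b$weights)
  ds <- degree_strength(connectivity_graph(W))
  expect_equal(ds$strength, rep(1, 3))
  expect_equal(ds$degree, rep(2, 3))
  K4 <- connectivity_graph(matrix(1, 4, 4) - diag(4))
  expect_equal(degree_strength(K4)$degree, rep(3, 4))
  star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star <- star + t(star)
  expect_equal(degree_strength(connectivity_graph(star))$degree,
               c(3, 1, 1, 1))
})

test_that("clustering coefficient matches triple enumeration on random graphs", {
  K3 <- connectivity_graph(matrix(1, 3, 3) - diag(3))
  expect_equal(clustering_coefficient(K3), rep(1, 3))
  star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star <- star + t(star)
  expect_equal(clustering_coefficient(connectivity_graph(star)), rep(0, 4))
  set.seed(72)
  for (rep in 1:10) {
    A <- (random_weights(8, density = 0.5) > 0) * 1
    cc <- clustering_coefficient(connectivity_graph(A, binary = TRUE))
    expect_lt(max(abs(cc - oracle_clustering_binary(A))), 1e-12)
  }
})

test_that("shortest paths agree with Floyd-Warshall on weighted graphs", {
  p3 <- connectivity_graph(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(shortest_paths_fc(p3),
               rbind(c(0, 1, 2), c(1, 0, 1), c(2, 1, 0)))
  set.seed(73)
  for (rep in 1:10) {
    W <- random_weights(10, density = 0.4)
    D <- shortest_paths_fc(connectivity_graph(W))
    L <- ifelse(W > 0, 1 / W, 0)
    expect_lt(max(abs(D - oracle_floyd_warshall(L))[is.finite(D)]), 1e-10)
    expect_identical(is.finite(D), is.finite(oracle_floyd_warshall(L)))
  }
  # two disconnected dyads: 8 infinite entries
  dy <- matrix(0, 4, 4); dy[1, 2] <- dy[2, 1] <- 1; dy[3, 4] <- dy[4, 3] <- 1
  D <- shortest_paths_fc(connectivity_graph(dy))
  expect_equal(sum(!is.finite(D)), 8L)
})

test_that("characteristic path length and efficiency match hand values", {
  p3 <- connectivity_graph(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  cpl <- characteristic_path_length(shortest_paths_fc(p3))
  expect_equal(cpl$L, 4 / 3)
  expect_equal(cpl$disconnected_fraction, 0)
  expect_equal(global_efficiency(p3), 0.8333333333, tolerance = 1e-10)
  K5 <- connectivity_graph(matrix(1, 5, 5) - diag(5))
  expect_equal(characteristic_path_length(shortest_paths_fc(K5))$L, 1)
  expect_equal(global_efficiency(K5), 1)
  empty <- connectivity_graph(matrix(0, 4, 4))
  expect_equal(global_efficiency(empty), 0)
  expect_error(characteristic_path_length(shortest_paths_fc(empty)),
               "disconnected")
})

test_that("adding an edge never increases path length nor decreases efficiency", {
  set.seed(74)
  for (rep in 1:8) {
    W <- random_weights(8, density = 0.4)
    g <- connectivity_graph(W)
    off <- which(W == 0 & upper.tri(W), arr.ind = TRUE)
    if (nrow(off) == 0) next
    pick <- off[sample.int(nrow(off), 1), ]
    W2 <- W
    W2[pick[1], pick[2]] <- W2[pick[2], pick[1]] <- runif(1, 0.1, 1)
    g2 <- connectivity_graph(W2)
    expect_gte(global_efficiency(g2), global_efficiency(g) - 1e-12)
    D1 <- shortest_paths_fc(g); D2 <- shortest_paths_fc(g2)
    both <- is.finite(D1)
    expect_true(all(D2[both] <= D1[both] + 1e-12))
  }
})

test_that("local efficiency matches the induced-subgraph oracle", {
  K4 <- connectivity_graph(matrix(1, 4, 4) - diag(4))
  expect_equal(local_efficiency(K4), rep(1, 4))
  star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star <- star + t(star)
  expect_equal(local_efficiency(connectivity_graph(star)), rep(0, 4))
  set.seed(75)
  for (rep in 1:8) {
    A <- (random_weights(12, density = 0.5) > 0) * 1
    le <- local_efficiency(connectivity_graph(A, binary = TRUE))
    expect_lt(max(abs(le - oracle_local_efficiency_binary(A))), 1e-10)
  }
})

test_that("weighted local efficiency is sane and reduces to binary on 0/1 weights", {
  set.seed(76)
  A <- (random_weights(10, density = 0.5) > 0) * 1
  gb <- connectivity_graph(A, binary = TRUE)
  gw <- connectivity_graph(A + 0)   # same matrix treated as weighted
  gw$binary <- FALSE
  expect_lt(max(abs(local_efficiency(gb) - local_efficiency(gw))), 1e-10)
})

test_that("matching index agrees with set arithmetic", {
  # a, b share neighborhood {c, d}, a-b absent -> M_ab = 1
  A <- matrix(0, 4, 4)
  A[1, 3] <- A[1, 4] <- A[2, 3] <- A[2, 4] <- 1
  A <- A + t(A)
  M <- matching_index(connectivity_graph(A, binary = TRUE))
  expect_equal(M[1, 2], 1)
  # disjoint neighborhoods
  B <- matrix(0, 6, 6); B[1, 3] <- B[2, 4] <- 1; B <- B + t(B)
  MB <- matching_index(connectivity_graph(B, binary = TRUE))
  expect_equal(MB[1, 2], 0)
  set.seed(77)
  for (rep in 1:10) {
    A <- (random_weights(10, density = 0.4) > 0) * 1
    M <- matching_index(connectivity_graph(A, binary = TRUE))
    expect_lt(max(abs(M - oracle_matching_index(A))), 1e-12)
    expect_equal(M, t(M))
    expect_true(all(M >= 0 & M <= 1))
  }
  expect_error(matching_index(connectivity_graph(A * 0.5)), "binary")
})

test_that("modularity matches the closed-form two-clique value", {
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1; diag(W) <- 0
  g <- connectivity_graph(W)
  part <- rep(1:2, each = 4)
  expect_equal(modularity_q(g, part), 0.5)
  expect_equal(modularity_q(g, rep(1, 8)), 0)
  # invariant to relabeling
  expect_equal(modularity_q(g, c(rep(7, 4), rep(3, 4))), 0.5)
  expect_error(modularity_q(connectivity_graph(matrix(0, 3, 3)), rep(1, 3)),
               "no edges")
})

test_that("louvain recovers planted communities", {
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1; diag(W) <- 0
  lv <- louvain(connectivity_graph(W), seed = 78)
  expect_equal(lv$Q, 0.5)
  expect_equal(adjusted_rand_index(lv$partition, rep(1:2, each = 4)), 1)
  pm <- simulate_modular_graph(20, 2, 0.9, 0.05, seed = 79)
  lv2 <- louvain(pm$graph, seed = 80)
  expect_equal(adjusted_rand_index(lv2$partition, pm$membership), 1)
  expect_gte(lv2$Q, 0)
  expect_lte(abs(lv2$Q), 1)
  # Q consistent with modularity_q and reproducible per seed
  expect_equal(lv2$Q, modularity_q(pm$graph, lv2$partition), tolerance = 1e-10)
  lv3 <- louvain(pm$graph, seed = 80)
  expect_identical(lv2$partition, lv3$partition)
})
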