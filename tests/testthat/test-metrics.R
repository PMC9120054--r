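test_that("proportional thresholding keeps the top-k weighted edges", {
  # N=3 triangle, k=1 keeps only the strongest edge
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 3; W[1, 3] <- W[3, 1] <- 2; W[2, 3] <- W[3, 2] <- 1
  Wt <- threshold_proportional(W, 1 / 3)   # k = floor(3*3/3 ... ) = 1
  expect_equal(sum(Wt > 0) / 2, 1)
  expect_equal(Wt[1, 2], 3)

  # S = 1 on a complete matrix is the identity
  Wc <- rand_sym_matrix(8, seed = 3)
  expect_equal(threshold_proportional(Wc, 1), Wc)

  expect_error(threshold_proportional(Wc, 0), "in \\(0, 1\\]")
  expect_error(threshold_proportional(Wc, 1.2), "in \\(0, 1\\]")

  # density below requested sparsity: keep everything, warn
  Ws <- matrix(0, 10, 10); Ws[1, 2] <- Ws[2, 1] <- 5
  expect_warning(out <- threshold_proportional(Ws, 0.5), "density")
  expect_equal(out, Ws)
})

test_that("thresholding matches the exhaustive sort oracle", {
  for (seed in 1:20) {
    W <- rand_sym_matrix(10, density = 0.9, seed = seed)
    S <- runif(1, 0.1, 0.6)
    Wt <- threshold_proportional(W, S)
    expect_equal(sum(Wt[upper.tri(Wt)] > 0),
                 min(floor(S * 45), sum(W[upper.tri(W)] > 0)))
    expect_equal(Wt, bf_threshold(W, S))
  }
  # deterministic tie-breaking by ascending (row, col)
  W <- matrix(0, 4, 4)
  for (p in list(c(1, 2), c(1, 3), c(2, 3), c(3, 4))) {
    W[p[1], p[2]] <- W[p[2], p[1]] <- 2
  }
  Wt <- threshold_proportional(W, 2 / 6 - 1e-9)  # k = 1, four tied edges
  expect_equal(which(Wt[upper.tri(Wt)] > 0), 1L)  # edge (1,2) wins
})

test_that("thresholding is idempotent and nested across sparsity levels", {
  W <- rand_sym_matrix(12, seed = 7)
  for (S in c(0.15, 0.30)) {
    Wt <- threshold_proportional(W, S)
    expect_equal(threshold_proportional(Wt, S), Wt)
  }
  W1 <- threshold_proportional(W, 0.12)
  W2 <- threshold_proportional(W, 0.28)
  expect_true(all(W2[W1 > 0] > 0))               # edge-set nesting
  expect_true(all(node_strength(W1) <= node_strength(W2) + 1e-12))
})

test_that("node strength matches its definition", {
  W4 <- matrix(1, 4, 4); diag(W4) <- 0
  expect_equal(node_strength(W4), rep(3, 4))
  expect_equal(node_strength(matrix(0, 5, 5)), rep(0, 5))
  W <- rand_sym_matrix(8, density = 0.7, seed = 11)
  bf <- vapply(1:8, function(i) sum(W[i, ]), numeric(1))
  expect_equal(node_strength(W), bf)
})

test_that("weighted betweenness matches closed forms and path enumeration", {
  # path a-b-c: middle node carries the single shortest path
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 1; W[2, 3] <- W[3, 2] <- 1
  expect_equal(betweenness_w(W), c(0, 1, 0))
  # star with 4 leaves: hub carries all 6 leaf pairs
  W <- matrix(0, 5, 5); W[1, 2:5] <- W[2:5, 1] <- 2
  expect_equal(betweenness_w(W), c(6, 0, 0, 0, 0))
  expect_error(betweenness_w(matrix(0, 3, 3)), "all-zero")

  for (seed in 1:6) {
    W <- rand_sym_matrix(7, density = 0.8, seed = 100 + seed)
    expect_equal(betweenness_w(W), bf_betweenness(W), tolerance = 1e-10)
  }
})

test_that("weighted clustering matches the triple-sum definition", {
  W <- matrix(1, 3, 3); diag(W) <- 0
  expect_equal(clustering_coef_w(W), rep(1, 3))
  W <- matrix(0, 5, 5); W[1, 2:5] <- W[2:5, 1] <- 3
  expect_equal(clustering_coef_w(W), rep(0, 5))
  expect_equal(clustering_coef_w(matrix(0, 4, 4)), rep(0, 4))

  for (seed in 1:6) {
    W <- rand_sym_matrix(8, density = 0.7, seed = 200 + seed)
    cc <- clustering_coef_w(W)
    expect_equal(cc, bf_clustering(W), tolerance = 1e-12)
    expect_true(all(cc >= 0 & cc <= 1))
  }

  # binary reduction to the classic triangle fraction 2T / (k (k-1))
  set.seed(5)
  A <- rand_sym_matrix(10, density = 0.5, seed = 5)
  A[A > 0] <- 1
  tri <- diag(A %*% A %*% A)
  k <- rowSums(A)
  classic <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  expect_equal(clustering_coef_w(A), classic)
})

test_that("metric vectors are permutation-equivariant and scale correctly", {
  W <- rand_sym_matrix(9, density = 0.8, seed = 31)
  perm <- sample(9)
  Wp <- W[perm, perm]
  for (f in list(node_strength, betweenness_w, clustering_coef_w))
    expect_equal(f(Wp), f(W)[perm], tolerance = 1e-12)
  # scaling: strength scales, betweenness and clustering invariant
  expect_equal(node_strength(3 * W), 3 * node_strength(W))
  expect_equal(betweenness_w(3 * W), betweenness_w(W))
  expect_equal(clustering_coef_w(3 * W), clustering_coef_w(W))
})

test_that("metric curves equal independent per-threshold recomputation", {
  W <- rand_sym_matrix(10, seed = 17)
  g1 <- 0.2
  mc <- metric_curves(W, g1, metrics = "strength")
  expect_equal(mc$strength[, 1],
               node_strength(threshold_proportional(W, g1)))

  grid <- sparsity_grid()
  mc <- metric_curves(W, grid)
  j <- 13
  Wt <- threshold_proportional(W, grid[j])
  expect_equal(mc$strength[, j], node_strength(Wt))
  expect_equal(mc$betweenness[, j], betweenness_w(Wt))
  expect_equal(mc$clustering[, j], clustering_coef_w(Wt))
})

test_that("AUC over thresholds matches closed forms and refinement", {
  grid <- sparsity_grid()
  # constant curve c integrates to 0.20 * c
  cc <- matrix(2.5, 3, length(grid))
  expect_equal(auc_over_thresholds(cc, grid), rep(0.5, 3))
  # linear curve f(S) = S integrates to (0.30^2 - 0.10^2)/2 = 0.04
  lin <- matrix(grid, 1, length(grid), byrow = TRUE)
  expect_equal(auc_over_thresholds(lin, grid), 0.04)
  expect_error(auc_over_thresholds(cc[, 1, drop = FALSE], grid[1]),
               "at least 2")

  # random piecewise-linear curve: refinement of the interpolant agrees
  set.seed(9)
  vals <- runif(length(grid))
  fine <- seq(0.10, 0.30, length.out = 4001)
  interp <- stats::approx(grid, vals, xout = fine)$y
  riemann <- sum((interp[-1] + interp[-length(fine)]) / 2 * diff(fine))
  expect_equal(auc_over_thresholds(matrix(vals, 1), grid), riemann,
               tolerance = 1e-10)
})

test_that("per-subject feature tables are deterministic and well-formed", {
  co <- make_test_cohort(n_nodes = 12, n_mdd = 3, n_hc = 3, seed = 2)
  f1 <- compute_nodal_features(co, short_grid(), c("strength", "clustering"))
  f2 <- compute_nodal_features(co, short_grid(), c("strength", "clustering"))
  expect_identical(f1, f2)
  expect_equal(nrow(f1), 6 * 12 * 2)
  expect_true(all(is.finite(f1$auc)))
  fm <- feature_matrix(f1, "strength", co)
  expect_equal(dim(fm), c(6, 12))
  expect_equal(fm["sub-001", "node_003"],
               f1$auc[f1$subject_id == "sub-001" & f1$region_index == 3 &
                        f1$metric == "strength"])
})
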