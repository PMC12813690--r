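k_complete <- function(n) {
  adj <- matrix(TRUE, n, n)
  diag(adj) <- FALSE
  adj
}

path_graph <- function(n) {
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- TRUE
  adj
}

star_graph <- function(leaves) {
  adj <- matrix(FALSE, leaves + 1, leaves + 1)
  adj[1, 2:(leaves + 1)] <- adj[2:(leaves + 1), 1] <- TRUE
  adj
}

ring_lattice <- function(n, k) {
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (d in seq_len(k / 2)) {
      j <- ((i - 1 + d) %% n) + 1
      adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  adj
}

test_that("closed-form graphs give exact global metrics", {
  k5 <- global_metrics(as_bg(k_complete(5)))
  expect_equal(k5$Cp, 1)
  expect_equal(k5$Lp, 1)
  expect_equal(k5$E_global, 1)
  expect_equal(k5$E_local, 1)

  p3 <- global_metrics(as_bg(path_graph(3)))
  expect_equal(p3$E_global, (1 + 1 + 0.5) / 3, tolerance = 1e-12)
  expect_equal(p3$Cp, 0)
  expect_equal(p3$Lp, (1 + 1 + 2) / 3, tolerance = 1e-12)

  # distances on a 3-chain and disjoint edges
  D <- shortest_paths(as_bg(path_graph(3)))
  expect_equal(D[1, 3], 2)
  D5 <- shortest_paths(as_bg(k_complete(5)))
  expect_true(all(D5[row(D5) != col(D5)] == 1))
  two_edges <- matrix(FALSE, 4, 4)
  two_edges[1, 2] <- two_edges[2, 1] <- TRUE
  two_edges[3, 4] <- two_edges[4, 3] <- TRUE
  Dd <- shortest_paths(as_bg(two_edges))
  expect_true(is.infinite(Dd[1, 3]))

  # two disjoint K4s with the clique partition: Q = 0.5
  adj <- matrix(FALSE, 8, 8)
  adj[1:4, 1:4] <- k_complete(4)
  adj[5:8, 5:8] <- k_complete(4)
  expect_equal(global_metrics(as_bg(adj))$Q, 0.5, tolerance = 1e-12)

  # empty graph flagged degenerate
  e <- global_metrics(as_bg(matrix(FALSE, 5, 5)))
  expect_true(e$degenerate)
  expect_equal(e$E_global, 0)
})

test_that("closed-form graphs give exact nodal metrics", {
  star <- nodal_metrics(as_bg(star_graph(4)))
  expect_equal(star$betweenness[1], 6)       # C(4,2) leaf pairs
  expect_equal(star$betweenness[-1], rep(0, 4))
  expect_equal(star$degree[1], 4)
  k5 <- nodal_metrics(as_bg(k_complete(5)))
  expect_equal(k5$betweenness, rep(0, 5))
  expect_equal(k5$nodal_Cp, rep(1, 5))
  expect_equal(k5$nodal_efficiency, rep(1, 5))
})

test_that("metrics match brute-force oracles exhaustively on small graphs", {
  # exhaustive over every labeled connected graph on 2..5 nodes
  for (n in 2:5) {
    graphs <- Filter(is_connected_adj, all_graphs(n))
    for (adj in graphs) {
      bg <- as_bg(adj)
      expect_identical(shortest_paths(bg), bf_distances(adj))
      nm <- nodal_metrics(bg)
      expect_equal(nm$betweenness, bf_betweenness(adj), tolerance = 1e-10)
      expect_equal(nm$nodal_Cp, bf_clustering(adj), tolerance = 1e-12)
      expect_equal(nm$nodal_efficiency, bf_nodal_efficiency(adj),
                   tolerance = 1e-12)
      expect_equal(nm$nodal_local_efficiency, bf_local_efficiency(adj),
                   tolerance = 1e-12)
      expect_equal(nm$nodal_shortest_path, bf_nodal_shortest_path(adj),
                   tolerance = 1e-12)
      expect_equal(nm$degree, rowSums(adj))
      gm <- global_metrics(bg)
      expect_equal(gm$E_global, bf_global_efficiency(adj), tolerance = 1e-12)
      expect_equal(gm$Cp, mean(bf_clustering(adj)), tolerance = 1e-12)
      expect_equal(gm$E_local, mean(bf_local_efficiency(adj)),
                   tolerance = 1e-12)
      expect_equal(gm$Lp, bf_char_path_length(adj), tolerance = 1e-12)
    }
  }
})

test_that("metrics match brute force on sampled 6-node connected graphs", {
  set.seed(606)
  for (k in 1:100) {
    adj <- random_connected_graph(6, runif(1, 0.3, 0.8))
    bg <- as_bg(adj)
    nm <- nodal_metrics(bg)
    expect_equal(nm$betweenness, bf_betweenness(adj), tolerance = 1e-10)
    expect_equal(nm$nodal_Cp, bf_clustering(adj), tolerance = 1e-12)
    expect_equal(nm$nodal_efficiency, bf_nodal_efficiency(adj),
                 tolerance = 1e-12)
    expect_equal(nm$nodal_local_efficiency, bf_local_efficiency(adj),
                 tolerance = 1e-12)
    expect_equal(nm$nodal_shortest_path, bf_nodal_shortest_path(adj),
                 tolerance = 1e-12)
    gm <- global_metrics(bg)
    expect_equal(gm$E_global, bf_global_efficiency(adj), tolerance = 1e-12)
    expect_equal(gm$Lp, bf_char_path_length(adj), tolerance = 1e-12)
  }
})

test_that("greedy modularity is never worse than the trivial partition", {
  set.seed(77)
  for (k in 1:20) {
    adj <- random_connected_graph(8, runif(1, 0.2, 0.7))
    expect_gte(global_metrics(as_bg(adj))$Q, 0)
  }
})

test_that("isomorphism invariance: relabeling permutes nodal, fixes global metrics", {
  set.seed(31)
  adj <- random_connected_graph(7, 0.4)
  perm <- sample(7)
  padj <- adj[perm, perm]
  nm <- nodal_metrics(as_bg(adj))
  pnm <- nodal_metrics(as_bg(padj))
  for (col in names(nm)) {
    expect_equal(pnm[[col]], nm[[col]][perm], tolerance = 1e-12)
  }
  gm <- global_metrics(as_bg(adj))
  pgm <- global_metrics(as_bg(padj))
  for (f in c("E_global", "E_local", "Cp", "Lp")) {
    expect_equal(pgm[[f]], gm[[f]], tolerance = 1e-12)
  }
})

test_that("degree-preserving rewiring keeps the degree sequence exactly", {
  set.seed(14)
  adj <- random_connected_graph(20, 0.3)
  for (s in 1:5) {
    nullg <- rewire_null(as_bg(adj), seed = s)
    expect_equal(rowSums(nullg$adjacency), rowSums(adj))
    expect_equal(sum(nullg$adjacency), sum(adj))
    expect_false(any(diag(nullg$adjacency)))
  }
  # a triangle admits no valid swap
  expect_warning(tri <- rewire_null(as_bg(k_complete(3)), seed = 1),
                 "no rewiring")
  expect_identical(tri$adjacency, k_complete(3))
})

test_that("small-world normalization behaves on reference topologies", {
  # a dense random graph is its own null: gamma and lambda near 1
  set.seed(42)
  adj <- random_connected_graph(90, 0.3)
  sw <- normalized_small_world(as_bg(adj), n_rand = 20, seed = 2)
  expect_gt(sw$gamma, 0.8); expect_lt(sw$gamma, 1.2)
  expect_gt(sw$lambda, 0.95); expect_lt(sw$lambda, 1.05)
  expect_equal(sw$sigma, sw$gamma / sw$lambda, tolerance = 1e-12)
  # ring lattice: strongly clustered, sigma > 1
  ring <- ring_lattice(90, 10)
  sw2 <- normalized_small_world(as_bg(ring), n_rand = 20, seed = 3)
  expect_gt(sw2$sigma, 1)
})

test_that("curve AUC matches closed-form integrals", {
  grid <- seq(0.05, 0.50, 0.01)
  expect_equal(metric_auc(rep(2, 46), grid), 0.45 * 2, tolerance = 1e-12)
  expect_equal(metric_auc(grid, grid), (0.50^2 - 0.05^2) / 2,
               tolerance = 1e-12)
  expect_equal(metric_auc(c(1, 3), c(0.05, 0.06)), 0.02, tolerance = 1e-12)
  expect_error(metric_auc(1:3, 1:2), "shape")
})

test_that("connectome curves are deterministic with the expected shape", {
  set.seed(6)
  s <- simulate_roi_signals(default_base_corr(20, 0.4, 0.1), 100, 2, seed = 4)
  cm <- pearson_matrix(t(s))
  gs <- graph_series(cm, s_min = 0.20, s_max = 0.30, step = 0.05)
  cv <- connectome_curves(gs, n_rand = 3, seed = 9)
  cv2 <- connectome_curves(gs, n_rand = 3, seed = 9)
  expect_identical(cv, cv2)
  expect_equal(dim(cv$global), c(3L, 8L))
  expect_equal(dim(cv$auc_nodal), c(20L, 6L))
  expect_equal(cv$global[, "sigma"], cv$global[, "gamma"] / cv$global[, "lambda"],
               tolerance = 1e-12)
  # E_global nondecreasing along the nested series
  expect_true(all(diff(cv$global[, "E_global"]) >= -1e-12))
})
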