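mk_blocks <- function(n1, n0, sep_C = 0, sep_idx = 1:5, seed = 1,
                      n_C = 45, n_G = 8, n_N = 60) {
  set.seed(seed)
  lapply(seq_len(n1 + n0), function(i) {
    g <- if (i <= n1) 1L else 0L
    C <- rnorm(n_C)
    if (g == 1L) C[sep_idx] <- C[sep_idx] + sep_C
    structure(list(C = C, G = rnorm(n_G), N = rnorm(n_N),
                   subject_id = sprintf("s%02d", i), group = g),
              class = "feature_blocks")
  })
}

test_that("feature assembly follows the documented index maps", {
  expect_equal(edge_index_to_pair(1, 90), c(1L, 2L))
  expect_equal(edge_index_to_pair(4005, 90), c(89L, 90L))
  expect_equal(pair_to_edge_index(1, 2, 90), 1L)
  expect_equal(pair_to_edge_index(89, 90, 90), 4005L)
  # round trip over all 4005 indices
  p <- connectoscope:::upper_tri_pairs(90)
  back <- mapply(pair_to_edge_index, p$i, p$j, MoreArgs = list(n = 90L))
  expect_identical(back, 1:4005)

  set.seed(2)
  s <- simulate_roi_signals(default_base_corr(90), 80, 2, seed = 2)
  cm <- fisher_z(pearson_matrix(t(s)))
  gs <- graph_series(cm, s_min = 0.25, s_max = 0.30, step = 0.05)
  cv <- connectome_curves(gs, n_rand = 2, seed = 1)
  fb <- assemble_features(cm, cv, "s1", 1L)
  expect_length(fb$C, 4005)
  expect_length(fb$G, 8)
  expect_length(fb$N, 540)
  expect_equal(fb$C[1], cm$z[1, 2])
  expect_equal(fb$C[4005], cm$z[89, 90])
  # N is metric-major: first 90 entries are the first metric's nodes
  expect_equal(fb$N[1:90], unname(cv$auc_nodal[, 1]))
})

test_that("t-test selection is calibrated and powered as expected", {
  set.seed(3)
  n <- 50
  labels <- rep(c(1, 0), each = 25)
  # strong feature (3 pooled sd) selected essentially always
  hits <- vapply(1:50, function(k) {
    X <- cbind(rnorm(n), rnorm(n))
    X[labels == 1, 1] <- X[labels == 1, 1] + 3
    1 %in% ttest_select(X, labels, 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.99)
  # null calibration: selection rate per feature ~ alpha
  rates <- vapply(1:200, function(k) {
    X <- matrix(rnorm(n * 10), n, 10)
    length(ttest_select(X, labels, 0.05)) / 10
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 0.02)
  # alpha = 1 selects everything
  X <- matrix(rnorm(n * 7), n, 7)
  expect_identical(ttest_select(X, labels, 1), 1:7)
  expect_error(ttest_select(X[1:3, ], c(1, 0, 0)), "split error")
})

test_that("kernels are trace-normalized, symmetric and PSD", {
  set.seed(4)
  Xtr <- matrix(rnorm(20 * 30), 20, 30)
  Xte <- matrix(rnorm(5 * 30), 5, 30)
  k <- build_kernels(list(C = Xtr), test = list(C = Xte))
  K <- k$C$K
  expect_equal(sum(diag(K)), 20, tolerance = 1e-8)
  expect_lt(max(abs(K - t(K))), 1e-10)
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  expect_equal(dim(k$C$K_cross), c(5L, 20L))
  # duplicating a subject duplicates its Gram row/column
  Xdup <- rbind(Xtr, Xtr[3, ])
  K2 <- build_kernels(list(C = Xdup))$C$K
  expect_equal(K2[21, 1:20], K2[3, 1:20], tolerance = 1e-10)
})

test_that("multi-kernel SVM reduces to single-kernel and separates separable data", {
  set.seed(5)
  n <- 20
  labels <- rep(c(1, 0), each = 10)
  X1 <- matrix(rnorm(n * 10), n, 10)
  X1[labels == 1, ] <- X1[labels == 1, ] + 4
  X2 <- matrix(rnorm(n * 6), n, 6)
  kern <- build_kernels(list(A = X1, B = X2))
  K_list <- list(kern$A$K, kern$B$K)
  # beta = (1, 0): identical decisions to SVM on kernel A alone
  m_mk <- mk_svm_train(K_list, c(1, 0), labels, C = 1)
  m_a <- connectoscope:::fit_svm(kern$A$K, labels, C = 1)
  pr_mk <- connectoscope:::svm_predict(m_mk, kern$A$K)
  pr_a <- connectoscope:::svm_predict(m_a, kern$A$K)
  expect_identical(pr_mk$pred, pr_a$pred)
  # far clusters: training accuracy 1
  expect_equal(mean(pr_mk$pred == labels), 1)
  expect_error(mk_svm_train(K_list, c(1, 0), rep(1, n), C = 1),
               "degenerate-training")
  expect_error(mk_svm_train(K_list, c(2, 0), labels, C = 1))
})

test_that("kernel-space and linear feature-space engines agree", {
  # dual route: the exported multi-kernel machine (kernlab on Gram matrices)
  # against the linear fast path (LIBSVM on sqrt(beta)-scaled features);
  # identical QPs, so predictions must coincide
  set.seed(17)
  n <- 24
  labels <- rep(c(1, 0), each = 12)
  X1 <- matrix(rnorm(n * 12), n, 12)
  X1[labels == 1, ] <- X1[labels == 1, ] + 1.5
  X2 <- matrix(rnorm(n * 5), n, 5)
  kern <- build_kernels(list(A = X1, B = X2))
  for (betas in list(c(1, 0), c(0.5, 0.5), c(0.2, 0.8))) {
    mk <- mk_svm_train(list(kern$A$K, kern$B$K), betas, labels, C = 1)
    pr_k <- connectoscope:::svm_predict(
      mk, combine_kernels_test <- betas[1] * kern$A$K + betas[2] * kern$B$K)
    Z <- cbind(kern$A$Z * sqrt(betas[1]), kern$B$Z * sqrt(betas[2]))
    lf <- connectoscope:::svm_fit_linear(Z, labels, C = 1)
    pr_l <- connectoscope:::svm_predict_linear(lf, Z)
    expect_equal(pr_l$pred, pr_k$pred)
    expect_equal(pr_l$decision, pr_k$decision, tolerance = 1e-3)
  }
})

test_that("beta lattice covers the simplex lexicographically", {
  b <- connectoscope:::beta_lattice(3, 0.5)
  expect_equal(nrow(b), 6)   # (0,0,1),(0,.5,.5),(0,1,0),(.5,0,.5),(.5,.5,0),(1,0,0)
  expect_true(all(abs(rowSums(b) - 1) < 1e-12))
  expect_identical(connectoscope:::beta_lattice(1, 0.1), matrix(1, 1, 1))
  b2 <- connectoscope:::beta_lattice(2, 0.25)
  expect_equal(nrow(b2), 5)
})

test_that("performance summary computes contingency and rank AUC correctly", {
  truth <- c(rep(1, 10), rep(0, 10))
  pred <- c(rep(1, 8), rep(0, 2), rep(0, 9), 1)
  dec <- c(seq(2, 0.2, length.out = 10), seq(0.1, -2, length.out = 10))
  s <- performance_summary(pred, truth, dec)
  expect_equal(s$accuracy, 0.85)
  expect_equal(s$sensitivity, 0.80)
  expect_equal(s$specificity, 0.90)
  expect_equal(s$auc, 1.0)    # decision values perfectly ordered
  # decision values independent of truth -> AUC near 0.5
  set.seed(6)
  aucs <- replicate(200, performance_summary(pred, truth, rnorm(20))$auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  expect_error(performance_summary(pred, rep(1, 20), dec),
               "undefined-sensitivity")
})

test_that("consensus connections are the intersection across folds", {
  sets <- list(c(1, 2, 3), c(1, 2), c(1, 2, 4))
  out <- consensus_connections(sets, n_nodes = 90)
  expect_equal(out$index, c(1, 2))
  expect_equal(out$node_i, c(1, 1))
  expect_equal(out$node_j, c(2, 3))
  # any empty fold gives an empty consensus
  expect_equal(nrow(consensus_connections(list(c(1, 2), integer(0)), 90)), 0)
  # network annotation joins through the lookup
  tab <- load_network_labels()
  out2 <- consensus_connections(sets, n_nodes = 90, network_table = tab)
  expect_equal(out2$network_i[1], tab$network[1])
})

test_that("nested LOOCV holds each subject out once and separates planted effects", {
  feats <- mk_blocks(8, 8, sep_C = 3, seed = 7)
  res <- nested_loocv(feats, combo = "C", alpha = 0.05, C_grid = c(0.1, 1),
                      beta_step = 0.5, seed = 1)
  expect_equal(nrow(res$folds), 16)
  expect_identical(res$folds$subject, 1:16)
  expect_gte(res$summary$accuracy, 0.9)
  # consensus recovers the planted columns
  expect_true(all(1:5 %in% res$consensus$index))
  # multi-block engine runs on every combination
  for (combo in c("G", "N", "C+G", "G+N", "C+G+N")) {
    r <- nested_loocv(mk_blocks(4, 4, sep_C = 3, seed = 8), combo = combo,
                      alpha = 0.2, C_grid = 1, beta_step = 0.5, seed = 1)
    expect_equal(nrow(r$folds), 8)
  }
  expect_error(nested_loocv(feats, combo = "X"), "combo")
  expect_error(nested_loocv(feats, combo = "C", C_grid = numeric(0)),
               "empty C grid")
})

test_that("no leakage: corrupting the held-out subject changes nothing about its fold", {
  feats <- mk_blocks(6, 6, sep_C = 2.5, seed = 9)
  res <- nested_loocv(feats, combo = "C", alpha = 0.1, C_grid = c(0.5, 2),
                      beta_step = 0.5, seed = 1)
  # corrupt subject 4's features wildly and rerun
  feats2 <- feats
  feats2[[4]]$C <- feats2[[4]]$C * 1000 + 500
  res2 <- nested_loocv(feats2, combo = "C", alpha = 0.1, C_grid = c(0.5, 2),
                       beta_step = 0.5, seed = 1)
  expect_identical(res2$selected_C[[4]], res$selected_C[[4]])
  expect_identical(res2$folds$C[4], res$folds$C[4])
  # folds not involving subject 4 as held-out DO see its (training) data,
  # so only fold 4's selection is guaranteed invariant
})
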