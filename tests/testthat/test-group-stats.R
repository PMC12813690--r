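test_that("covariate-adjusted group t matches the normal-equations oracle", {
  set.seed(10)
  n <- 30
  group <- rep(c(1, 0), each = 15)
  covs <- cbind(age = rnorm(n, 40, 10), sex = rbinom(n, 1, 0.5))
  y <- rnorm(n) + 0.5 * group + 0.02 * covs[, 1]
  fit <- glm_group_t(y, group, covs)
  oracle <- bf_glm_t(y, group, covs)
  expect_equal(fit$t, oracle$t, tolerance = 1e-10)
  expect_equal(fit$p, oracle$p, tolerance = 1e-10)
  expect_equal(fit$df, oracle$df)

  # without covariates: equals the pooled two-sample t
  fit2 <- glm_group_t(y, group)
  tt <- t.test(y[group == 1], y[group == 0], var.equal = TRUE)
  expect_equal(fit2$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(fit2$p, tt$p.value, tolerance = 1e-10)

  # mean-matched groups (identical value multisets): t = 0, p = 1
  y0 <- rep(c(2, 3), 14)                     # 7 of each value per group
  fit0 <- glm_group_t(y0, rep(c(1, 0), each = 14))
  expect_equal(abs(fit0$t), 0, tolerance = 1e-10)
  expect_equal(fit0$p, 1, tolerance = 1e-10)

  expect_error(glm_group_t(y, group, cbind(covs, covs[, 1])), "collinearity")
})

test_that("covariates orthogonal to group leave the group t nearly unchanged", {
  set.seed(11)
  n <- 40
  group <- rep(c(1, 0), each = 20)
  # construct covariate exactly orthogonal to group and intercept
  raw <- rnorm(n)
  X0 <- cbind(1, group)
  cov_orth <- raw - X0 %*% solve(t(X0) %*% X0, t(X0) %*% raw)
  y <- rnorm(n) + 0.8 * group
  t_adj <- glm_group_t(y, group, cov_orth)$t
  t_un <- glm_group_t(y, group)$t
  # same group estimate; t differs only through the residual df/variance
  b_adj <- qr.coef(qr(cbind(1, group, cov_orth)), y)[2]
  b_un <- qr.coef(qr(cbind(1, group)), y)[2]
  expect_equal(b_adj, b_un, tolerance = 1e-10)
  expect_equal(sign(t_adj), sign(t_un))
})

test_that("voxelwise maps localize planted effects and respect exchangeability", {
  set.seed(12)
  mask <- array(TRUE, c(6, 6, 1))
  n <- 30
  group <- rep(c(1, 0), each = 15)
  effect_vox <- as.matrix(expand.grid(2:3, 2:3, 1))
  maps <- lapply(seq_len(n), function(i) {
    v <- array(rnorm(36), c(6, 6, 1))
    if (group[i] == 1) v[effect_vox] <- v[effect_vox] + 2
    voxel_map(v, mask, "ALFF")
  })
  sm <- voxelwise_group_map(maps, group)
  peak <- which.max(abs(sm$t_values))
  expect_true(peak %in% (effect_vox[, 1] + (effect_vox[, 2] - 1) * 6))
  # label negation flips t exactly
  sm2 <- voxelwise_group_map(maps, 1 - group)
  expect_equal(sm2$t_values, -sm$t_values, tolerance = 1e-10)
  # mask mismatch errors
  maps2 <- maps
  maps2[[1]]$mask[1] <- FALSE
  expect_error(voxelwise_group_map(maps2, group), "alignment")
})

test_that("permutation cluster correction is deterministic and label-symmetric", {
  set.seed(13)
  mask <- array(TRUE, c(5, 5, 2))
  n <- 24
  group <- rep(c(1, 0), each = 12)
  maps <- lapply(seq_len(n), function(i) {
    v <- array(rnorm(50), c(5, 5, 2))
    if (group[i] == 1) v[2:3, 2:3, 1] <- v[2:3, 2:3, 1] + 3
    voxel_map(v, mask, "ReHo")
  })
  r1 <- permutation_cluster_correct(maps, group, n_perm = 200,
                                    voxel_p = 0.05, cluster_p = 0.05,
                                    seed = 7)
  r2 <- permutation_cluster_correct(maps, group, n_perm = 200,
                                    voxel_p = 0.05, cluster_p = 0.05,
                                    seed = 7)
  expect_identical(r1$surviving_clusters, r2$surviving_clusters)
  expect_true(any(r1$surviving_clusters$survives))
  # swapped coding: same clusters survive
  r3 <- permutation_cluster_correct(maps, 1 - group, n_perm = 200,
                                    voxel_p = 0.05, cluster_p = 0.05,
                                    seed = 7)
  expect_equal(r3$surviving_clusters$size, r1$surviving_clusters$size)
  expect_error(permutation_cluster_correct(maps, group, n_perm = 50),
               "at least 100")
})

test_that("cluster labeling uses face connectivity only", {
  supra <- array(FALSE, c(4, 4, 1))
  supra[1, 1, 1] <- TRUE
  supra[2, 1, 1] <- TRUE    # face neighbor of (1,1): same cluster
  supra[3, 2, 1] <- TRUE    # only diagonal contact: separate cluster
  lab <- connectoscope:::label_clusters(supra)
  expect_equal(lab[1, 1, 1], lab[2, 1, 1])
  expect_true(lab[3, 2, 1] != lab[1, 1, 1])
  expect_equal(max(lab), 2L)
  # third-dimension face adjacency joins across slices
  supra2 <- array(FALSE, c(3, 3, 2))
  supra2[2, 2, 1] <- TRUE
  supra2[2, 2, 2] <- TRUE
  lab2 <- connectoscope:::label_clusters(supra2)
  expect_equal(lab2[2, 2, 1], lab2[2, 2, 2])
})

test_that("BH-FDR agrees with the independent step-up implementation", {
  f <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), 0.05)
  expect_true(all(f$reject))
  f2 <- bh_fdr(c(0.04, 0.5, 0.9), 0.05)
  expect_false(any(f2$reject))
  f3 <- bh_fdr(rep(0, 5), 0.05)
  expect_true(all(f3$reject))
  expect_equal(f3$adjusted, rep(0, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "validation")
  set.seed(14)
  for (k in 1:200) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    f <- bh_fdr(p, 0.05)
    expect_identical(f$reject, bf_bh_reject(p, 0.05))
    expect_equal(f$adjusted, bf_bh_adjust(p), tolerance = 1e-12)
    expect_true(all(f$adjusted >= p - 1e-15))
  }
})

test_that("metric group tests have the contracted shape and flags", {
  set.seed(15)
  mk_curves <- function(shift = 0) {
    g <- matrix(rnorm(3 * 8), 3, 8, dimnames = list(NULL, NULL))
    colnames(g) <- connectoscope:::GLOBAL_METRIC_NAMES
    nodal <- lapply(connectoscope:::NODAL_METRIC_NAMES,
                    function(x) matrix(rnorm(3 * 10), 3, 10))
    names(nodal) <- connectoscope:::NODAL_METRIC_NAMES
    auc_nodal <- vapply(nodal, function(m) colMeans(m) + shift, numeric(10))
    structure(list(sparsity_grid = c(0.1, 0.2, 0.3), global = g,
                   nodal = nodal,
                   auc_global = colMeans(g) + shift,
                   auc_nodal = auc_nodal),
              class = "metric_curves")
  }
  curves <- c(lapply(1:6, function(i) mk_curves(0.1)),
              lapply(1:6, function(i) mk_curves(0)))
  group <- rep(c(1, 0), each = 6)
  tab <- metric_group_tests(curves, group, q = 0.05)
  expect_equal(nrow(tab), 8 + 6 * 10)
  expect_true(all(tab$p_fdr >= tab$p - 1e-15))
  expect_identical(tab$significant, tab$p_fdr <= 0.05)
  tab2 <- metric_group_tests(curves, group, q = 0.05)
  expect_identical(tab, tab2)
  expect_error(metric_group_tests(curves[1:3], group), "mismatch")
})
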