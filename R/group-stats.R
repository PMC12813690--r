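design_matrix <- function(group, covariates = NULL, n = length(group)) {
  X <- cbind(intercept = 1, group = as.numeric(group))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    X <- cbind(X, covariates)
  }
  X
}

# vectorized GLM group-effect t: Y is n x V, one column per test
glm_group_t_mat <- function(Y, group, covariates = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  X <- design_matrix(group, covariates, n)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("collinearity error: design is rank deficient")
  df <- n - ncol(X)
  if (df < 1L) stop("too few subjects for the design")
  coefs <- qr.coef(qr_x, Y)
  res <- Y - X %*% coefs
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  t_vals <- ifelse(se > 0, coefs[2, ] / se, 0)
  p_vals <- 2 * stats::pt(-abs(t_vals), df)
  list(t = t_vals, p = p_vals, df = df)
}

#' Covariate-adjusted group comparison
#'
#' Least-squares fit of `value ~ intercept + group + covariates`; reports
#' the t statistic on the group coefficient with its two-sided p-value.
#' Without covariates this equals the pooled two-sample Student's t-test.
#'
#' @param values numeric vector, one value per subject
#' @param group binary labels (1 = patients, 0 = controls)
#' @param covariates optional subject x K matrix (e.g. age, sex, education,
#'   BMI)
#' @return list with `t`, `p`, `df`
#' @export
glm_group_t <- function(values, group, covariates = NULL) {
  out <- glm_group_t_mat(matrix(values, ncol = 1L), group, covariates)
  list(t = unname(out$t), p = unname(out$p), df = out$df)
}

#' Voxelwise group-difference map
#'
#' Applies [glm_group_t()] at every in-mask voxel of a stack of subject
#' maps.
#'
#' @param maps list of `voxel_map`s sharing grid and mask
#' @param group binary labels
#' @param covariates optional covariate matrix
#' @return object of class `stat_map`: `t_values` and `p_values` (3D
#'   arrays), `mask`, `df`
#' @export
voxelwise_group_map <- function(maps, group, covariates = NULL) {
  mask <- maps[[1]]$mask
  same <- vapply(maps, function(m) identical(dim(m$values), dim(mask)) &&
                   identical(m$mask, mask), logical(1))
  if (!all(same)) stop("alignment error: maps must share grid and mask")
  idx <- which(mask)
  Y <- t(vapply(maps, function(m) m$values[idx], numeric(length(idx))))
  fit <- glm_group_t_mat(Y, group, covariates)
  t_arr <- array(0, dim = dim(mask)); t_arr[idx] <- fit$t
  p_arr <- array(1, dim = dim(mask)); p_arr[idx] <- fit$p
  structure(list(t_values = t_arr, p_values = p_arr, mask = mask,
                 df = fit$df),
            class = "stat_map")
}

# 6-connectivity (faces only) connected components of a 3D logical array
label_clusters <- function(supra) {
  d <- dim(supra)
  idx <- which(supra)
  labels <- array(0L, dim = d)
  if (length(idx) == 0L) return(labels)
  pos <- integer(prod(d)); pos[idx] <- seq_along(idx)
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  co <- arrayInd(idx, d)
  strides <- c(1L, d[1], d[1] * d[2])
  for (ax in 1:3) {
    ok <- co[, ax] < d[ax]
    nb <- idx[ok] + strides[ax]
    nbp <- pos[nb]
    hit <- nbp > 0L
    a <- which(ok)[hit]; b <- nbp[hit]
    for (k in seq_along(a)) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  labels[idx] <- as.integer(factor(roots))
  labels
}

#' Permutation-based cluster correction
#'
#' Two-tailed voxel-level thresholding at `voxel_p` followed by
#' cluster-extent correction: group labels are permuted `n_perm` times, the
#' maximum suprathreshold cluster size per permutation forms the null, and
#' an observed cluster survives when its size exceeds the `1 - cluster_p`
#' quantile of that null. Clusters are face-connected (6-connectivity)
#' components. Covariates stay attached to their subjects; only the group
#' column is permuted.
#'
#' @param maps list of `voxel_map`s
#' @param group binary labels
#' @param covariates optional covariate matrix
#' @param n_perm number of permutations (>= 100)
#' @param voxel_p two-tailed voxel-level threshold (default 0.01)
#' @param cluster_p cluster-level threshold (default 0.01)
#' @param seed integer seed
#' @return `stat_map` with `cluster_labels` (3D integer array) and
#'   `surviving_clusters` (data.frame: cluster, size, peak voxel,
#'   corrected_p, survives)
#' @export
permutation_cluster_correct <- function(maps, group, covariates = NULL,
                                        n_perm = 1000L, voxel_p = 0.01,
                                        cluster_p = 0.01, seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  if (n_perm < ceiling(1 / cluster_p)) {
    warning("n_perm too small to resolve the requested cluster_p")
  }
  sm <- voxelwise_group_map(maps, group, covariates)
  mask <- sm$mask
  idx <- which(mask)
  Y <- t(vapply(maps, function(m) m$values[idx], numeric(length(idx))))
  n <- nrow(Y)
  t_crit <- stats::qt(1 - voxel_p / 2, sm$df)

  supra <- array(FALSE, dim = dim(mask))
  supra[idx] <- abs(sm$t_values[idx]) > t_crit
  labels <- label_clusters(supra)
  obs_sizes <- if (max(labels) > 0L) tabulate(labels[labels > 0L]) else integer(0)

  set.seed(as.integer(seed))
  max_null <- integer(n_perm)
  tmp <- array(FALSE, dim = dim(mask))
  for (b in seq_len(n_perm)) {
    gp <- sample(group)
    fit <- glm_group_t_mat(Y, gp, covariates)
    tmp[idx] <- abs(fit$t) > t_crit
    lb <- label_clusters(tmp)
    max_null[b] <- if (max(lb) > 0L) max(tabulate(lb[lb > 0L])) else 0L
  }
  cutoff <- stats::quantile(max_null, 1 - cluster_p, type = 1, names = FALSE)

  surviving <- data.frame(cluster = integer(0), size = integer(0),
                          peak_voxel = integer(0), corrected_p = numeric(0),
                          survives = logical(0))
  if (length(obs_sizes) > 0L) {
    rows <- lapply(seq_along(obs_sizes), function(cl) {
      members <- which(labels == cl)
      peak <- members[which.max(abs(sm$t_values[members]))]
      data.frame(cluster = cl, size = obs_sizes[cl], peak_voxel = peak,
                 corrected_p = (1 + sum(max_null >= obs_sizes[cl])) / (n_perm + 1),
                 survives = obs_sizes[cl] > cutoff)
    })
    surviving <- do.call(rbind, rows)
  }
  sm$cluster_labels <- labels
  sm$surviving_clusters <- surviving
  sm$null_max_sizes <- max_null
  sm$size_cutoff <- cutoff
  sm
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up adjustment; a hypothesis is rejected when its adjusted p-value
#' is at most `q`.
#'
#' @param p_values vector of p-values in `[0, 1]`
#' @param q FDR level (default 0.05)
#' @return list with `adjusted` and `reject`
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("validation error: p-values must lie in [0, 1]")
  }
  adjusted <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= q)
}

#' Group tests on network-metric AUCs
#'
#' Two-sample Student's t-test (optionally covariate-adjusted) per global
#' metric AUC and per (node, nodal metric) AUC, with Benjamini-Hochberg
#' correction applied within each metric family (the 8 global metrics form
#' one family; each nodal metric's 90 node tests form their own family).
#'
#' @param curves_list per-subject list of `metric_curves`
#' @param group binary labels
#' @param q FDR level
#' @param covariates optional covariate matrix (default none, matching a
#'   plain two-sample test; supply to adjust)
#' @return data.frame with 8 global + 6 x nodes rows: `metric`, `node`,
#'   group means and sds, `t`, `p`, `p_fdr`, `significant`
#' @export
metric_group_tests <- function(curves_list, group, q = 0.05,
                               covariates = NULL) {
  if (length(curves_list) != length(group)) stop("input error: curves/labels mismatch")
  if (any(vapply(curves_list, is.null, logical(1)))) {
    stop("input error: missing curves")
  }
  g1 <- group == 1
  test_block <- function(Y, metric, node) {
    fit <- glm_group_t_mat(Y, group, covariates)
    data.frame(metric = metric, node = node,
               mean_patients = colMeans(Y[g1, , drop = FALSE]),
               sd_patients = apply(Y[g1, , drop = FALSE], 2, stats::sd),
               mean_controls = colMeans(Y[!g1, , drop = FALSE]),
               sd_controls = apply(Y[!g1, , drop = FALSE], 2, stats::sd),
               t = fit$t, p = fit$p, row.names = NULL)
  }
  G <- t(vapply(curves_list, function(cv) cv$auc_global, numeric(8L)))
  out <- test_block(G, GLOBAL_METRIC_NAMES, NA_integer_)
  fdr <- bh_fdr(out$p, q)
  out$p_fdr <- fdr$adjusted
  out$significant <- fdr$reject
  n_nodes <- nrow(curves_list[[1]]$auc_nodal)
  for (k in seq_along(NODAL_METRIC_NAMES)) {
    Yk <- t(vapply(curves_list, function(cv) cv$auc_nodal[, k],
                   numeric(n_nodes)))
    blk <- test_block(Yk, NODAL_METRIC_NAMES[k], seq_len(n_nodes))
    fdr <- bh_fdr(blk$p, q)
    blk$p_fdr <- fdr$adjusted
    blk$significant <- fdr$reject
    out <- rbind(out, blk)
  }
  out
}
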