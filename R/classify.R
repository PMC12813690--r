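#' Edge-index bookkeeping for the connection block
#'
#' The C block stores the upper triangle in lexicographic `(i, j)` order:
#' index 1 is edge (1, 2), index `n(n-1)/2` is edge (n-1, n).
#'
#' @param k edge index (1-based)
#' @param n node count
#' @return `edge_index_to_pair`: integer vector `c(i, j)`;
#'   `pair_to_edge_index`: integer index
#' @export
edge_index_to_pair <- function(k, n = 90L) {
  p <- upper_tri_pairs(n)
  c(p$i[k], p$j[k])
}

#' @rdname edge_index_to_pair
#' @param i,j node pair with `i < j`
#' @export
pair_to_edge_index <- function(i, j, n = 90L) {
  stopifnot(i < j)
  as.integer((i - 1L) * n - i * (i - 1L) / 2 + (j - i))
}

#' Assemble the per-subject feature blocks
#'
#' C: Fisher-z edge weights (upper triangle, lexicographic order); G: the 8
#' global-metric AUCs; N: the 540 nodal-metric AUCs in metric-major order
#' (all 90 nodes of the first metric, then the second, ...).
#'
#' @param z_matrix `connectivity_matrix` with `z` filled ([fisher_z()])
#' @param curves `metric_curves` for the same subject
#' @param subject_id,group identifiers stored with the blocks
#' @return object of class `feature_blocks` with elements `C`, `G`, `N`,
#'   `subject_id`, `group`
#' @export
assemble_features <- function(z_matrix, curves, subject_id = NA_character_,
                              group = NA_integer_) {
  if (is.null(z_matrix$z)) stop("assembly error: Fisher-z matrix missing")
  if (!inherits(curves, "metric_curves")) stop("assembly error: curves missing")
  n <- nrow(z_matrix$z)
  p <- upper_tri_pairs(n)
  C <- z_matrix$z[cbind(p$i, p$j)]
  G <- as.numeric(curves$auc_global)
  N <- as.numeric(curves$auc_nodal)
  structure(list(C = C, G = G, N = N, subject_id = subject_id,
                 group = as.integer(group)),
            class = "feature_blocks")
}

#' Two-sample t-test feature selection
#'
#' Selects the feature indices whose pooled two-sample t-test p-value falls
#' below `alpha`; computed on the training split only.
#'
#' @param features subjects x features matrix
#' @param labels binary labels
#' @param alpha selection threshold (default 0.05)
#' @return integer index vector
#' @export
ttest_select <- function(features, labels, alpha = 0.05) {
  X <- as.matrix(features)
  g1 <- labels == 1; g0 <- !g1
  n1 <- sum(g1); n0 <- sum(g0)
  if (n1 < 2L || n0 < 2L) stop("split error: need >= 2 subjects per class")
  m1 <- colMeans(X[g1, , drop = FALSE]); m0 <- colMeans(X[g0, , drop = FALSE])
  v1 <- colSums(sweep(X[g1, , drop = FALSE], 2L, m1)^2)
  v0 <- colSums(sweep(X[g0, , drop = FALSE], 2L, m0)^2)
  sp2 <- (v1 + v0) / (n1 + n0 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  t_vals <- ifelse(se > 0, (m1 - m0) / se, 0)
  p_vals <- 2 * stats::pt(-abs(t_vals), n1 + n0 - 2)
  which(p_vals < alpha)
}

# z-score by train statistics (zero-variance features dropped), linear
# kernel, trace-normalized to the training-set size. Also returns the
# scaled feature matrices Z with K = Z Z' for the linear fast path.
build_block_kernel <- function(train, test = NULL, selected = NULL) {
  Xtr <- as.matrix(train)
  if (!is.null(selected)) Xtr <- Xtr[, selected, drop = FALSE]
  n <- nrow(Xtr)
  if (ncol(Xtr) == 0L) {
    n_te <- if (is.null(test)) 0L else nrow(as.matrix(test))
    return(list(K = matrix(0, n, n),
                K_cross = if (is.null(test)) NULL else matrix(0, n_te, n),
                Z = matrix(0, n, 0),
                Z_cross = if (is.null(test)) NULL else matrix(0, n_te, 0)))
  }
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2L, stats::sd)
  keep <- sdv > 0
  Xtr <- scale(Xtr[, keep, drop = FALSE], center = mu[keep], scale = sdv[keep])
  K <- tcrossprod(Xtr)
  tr <- sum(diag(K))
  fac <- if (tr > 0) n / tr else 1
  K <- K * fac
  Z <- Xtr * sqrt(fac)
  K_cross <- NULL
  Z_cross <- NULL
  if (!is.null(test)) {
    Xte <- as.matrix(test)
    if (!is.null(selected)) Xte <- Xte[, selected, drop = FALSE]
    Xte <- scale(Xte[, keep, drop = FALSE], center = mu[keep],
                 scale = sdv[keep])
    K_cross <- tcrossprod(Xte, Xtr) * fac
    Z_cross <- Xte * sqrt(fac)
  }
  list(K = K, K_cross = K_cross, Z = Z, Z_cross = Z_cross)
}

#' Per-block kernel matrices
#'
#' For each feature block: z-score features by training statistics (fit on
#' the training subjects only; zero-variance features dropped), form the
#' linear Gram matrix, and trace-normalize it to the training-set size.
#'
#' @param blocks named list of subjects x features matrices (training rows)
#' @param test optional matching list of test rows
#' @param selected optional named list of selected column indices per block
#' @return named list, each element a list with `K` (train Gram) and
#'   `K_cross` (test x train)
#' @export
build_kernels <- function(blocks, test = NULL, selected = NULL) {
  out <- lapply(names(blocks), function(b) {
    build_block_kernel(blocks[[b]],
                       test = if (is.null(test)) NULL else test[[b]],
                       selected = if (is.null(selected)) NULL else selected[[b]])
  })
  names(out) <- names(blocks)
  out
}

combine_kernels <- function(K_list, betas) {
  Reduce(`+`, Map(function(K, b) K * b, K_list, as.list(betas)))
}

#' Train a multi-kernel SVM
#'
#' Soft-margin SVM on the convex kernel combination `K = sum(beta_m K_m)`.
#' Decision values are oriented so positive means group 1 (patients).
#'
#' @param kernels list of aligned train Gram matrices
#' @param betas nonnegative weights summing to 1
#' @param labels binary labels (1 = patients, 0 = controls)
#' @param C soft-margin cost
#' @return model list with the fitted `ksvm`, support indices and the
#'   decision-sign orientation
#' @export
mk_svm_train <- function(kernels, betas, labels, C = 1) {
  stopifnot(all(betas >= 0), abs(sum(betas) - 1) < 1e-8)
  if (length(unique(labels)) < 2L) {
    stop("degenerate-training error: single-class labels")
  }
  K <- combine_kernels(kernels, betas)
  fit_svm(K, labels, C)
}

fit_svm <- function(K, labels, C) {
  yf <- factor(labels, levels = c(0, 1))
  model <- kernlab::ksvm(kernlab::as.kernelMatrix(K), yf, type = "C-svc",
                         C = C, scaled = FALSE)
  sv <- kernlab::SVindex(model)
  alpha <- unlist(kernlab::coef(model))
  b <- kernlab::b(model)
  # decision values via the support expansion (avoids S4 predict overhead);
  # orientation fixed so positive decisions mean group 1 (patients)
  dec_tr <- as.numeric(K[, sv, drop = FALSE] %*% alpha) - b
  orient <- 1
  if (mean(dec_tr[labels == 1]) < mean(dec_tr[labels == 0])) orient <- -1
  list(sv_index = sv, alpha = alpha, b = b, orient = orient)
}

svm_predict <- function(fit, K_cross) {
  dec <- (as.numeric(K_cross[, fit$sv_index, drop = FALSE] %*% fit$alpha) -
            fit$b) * fit$orient
  list(pred = as.integer(dec > 0), decision = dec)
}

# linear-kernel fast path (LIBSVM via e1071): on the sqrt(beta)-scaled,
# trace-normalized block features this is identical to the multi-kernel
# machine, since sum(beta_m Z_m Z_m') = [sqrt(beta) Z][sqrt(beta) Z]'
svm_fit_linear <- function(X, labels, C) {
  if (ncol(X) == 0L) {
    maj <- as.integer(mean(labels) >= 0.5)
    return(list(empty = TRUE, majority = maj))
  }
  yf <- factor(labels, levels = c(0, 1))
  m <- e1071::svm(X, yf, kernel = "linear", cost = C, scale = FALSE)
  w <- as.numeric(t(m$coefs) %*% m$SV)
  dec_tr <- as.numeric(X %*% w) - m$rho
  orient <- if (mean(dec_tr[labels == 1]) < mean(dec_tr[labels == 0])) -1 else 1
  list(empty = FALSE, w = w, rho = m$rho, orient = orient)
}

svm_predict_linear <- function(fit, X) {
  if (isTRUE(fit$empty)) {
    return(list(pred = rep(fit$majority, nrow(X)),
                decision = rep(0, nrow(X))))
  }
  dec <- (as.numeric(X %*% fit$w) - fit$rho) * fit$orient
  list(pred = as.integer(dec > 0), decision = dec)
}

# simplex lattice with the given step over n_blocks weights (lexicographic)
beta_lattice <- function(n_blocks, step = 0.1) {
  if (n_blocks == 1L) return(matrix(1, 1, 1))
  k <- round(1 / step)
  grids <- rep(list(0:k), n_blocks - 1L)
  combos <- as.matrix(expand.grid(grids))
  keep <- rowSums(combos) <= k
  combos <- combos[keep, , drop = FALSE]
  betas <- cbind(combos, k - rowSums(combos)) / k
  betas <- betas[do.call(order, as.data.frame(betas)), , drop = FALSE]
  unname(betas)
}

#' Classification performance summary
#'
#' Accuracy, sensitivity (group 1 = patients = positive), specificity, the
#' ROC curve from a decision-value sweep, and its area computed by the rank
#' (Mann-Whitney) statistic.
#'
#' @param predictions predicted binary labels
#' @param truth true binary labels
#' @param decision_values continuous scores, larger = more patient-like
#' @return list with `accuracy`, `sensitivity`, `specificity`, `roc`
#'   (data.frame of FPR/TPR points), `auc`
#' @export
performance_summary <- function(predictions, truth, decision_values) {
  stopifnot(length(predictions) == length(truth),
            length(decision_values) == length(truth))
  if (length(unique(truth)) < 2L) {
    stop("undefined-sensitivity error: single-class truth")
  }
  tp <- sum(predictions == 1 & truth == 1)
  fn <- sum(predictions == 0 & truth == 1)
  tn <- sum(predictions == 0 & truth == 0)
  fp <- sum(predictions == 1 & truth == 0)
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  thr <- c(Inf, sort(unique(decision_values), decreasing = TRUE))
  roc <- t(vapply(thr, function(th) {
    c(fpr = sum(decision_values >= th & truth == 0) / n0,
      tpr = sum(decision_values >= th & truth == 1) / n1)
  }, numeric(2)))
  ranks <- rank(decision_values)
  auc <- (sum(ranks[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(accuracy = (tp + tn) / length(truth),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       roc = as.data.frame(roc), auc = auc)
}

#' Consensus connections across outer folds
#'
#' The intersection of the connection features selected in every outer
#' fold: the stable discriminative edges. If any fold selected nothing the
#' consensus is empty.
#'
#' @param per_fold_selected list of C-index sets, one per outer fold
#' @param n_nodes node count (default 90)
#' @param network_table optional node annotation from
#'   [load_network_labels()]
#' @param features,labels optional full C-feature matrix and labels used to
#'   attach a whole-sample two-sample p-value per consensus edge
#' @return data.frame: `index`, `node_i`, `node_j`, names/networks when
#'   available, and `p` when features are supplied
#' @export
consensus_connections <- function(per_fold_selected, n_nodes = 90L,
                                  network_table = NULL, features = NULL,
                                  labels = NULL) {
  consensus <- Reduce(intersect, per_fold_selected)
  consensus <- sort(consensus)
  p <- upper_tri_pairs(n_nodes)
  out <- data.frame(index = consensus,
                    node_i = p$i[consensus], node_j = p$j[consensus])
  if (!is.null(network_table)) {
    out$name_i <- network_table$name[out$node_i]
    out$name_j <- network_table$name[out$node_j]
    out$network_i <- network_table$network[out$node_i]
    out$network_j <- network_table$network[out$node_j]
  }
  if (!is.null(features) && !is.null(labels) && nrow(out) > 0L) {
    X <- as.matrix(features)[, consensus, drop = FALSE]
    pv <- vapply(seq_len(ncol(X)), function(k)
      stats::t.test(X[labels == 1, k], X[labels == 0, k],
                    var.equal = TRUE)$p.value, numeric(1))
    out$p <- pv
  }
  out
}

parse_combo <- function(combo) {
  blocks <- strsplit(toupper(combo), "\\+")[[1]]
  blocks <- trimws(blocks)
  if (!all(blocks %in% c("C", "G", "N")) || length(blocks) == 0L) {
    stop("configuration error: combo must be a +-combination of C, G, N")
  }
  unique(blocks)
}

#' Nested leave-one-out cross-validation with multi-kernel SVM
#'
#' Outer loop: hold out one subject. Inner loop: leave-one-out on the
#' remaining subjects selects the cost `C` and kernel weights `betas`
#' maximizing inner accuracy (ties broken toward smaller `C`, then
#' lexicographically smaller betas). Feature selection (t-test at `alpha`
#' on the C and N blocks; G always passed whole) and feature standardizers
#' are refit inside every training split -- per inner fold during tuning
#' and per outer fold for the final model -- so no information from any
#' held-out subject enters selection or tuning, and inner accuracy is an
#' honest estimate rather than a selection-biased one. The per-fold
#' selected C-sets reported for consensus are the outer-fold selections.
#'
#' @param features list of `feature_blocks`, one per subject
#' @param combo feature combination, e.g. `"C"`, `"G+N"`, `"C+G+N"`
#' @param alpha t-test selection threshold (default 0.05)
#' @param C_grid soft-margin cost grid (default `2^(-5:5)`)
#' @param beta_step simplex lattice step for the kernel weights
#'   (default 0.1)
#' @param seed integer seed (recorded; the procedure itself is
#'   deterministic)
#' @return object of class `classification_result`: `folds` (data.frame of
#'   per-fold predictions, decisions and chosen hyperparameters),
#'   `selected_C`/`selected_N` (per-fold index sets), `consensus`
#'   (data.frame), `summary` (from [performance_summary()])
#' @export
nested_loocv <- function(features, combo = "C+G+N", alpha = 0.05,
                         C_grid = 2^(-5:5), beta_step = 0.1, seed = 1L) {
  if (length(C_grid) == 0L) stop("configuration error: empty C grid")
  blocks_active <- parse_combo(combo)
  y <- vapply(features, function(f) f$group, integer(1))
  n <- length(y)
  if (sum(y == 1) < 3L || sum(y == 0) < 3L) {
    stop("need at least 3 subjects per class")
  }
  mats <- list(C = do.call(rbind, lapply(features, `[[`, "C")),
               G = do.call(rbind, lapply(features, `[[`, "G")),
               N = do.call(rbind, lapply(features, `[[`, "N")))
  mats <- mats[blocks_active]
  betas_grid <- beta_lattice(length(blocks_active), beta_step)
  C_grid <- sort(C_grid)

  fold_pred <- integer(n); fold_dec <- numeric(n)
  fold_C <- numeric(n); fold_betas <- vector("list", n)
  selected_C <- vector("list", n); selected_N <- vector("list", n)

  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    ytr <- y[tr]
    sel <- lapply(blocks_active, function(b) {
      if (b %in% c("C", "N")) ttest_select(mats[[b]][tr, , drop = FALSE],
                                           ytr, alpha)
      else seq_len(ncol(mats[[b]]))
    })
    names(sel) <- blocks_active
    selected_C[[i]] <- if ("C" %in% blocks_active) sel$C else integer(0)
    selected_N[[i]] <- if ("N" %in% blocks_active) sel$N else integer(0)

    kern <- build_kernels(lapply(mats, function(M) M[tr, , drop = FALSE]),
                          test = lapply(mats, function(M) M[i, , drop = FALSE]),
                          selected = sel)

    combine_feats <- function(kern_list, field, betas) {
      parts <- Map(function(k, b) if (b > 0) k[[field]] * sqrt(b) else NULL,
                   kern_list, as.list(betas))
      parts <- Filter(Negate(is.null), parts)
      if (length(parts) == 0L) matrix(0, nrow(kern_list[[1]][[field]]), 0) else
        do.call(cbind, parts)
    }

    # inner LOOCV: selection and standardization refit inside every inner
    # fold so the tuning accuracy is unbiased. A singleton grid needs no
    # inner evaluation.
    n_tr <- length(tr)
    if (nrow(betas_grid) * length(C_grid) == 1L) {
      best <- list(acc = NA_real_, C = C_grid[1], betas = betas_grid[1, ])
      fit <- svm_fit_linear(combine_feats(kern, "Z", best$betas), ytr, best$C)
      pr <- svm_predict_linear(fit, combine_feats(kern, "Z_cross", best$betas))
      fold_pred[i] <- pr$pred
      fold_dec[i] <- pr$decision
      fold_C[i] <- best$C
      fold_betas[[i]] <- stats::setNames(best$betas, blocks_active)
      next
    }
    correct <- matrix(0L, nrow(betas_grid), length(C_grid))
    for (j in seq_len(n_tr)) {
      inn <- tr[-j]
      if (length(unique(y[inn])) < 2L) next
      sel_j <- lapply(blocks_active, function(b) {
        if (b %in% c("C", "N")) ttest_select(mats[[b]][inn, , drop = FALSE],
                                             y[inn], alpha)
        else seq_len(ncol(mats[[b]]))
      })
      names(sel_j) <- blocks_active
      kern_j <- build_kernels(lapply(mats, function(M) M[inn, , drop = FALSE]),
                              test = lapply(mats, function(M)
                                M[tr[j], , drop = FALSE]),
                              selected = sel_j)
      for (bi in seq_len(nrow(betas_grid))) {
        Xb <- combine_feats(kern_j, "Z", betas_grid[bi, ])
        xb <- combine_feats(kern_j, "Z_cross", betas_grid[bi, ])
        for (ci in seq_along(C_grid)) {
          fit <- svm_fit_linear(Xb, y[inn], C_grid[ci])
          pr <- svm_predict_linear(fit, xb)
          if (pr$pred == ytr[j]) correct[bi, ci] <- correct[bi, ci] + 1L
        }
      }
    }
    # best config: max inner accuracy, ties -> smallest C, then
    # lexicographically smallest betas (beta rows are already ordered)
    cfg <- expand.grid(bi = seq_len(nrow(betas_grid)),
                       ci = seq_along(C_grid))
    cfg$acc <- correct[as.matrix(cfg[, c("bi", "ci")])] / n_tr
    cfg <- cfg[order(-cfg$acc, C_grid[cfg$ci], cfg$bi), ]
    best <- list(acc = cfg$acc[1], C = C_grid[cfg$ci[1]],
                 betas = betas_grid[cfg$bi[1], ])

    fit <- svm_fit_linear(combine_feats(kern, "Z", best$betas), ytr, best$C)
    pr <- svm_predict_linear(fit, combine_feats(kern, "Z_cross", best$betas))
    fold_pred[i] <- pr$pred
    fold_dec[i] <- pr$decision
    fold_C[i] <- best$C
    fold_betas[[i]] <- stats::setNames(best$betas, blocks_active)
  }

  summary <- performance_summary(fold_pred, y, fold_dec)
  n_nodes <- if (!is.null(mats$C)) round((1 + sqrt(1 + 8 * ncol(mats$C))) / 2) else 90L
  consensus <- if ("C" %in% blocks_active) {
    consensus_connections(selected_C, n_nodes = n_nodes,
                          network_table = if (n_nodes == 90L)
                            default_network_table() else NULL,
                          features = mats$C, labels = y)
  } else data.frame()
  structure(list(folds = data.frame(subject = seq_len(n), truth = y,
                                    predicted = fold_pred,
                                    decision = fold_dec, C = fold_C),
                 betas = fold_betas,
                 selected_C = selected_C, selected_N = selected_N,
                 consensus = consensus, summary = summary,
                 combo = paste(blocks_active, collapse = "+"),
                 seed = as.integer(seed)),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("classification_result [%s]: accuracy %.3f, sensitivity %.3f, specificity %.3f, AUC %.3f; %d consensus connections\n",
              x$combo, s$accuracy, s$sensitivity, s$specificity, s$auc,
              nrow(x$consensus)))
  invisible(x)
}
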