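# Independent brute-force oracles used across the suite. These are written
# from first principles (Floyd-Warshall, exhaustive path enumeration, direct
# formula sums) and deliberately share no code with the package internals.

# all-pairs shortest paths by Floyd-Warshall
bf_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[adj] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# betweenness by exhaustive enumeration of all shortest simple paths
bf_betweenness <- function(adj) {
  n <- nrow(adj)
  D <- bf_distances(adj)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      dst <- D[s, t]
      if (!is.finite(dst) || dst < 2) next   # length-1 paths have no interior
      total <- 0
      through <- numeric(n)
      rec <- function(v, visited, len) {
        if (len == dst) {
          if (v == t) {
            total <<- total + 1
            mid <- setdiff(visited, c(s, t))
            through[mid] <<- through[mid] + 1
          }
          return(invisible())
        }
        for (w in which(adj[v, ])) {
          if (!(w %in% visited)) rec(w, c(visited, w), len + 1)
        }
      }
      rec(s, s, 0)
      if (total > 0) btw <- btw + through / total
    }
  }
  btw
}

# per-node clustering by direct neighbor-edge counting
bf_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ])
    k <- length(nb)
    if (k < 2) return(0)
    e <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) if (adj[nb[a], nb[b]]) e <- e + 1
    }
    e / (k * (k - 1) / 2)
  }, numeric(1))
}

bf_global_efficiency <- function(adj) {
  D <- bf_distances(adj)
  n <- nrow(adj)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(D[i, j])) tot <- tot + 1 / D[i, j]
  }
  tot / (n * (n - 1))
}

bf_nodal_efficiency <- function(adj) {
  D <- bf_distances(adj)
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    s <- 0
    for (j in seq_len(n)) if (j != i && is.finite(D[i, j])) s <- s + 1 / D[i, j]
    s / (n - 1)
  }, numeric(1))
}

bf_local_efficiency <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ])
    if (length(nb) < 2) return(0)
    bf_global_efficiency(adj[nb, nb, drop = FALSE])
  }, numeric(1))
}

bf_nodal_shortest_path <- function(adj) {
  D <- bf_distances(adj)
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (length(d) == 0) 0 else mean(d)
  }, numeric(1))
}

bf_char_path_length <- function(adj) {
  D <- bf_distances(adj)
  off <- D[row(D) != col(D)]
  off <- off[is.finite(off)]
  if (length(off) == 0) 0 else mean(off)
}

# Kendall W by the rank-sum formula, written with explicit loops
bf_kendall_w <- function(X) {
  m <- nrow(X); n <- ncol(X)
  R <- matrix(0, m, n)
  for (i in seq_len(m)) R[i, ] <- rank(X[i, ])
  Ri <- numeric(n)
  for (j in seq_len(n)) Ri[j] <- sum(R[, j])
  Rbar <- mean(Ri)
  S <- sum((Ri - Rbar)^2)
  12 * S / (m^2 * (n^3 - n))
}

# one-sided DFT amplitude spectrum by direct trigonometric sums
bf_amplitude_spectrum <- function(x, tr) {
  n <- length(x)
  kmax <- floor(n / 2)
  amp <- numeric(kmax)
  for (k in seq_len(kmax)) {
    re <- sum(x * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(x * sin(-2 * pi * k * (0:(n - 1)) / n))
    amp[k] <- 2 * sqrt(re^2 + im^2) / n
  }
  list(amp = amp, freqs = seq_len(kmax) / (n * tr))
}

bf_alff <- function(x, tr, band) {
  sp <- bf_amplitude_spectrum(x, tr)
  inb <- sp$freqs >= band[1] - 1e-12 & sp$freqs <= band[2] + 1e-12
  mean(sp$amp[inb])
}

bf_falff <- function(x, tr, band) {
  sp <- bf_amplitude_spectrum(x, tr)
  inb <- sp$freqs >= band[1] - 1e-12 & sp$freqs <= band[2] + 1e-12
  sum(sp$amp[inb]) / sum(sp$amp)
}

# Benjamini-Hochberg step-up by the textbook procedure
bf_bh_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k <- 0
  for (i in seq_len(m)) if (p[ord[i]] <= i * q / m) k <- i
  reject <- rep(FALSE, m)
  if (k > 0) reject[ord[seq_len(k)]] <- TRUE
  reject
}

bf_bh_adjust <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, m * p[ord[i]] / i)
    adj[ord[i]] <- val
    prev <- val
  }
  adj
}

# GLM group t by explicit normal equations
bf_glm_t <- function(y, group, covariates = NULL) {
  X <- cbind(1, group)
  if (!is.null(covariates)) X <- cbind(X, covariates)
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * solve(XtX)[2, 2])
  t_val <- b[2] / se
  list(t = as.numeric(t_val), p = 2 * pt(-abs(t_val), df), df = df)
}

# enumerate every labeled graph on n nodes as logical adjacency matrices
all_graphs <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- nrow(pairs)
  lapply(seq_len(2^m) - 1L, function(bits) {
    adj <- matrix(FALSE, n, n)
    on <- bitwAnd(bits, 2^(seq_len(m) - 1L)) > 0
    adj[pairs[on, , drop = FALSE]] <- TRUE
    adj | t(adj)
  })
}

is_connected_adj <- function(adj) {
  n <- nrow(adj)
  seen <- c(1L)
  frontier <- c(1L)
  while (length(frontier) > 0) {
    nxt <- setdiff(which(rowSums(adj[, frontier, drop = FALSE]) > 0), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == n
}

random_connected_graph <- function(n, p) {
  repeat {
    adj <- matrix(FALSE, n, n)
    up <- which(upper.tri(adj))
    adj[up] <- runif(length(up)) < p
    adj <- adj | t(adj)
    if (is_connected_adj(adj)) return(adj)
  }
}

# small helper: wrap an adjacency as the package's binary_graph
as_bg <- function(adj) {
  structure(list(adjacency = adj, sparsity = NA_real_,
                 edge_count = sum(adj) / 2),
            class = "binary_graph")
}

# quick ROI-level feature cohort for classification tests: draws per-subject
# Fisher-z edge features directly from the planted group correlation models
# (fast stand-in for the full rendering pipeline where voxel data is not
# the point of the test)
simulate_edge_features <- function(n1, n0, n_rois, n_volumes, edge_effect,
                                   seed, tr = 2, band = c(0.01, 0.08)) {
  base <- default_base_corr(n_rois)
  spec1 <- if (is.null(edge_effect)) base else
    connectoscope:::apply_edge_effect(base, edge_effect)
  feats <- vector("list", n1 + n0)
  for (i in seq_len(n1 + n0)) {
    g <- if (i <= n1) 1L else 0L
    s <- simulate_roi_signals(if (g == 1L) spec1 else base, n_volumes, tr,
                              band, seed = seed * 3000L + i)
    cm <- fisher_z(pearson_matrix(t(s)))
    p <- connectoscope:::upper_tri_pairs(n_rois)
    feats[[i]] <- structure(list(C = cm$z[cbind(p$i, p$j)],
                                 G = numeric(0), N = numeric(0),
                                 subject_id = sprintf("s%02d", i),
                                 group = g),
                            class = "feature_blocks")
  }
  feats
}
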