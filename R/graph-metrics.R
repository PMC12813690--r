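as_igraph <- function(graph) {
  adj <- if (inherits(graph, "binary_graph")) graph$adjacency else graph
  igraph::graph_from_adjacency_matrix(adj * 1, mode = "undirected",
                                      diag = FALSE)
}

graph_adj <- function(graph) {
  if (inherits(graph, "binary_graph")) graph$adjacency else graph
}

#' Unweighted shortest-path distance matrix
#'
#' Breadth-first-search distances between all node pairs; unreachable pairs
#' are `Inf`. Implemented as simultaneous BFS from all sources via boolean
#' matrix products, which is fast for the dense 90-node graphs of the
#' sparsity series.
#'
#' @param graph `binary_graph` or logical adjacency matrix
#' @return numeric distance matrix
#' @export
shortest_paths <- function(graph) {
  adj <- graph_adj(graph)
  n <- nrow(adj)
  A <- matrix(as.numeric(adj), n, n)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  frontier <- adj & !diag(TRUE, n)
  visited <- adj | diag(TRUE, n)
  d <- 1
  while (any(frontier)) {
    D[frontier] <- d
    nxt <- ((frontier * 1) %*% A) > 0
    frontier <- nxt & !visited
    visited <- visited | nxt
    d <- d + 1
  }
  D
}

# per-node clustering coefficient: realized / possible neighbor edges,
# 0 for degree < 2
nodal_clustering <- function(adj) {
  A <- adj * 1
  deg <- rowSums(A)
  tri <- rowSums((A %*% A) * A) / 2     # = diag(A^3)/2, triangles per node
  poss <- deg * (deg - 1) / 2
  ifelse(deg >= 2, tri / pmax(poss, 1), 0)
}

# global efficiency of an adjacency matrix: mean over ordered pairs of 1/d
global_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2L) return(0)
  D <- shortest_paths(adj)
  inv <- 1 / D
  diag(inv) <- 0
  inv[is.infinite(D)] <- 0
  sum(inv) / (n * (n - 1))
}

# per-node local efficiency: global efficiency of the neighbor-induced
# subgraph, 0 for degree < 2
nodal_local_efficiency <- function(adj) {
  deg <- rowSums(adj)
  vapply(seq_len(nrow(adj)), function(v) {
    if (deg[v] < 2) return(0)
    nb <- which(adj[v, ])
    global_efficiency(adj[nb, nb, drop = FALSE])
  }, numeric(1))
}

# characteristic path length: mean shortest path over reachable pairs
char_path_length <- function(D) {
  off <- D[row(D) != col(D)]
  finite <- is.finite(off)
  if (any(finite)) mean(off[finite]) else 0
}

#' Global topology metrics of a binary graph
#'
#' Modularity `Q` (Newman modularity of the best partition found by
#' deterministic greedy agglomeration), global efficiency, local
#' efficiency, clustering coefficient and characteristic path length.
#' Conventions for sparse, possibly disconnected graphs: efficiencies use
#' `1/Inf = 0`; `Lp` averages over reachable pairs only; nodes of degree
#' < 2 contribute 0 to `Cp` and local efficiency. An empty graph returns
#' all zeros with `degenerate = TRUE`.
#'
#' @param graph `binary_graph` or logical adjacency matrix
#' @return list with `Q`, `E_global`, `E_local`, `Cp`, `Lp`, `degenerate`
#' @export
global_metrics <- function(graph) {
  adj <- graph_adj(graph)
  n <- nrow(adj)
  m <- sum(adj) / 2
  if (m == 0) {
    return(list(Q = 0, E_global = 0, E_local = 0, Cp = 0, Lp = 0,
                degenerate = TRUE))
  }
  D <- shortest_paths(adj)
  off <- row(D) != col(D)
  inv <- 1 / D[off]
  inv[is.infinite(D[off])] <- 0
  e_glob <- mean(inv)
  cp <- mean(nodal_clustering(adj))
  e_loc <- mean(nodal_local_efficiency(adj))
  fg <- igraph::cluster_fast_greedy(as_igraph(adj))
  q <- igraph::modularity(fg)
  list(Q = q, E_global = e_glob, E_local = e_loc, Cp = cp,
       Lp = char_path_length(D), degenerate = FALSE)
}

#' Nodal topology metrics of a binary graph
#'
#' Betweenness by Brandes accumulation (unnormalized pair counts, shortest
#' paths of equal length counted fractionally), degree centrality, nodal
#' clustering, nodal efficiency (mean inverse distance to all others),
#' nodal local efficiency (global efficiency of the neighbor subgraph), and
#' nodal shortest path (mean finite distance to reachable others).
#'
#' @param graph `binary_graph` or logical adjacency matrix
#' @return data.frame with one row per node and columns `betweenness`,
#'   `degree`, `nodal_Cp`, `nodal_efficiency`, `nodal_local_efficiency`,
#'   `nodal_shortest_path`
#' @export
nodal_metrics <- function(graph) {
  adj <- graph_adj(graph)
  D <- shortest_paths(adj)
  diag(D) <- NA
  inv <- 1 / D
  inv[is.infinite(D)] <- 0
  ne <- rowMeans(inv, na.rm = TRUE)
  nsp <- apply(D, 1L, function(d) {
    d <- d[is.finite(d)]
    if (length(d) == 0L) 0 else mean(d)
  })
  data.frame(betweenness = igraph::betweenness(as_igraph(adj),
                                               directed = FALSE),
             degree = rowSums(adj),
             nodal_Cp = nodal_clustering(adj),
             nodal_efficiency = ne,
             nodal_local_efficiency = nodal_local_efficiency(adj),
             nodal_shortest_path = nsp,
             row.names = NULL)
}

#' Degree-preserving null network
#'
#' Maslov-Sneppen double-edge swaps: the degree sequence is preserved
#' exactly and no self-loops or multi-edges are introduced. If the graph is
#' rigid (no valid swap exists, e.g. a triangle) the input is returned with
#' a warning.
#'
#' @param graph `binary_graph` or adjacency matrix
#' @param n_swaps number of attempted swaps (default 10 x edge count)
#' @param seed integer seed
#' @return `binary_graph` with the same sparsity
#' @export
rewire_null <- function(graph, n_swaps = NULL, seed = 1L) {
  adj <- graph_adj(graph)
  m <- sum(adj) / 2
  if (is.null(n_swaps)) n_swaps <- 10L * m
  set.seed(as.integer(seed))
  g <- igraph::rewire(as_igraph(adj), igraph::keeping_degseq(niter = n_swaps))
  el <- igraph::as_edgelist(g, names = FALSE)
  n <- nrow(adj)
  adj2 <- matrix(FALSE, n, n)
  adj2[el] <- TRUE
  adj2 <- adj2 | t(adj2)
  if (m >= 2 && identical(adj2, adj)) {
    warning("no rewiring achieved; graph may admit no valid swap")
  }
  out <- list(adjacency = adj2,
              sparsity = if (inherits(graph, "binary_graph")) graph$sparsity else NA_real_,
              edge_count = as.integer(m))
  class(out) <- "binary_graph"
  out
}

#' Small-world normalization against matched random networks
#'
#' `gamma` is the observed clustering coefficient divided by the mean over
#' `n_rand` degree-preserving rewired null networks; `lambda` likewise for
#' the characteristic path length; `sigma = gamma / lambda`.
#'
#' @param graph `binary_graph` or adjacency matrix
#' @param n_rand number of null networks (default 100)
#' @param n_swaps swaps per null (default 10 x edge count)
#' @param seed integer seed
#' @return list with `gamma`, `lambda`, `sigma`, `null_Cp`, `null_Lp`
#' @export
normalized_small_world <- function(graph, n_rand = 100L, n_swaps = NULL,
                                   seed = 1L) {
  adj <- graph_adj(graph)
  if (sum(adj) == 0) stop("degenerate-null error: empty graph")
  cp_lp <- function(a) {
    c(mean(nodal_clustering(a)), char_path_length(shortest_paths(a)))
  }
  obs <- cp_lp(adj)
  nulls <- vapply(seq_len(n_rand), function(k) {
    nk <- rewire_null(adj, n_swaps, seed = (as.integer(seed) + k) %% 2147483647L)
    cp_lp(nk$adjacency)
  }, numeric(2))
  null_cp <- mean(nulls[1, ]); null_lp <- mean(nulls[2, ])
  if (null_cp == 0 || null_lp == 0) {
    stop("degenerate-null error: null mean Cp or Lp is zero")
  }
  gamma <- obs[1] / null_cp
  lambda <- obs[2] / null_lp
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       null_Cp = null_cp, null_Lp = null_lp)
}

#' Area under a metric-versus-sparsity curve
#'
#' Trapezoidal integral of the metric values over the sparsity grid; the
#' threshold-free scalar summary used for group comparison and as
#' classifier features.
#'
#' @param curve metric values, one per grid point
#' @param grid sparsity values (strictly increasing, same length >= 2)
#' @return scalar
#' @export
metric_auc <- function(curve, grid) {
  if (length(curve) != length(grid)) stop("shape error: curve/grid length mismatch")
  if (length(grid) < 2L) stop("shape error: need at least 2 grid points")
  sum(diff(grid) * (curve[-1] + curve[-length(curve)]) / 2)
}

GLOBAL_METRIC_NAMES <- c("Q", "E_global", "E_local", "Cp", "gamma", "lambda",
                         "sigma", "Lp")
NODAL_METRIC_NAMES <- c("betweenness", "degree", "nodal_Cp",
                        "nodal_efficiency", "nodal_local_efficiency",
                        "nodal_shortest_path")

#' Metric curves over the sparsity grid for one subject
#'
#' Computes the eight global metrics (including the null-normalized
#' `gamma`, `lambda`, `sigma`) and six nodal metrics at every sparsity
#' threshold, plus the trapezoidal AUC of each curve. Deterministic given
#' the seed.
#'
#' @param graphs list of `binary_graph` from [graph_series()]
#' @param n_rand null networks per threshold (default 100)
#' @param seed integer seed for the null models
#' @param n_swaps swaps per null (default 10 x edge count)
#' @return object of class `metric_curves`: `sparsity_grid`, `global`
#'   (grid x 8 matrix), `nodal` (list of six grid x node matrices),
#'   `auc_global` (named length-8 vector), `auc_nodal` (node x 6 matrix)
#' @export
connectome_curves <- function(graphs, n_rand = 100L, seed = 1L,
                              n_swaps = NULL) {
  grid <- attr(graphs, "sparsity_grid")
  if (is.null(grid)) grid <- vapply(graphs, function(g) g$sparsity, numeric(1))
  n_thr <- length(graphs)
  n_nodes <- nrow(graphs[[1]]$adjacency)
  glob <- matrix(NA_real_, n_thr, 8L,
                 dimnames = list(NULL, GLOBAL_METRIC_NAMES))
  nodal <- lapply(NODAL_METRIC_NAMES, function(nm)
    matrix(NA_real_, n_thr, n_nodes))
  names(nodal) <- NODAL_METRIC_NAMES
  for (t in seq_len(n_thr)) {
    adj <- graphs[[t]]$adjacency
    D <- shortest_paths(adj)
    nloc <- nodal_local_efficiency(adj)
    ncp <- nodal_clustering(adj)
    diag(D) <- NA
    inv <- 1 / D
    inv[is.infinite(D)] <- 0
    ne <- rowMeans(inv, na.rm = TRUE)
    nsp <- apply(D, 1L, function(d) {
      d <- d[is.finite(d)]
      if (length(d) == 0L) 0 else mean(d)
    })
    diag(D) <- 0
    q <- igraph::modularity(igraph::cluster_fast_greedy(as_igraph(adj)))
    sw <- normalized_small_world(graphs[[t]], n_rand = n_rand,
                                 n_swaps = n_swaps,
                                 seed = (as.numeric(seed) * 131 + t) %% 2147483647)
    glob[t, ] <- c(q, mean(ne), mean(nloc), mean(ncp),
                   sw$gamma, sw$lambda, sw$sigma, char_path_length(D))
    nodal$betweenness[t, ] <- igraph::betweenness(as_igraph(adj),
                                                  directed = FALSE)
    nodal$degree[t, ] <- rowSums(adj)
    nodal$nodal_Cp[t, ] <- ncp
    nodal$nodal_efficiency[t, ] <- ne
    nodal$nodal_local_efficiency[t, ] <- nloc
    nodal$nodal_shortest_path[t, ] <- nsp
  }
  auc_global <- apply(glob, 2L, metric_auc, grid = grid)
  auc_nodal <- vapply(NODAL_METRIC_NAMES, function(k)
    apply(nodal[[k]], 2L, metric_auc, grid = grid), numeric(n_nodes))
  structure(list(sparsity_grid = grid, global = glob, nodal = nodal,
                 auc_global = auc_global, auc_nodal = auc_nodal),
            class = "metric_curves")
}
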