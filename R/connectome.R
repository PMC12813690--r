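#' Extract mean parcel time series
#'
#' Column `j` is the mean over all in-mask voxels labeled `j` at each time
#' point.
#'
#' @param run `bold_run`
#' @param atlas `atlas_volume` aligned to the run grid
#' @return time x node numeric matrix
#' @export
extract_roi_timeseries <- function(run, atlas) {
  stopifnot(all(dim(run$data)[1:3] == atlas$dims))
  dims <- dim(run$data)
  idx <- which(atlas$mask & run$mask)
  lab <- atlas$labels[idx]
  counts <- tabulate(lab, nbins = atlas$n_rois)
  if (any(counts == 0L)) {
    stop("missing-node error: empty parcel(s) ",
         paste(which(counts == 0L), collapse = ", "))
  }
  flat <- matrix(run$data, nrow = prod(dims[1:3]))[idx, , drop = FALSE]
  sums <- rowsum(flat, group = lab)
  t(sums / counts)
}

#' Pearson connectivity matrix
#'
#' Pairwise Pearson correlation between node time series; symmetric with
#' unit diagonal.
#'
#' @param ts time x node matrix (>= 3 time points, no constant column)
#' @param node_labels,network_labels optional node annotation (defaults to
#'   the packaged lookup for 90 nodes)
#' @return object of class `connectivity_matrix` with elements `r`, `z`
#'   (filled by [fisher_z()]), `node_labels`, `network_labels`
#' @export
pearson_matrix <- function(ts, node_labels = NULL, network_labels = NULL) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L) stop("need at least 3 time points")
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance error: constant node series at node(s) ",
         paste(which(sds == 0), collapse = ", "))
  }
  r <- stats::cor(ts)
  n <- ncol(ts)
  if (is.null(node_labels) && n == 90L) {
    lk <- default_network_table()
    node_labels <- lk$name
    network_labels <- lk$network
  }
  structure(list(r = r, z = NULL,
                 node_labels = node_labels %||% sprintf("ROI%03d", seq_len(n)),
                 network_labels = network_labels),
            class = "connectivity_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fisher z-transform of a connectivity matrix
#'
#' `z = atanh(r)` off-diagonal with `|r|` clipped at `1 - clip` so edges at
#' `|r| = 1` stay finite; the diagonal is 0.
#'
#' @param matrix `connectivity_matrix`
#' @param clip clipping margin (default 1e-7)
#' @return the matrix with `z` filled
#' @export
fisher_z <- function(matrix, clip = 1e-7) {
  stopifnot(inherits(matrix, "connectivity_matrix"))
  r <- matrix$r
  z <- atanh(pmin(abs(r), 1 - clip) * sign(r))
  diag(z) <- 0
  matrix$z <- z
  matrix
}

#' Threshold a connectivity matrix at a given sparsity
#'
#' Sparsity `S` is the ratio of retained edges to the `n(n-1)/2` possible
#' edges. The `floor(S * n(n-1)/2)` edges with largest `|r|` are kept
#' (diagonal excluded; ties broken lexicographically by `(i, j)`), yielding
#' an undirected binary graph.
#'
#' @param matrix `connectivity_matrix`
#' @param S sparsity in `(0, 0.5]`
#' @return object of class `binary_graph`: `adjacency` (logical, symmetric,
#'   zero diagonal), `sparsity`, `edge_count`
#' @export
sparsity_threshold <- function(matrix, S) {
  stopifnot(inherits(matrix, "connectivity_matrix"))
  if (S <= 0 || S > 0.5) stop("parameter error: sparsity must lie in (0, 0.5]")
  r <- matrix$r
  n <- nrow(r)
  pairs <- upper_tri_pairs(n)
  vals <- abs(r[cbind(pairs$i, pairs$j)])
  m_edges <- floor(S * n * (n - 1) / 2 + 1e-9)
  ord <- order(-vals, pairs$i, pairs$j)
  keep <- ord[seq_len(m_edges)]
  adj <- matrix(FALSE, n, n)
  adj[cbind(pairs$i[keep], pairs$j[keep])] <- TRUE
  adj <- adj | t(adj)
  structure(list(adjacency = adj, sparsity = S, edge_count = m_edges),
            class = "binary_graph")
}

# upper-triangle pairs in lexicographic (i, j) order: (1,2), (1,3), ..., (n-1,n)
upper_tri_pairs <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  list(i = i, j = j)
}

#' Threshold over the full sparsity grid
#'
#' Produces one binary graph per sparsity value; because all graphs share
#' the same `|r|` ranking, consecutive edge sets are nested.
#'
#' @param matrix `connectivity_matrix`
#' @param s_min,s_max,step sparsity grid (default 0.05 to 0.50 by 0.01, 46
#'   thresholds)
#' @return list of `binary_graph`, one per grid value, with attribute
#'   `sparsity_grid`
#' @export
graph_series <- function(matrix, s_min = 0.05, s_max = 0.50, step = 0.01) {
  if (step <= 0 || s_min <= 0 || s_max > 0.5 || s_min > s_max) {
    stop("parameter error: invalid sparsity grid")
  }
  grid <- seq(s_min, s_max, by = step)
  graphs <- lapply(grid, function(S) sparsity_threshold(matrix, S))
  attr(graphs, "sparsity_grid") <- grid
  graphs
}
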