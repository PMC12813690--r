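#' Build a synthetic brain parcellation
#'
#' Partitions the interior of a voxel grid into `n_rois` spatially contiguous
#' parcels, emulating an anatomical atlas (e.g., a 90-node AAL-style
#' parcellation) on a small synthetic volume. Seeds are placed by
#' farthest-point sampling and parcels grown by multi-source breadth-first
#' search over the 6-neighborhood, so every parcel is connected and parcels
#' are roughly equal in size. The outermost one-voxel shell is background
#' (label 0), standing in for out-of-brain space.
#'
#' @param grid_dims integer vector of length 3, voxel counts per axis.
#' @param n_rois number of parcels (default 90).
#' @param seed integer seed; the same seed always yields the same atlas.
#' @param node_names optional character vector of length `n_rois`; defaults to
#'   the packaged AAL-90 region names when `n_rois == 90`, otherwise
#'   `"ROI001"...`.
#' @return An object of class `atlas_volume`: list with `labels` (3D integer
#'   array, 0 = background), `mask` (3D logical), `n_rois`, `dims`,
#'   `node_names`, and `network_labels` (when available from the packaged
#'   lookup).
#' @export
build_atlas <- function(grid_dims, n_rois = 90L, seed = 1L, node_names = NULL) {
  stopifnot(length(grid_dims) == 3L, all(grid_dims >= 1L))
  grid_dims <- as.integer(grid_dims)
  n_rois <- as.integer(n_rois)
  if (n_rois < 1L) stop("n_rois must be >= 1")

  mask <- array(FALSE, dim = grid_dims)
  if (all(grid_dims >= 3L)) {
    mask[2:(grid_dims[1] - 1L), 2:(grid_dims[2] - 1L), 2:(grid_dims[3] - 1L)] <- TRUE
  }
  n_vox <- sum(mask)
  if (n_vox < n_rois) {
    stop(sprintf("atlas sizing error: %d interior mask voxels cannot hold %d parcels",
                 n_vox, n_rois))
  }

  vox <- which(mask, arr.ind = TRUE)         # n_vox x 3 coordinates
  idx <- which(mask)                         # linear indices, same order

  # farthest-point seeding, deterministic: first seed pseudo-random from seed
  set.seed(as.integer(seed))
  seeds <- integer(n_rois)
  seeds[1] <- sample.int(n_vox, 1L)
  mind <- colSums((t(vox) - vox[seeds[1], ])^2)
  if (n_rois > 1L) {
    for (k in 2:n_rois) {
      seeds[k] <- which.max(mind)            # ties -> lowest index
      mind <- pmin(mind, colSums((t(vox) - vox[seeds[k], ])^2))
    }
  }

  # geodesic Voronoi growth: multi-source BFS on the 6-connected mask graph;
  # frontier processed in rounds, ties broken by label order
  lab_of_vox <- integer(n_vox)
  lab_of_vox[seeds] <- seq_len(n_rois)
  lin_to_ord <- integer(prod(grid_dims))
  lin_to_ord[idx] <- seq_len(n_vox)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  frontier <- seeds[order(seq_len(n_rois))]
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (v in frontier) {
      for (o in seq_len(6L)) {
        nb <- vox[v, ] + offs[o, ]
        if (any(nb < 1L) || any(nb > grid_dims)) next
        lin <- nb[1] + (nb[2] - 1L) * grid_dims[1] +
          (nb[3] - 1L) * grid_dims[1] * grid_dims[2]
        w <- lin_to_ord[lin]
        if (w > 0L && lab_of_vox[w] == 0L) {
          lab_of_vox[w] <- lab_of_vox[v]
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt[order(lab_of_vox[nxt], nxt)]
  }

  labels <- array(0L, dim = grid_dims)
  labels[idx] <- lab_of_vox

  if (is.null(node_names)) {
    if (n_rois == 90L) {
      lk <- default_network_table()
      node_names <- lk$name
      network_labels <- lk$network
    } else {
      node_names <- sprintf("ROI%03d", seq_len(n_rois))
      network_labels <- NULL
    }
  } else {
    stopifnot(length(node_names) == n_rois)
    network_labels <- NULL
  }

  structure(list(labels = labels, mask = mask, n_rois = n_rois,
                 dims = grid_dims, node_names = node_names,
                 network_labels = network_labels),
            class = "atlas_volume")
}

#' @export
print.atlas_volume <- function(x, ...) {
  cat(sprintf("atlas_volume: %s grid, %d parcels over %d mask voxels\n",
              paste(x$dims, collapse = "x"), x$n_rois, sum(x$mask)))
  invisible(x)
}

# packaged AAL-90 -> network lookup as a data.frame (node, name, network)
default_network_table <- function() {
  path <- system.file("extdata", "aal90_networks.tsv", package = "connectoscope")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Load and validate a node-to-network lookup
#'
#' Attaches resting-state network labels (7 cortical networks plus a
#' Subcortical network) to the 90 atlas nodes. The packaged default is a
#' curated, approximate AAL-90 assignment; subcortical structures (thalamus,
#' caudate, putamen, pallidum, hippocampus, amygdala) map to "Subcortical".
#'
#' @param path TSV with columns `node`, `name`, `network`; defaults to the
#'   packaged table.
#' @param n_nodes expected node count (default 90).
#' @return data.frame with one row per node, ordered by node index.
#' @export
load_network_labels <- function(path = NULL, n_nodes = 90L) {
  tab <- if (is.null(path)) default_network_table() else
    utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("node", "name", "network")
  if (!all(required %in% names(tab))) {
    stop("network table validation error: columns must include ",
         paste(required, collapse = ", "))
  }
  if (!setequal(tab$node, seq_len(n_nodes))) {
    missing <- setdiff(seq_len(n_nodes), tab$node)
    stop("network table validation error: missing nodes ",
         paste(missing, collapse = ", "))
  }
  allowed <- c("Visual", "Somatomotor", "Dorsal Attention", "Ventral Attention",
               "Limbic", "Frontoparietal", "Default Mode", "Subcortical")
  bad <- setdiff(unique(tab$network), allowed)
  if (length(bad) > 0L) {
    stop("network table validation error: unknown network label(s) ",
         paste(bad, collapse = ", "))
  }
  tab[order(tab$node), , drop = FALSE]
}
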