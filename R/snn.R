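#' Build a shared-nearest-neighbor graph over cells
#'
#' For each cell the `k` nearest neighbors by Euclidean distance in the
#' M-dimensional normalized tag space are found (the cell belongs to its own
#' neighborhood, so neighborhoods have `k + 1` members). Cells are connected
#' by an edge weighted with the Jaccard overlap of their neighborhoods,
#' \eqn{|A \cap B| / |A \cup B|}; edges with weight `<= prune` are removed.
#'
#' Exact kNN is used: the number of tags is small, so no dimensionality
#' reduction or approximate index is needed at the scales this package
#' targets. Distance ties are broken by cell index (stable order).
#'
#' @param x a `norm_tags` matrix (tags x cells); raw [tag_counts] are accepted
#'   and used as-is.
#' @param k neighborhood size, `1 <= k <` number of cells.
#' @param prune Jaccard threshold; edges with weight less than or equal to it
#'   are dropped (default `1/15`).
#' @return an object of class `snn_graph`: list with `n_cells`, `k`,
#'   `prune_threshold`, and `edges` (data.frame `from`, `to`, `weight` with
#'   `from < to`, 1-based cell indices).
#' @export
build_snn <- function(x, k, prune = 1 / 15) {
  m <- as.matrix(x)
  n <- ncol(m)
  k <- as.integer(k)
  if (k < 1 || k >= n) {
    stop("k must satisfy 1 <= k < number of cells (", n, ")", call. = FALSE)
  }
  # squared Euclidean distances via the Gram matrix; monotone in distance
  cs <- colSums(m^2)
  d2 <- outer(cs, cs, "+") - 2 * crossprod(m)
  nbr <- matrix(0L, nrow = k + 1L, ncol = n)
  for (j in seq_len(n)) {
    nbr[, j] <- order(d2[, j])[seq_len(k + 1L)]
  }
  # neighborhood incidence (cells x cells, row j marks members of N(j));
  # shared counts are the sparse Gram matrix of the incidence rows
  a <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k + 1L),
                            j = as.vector(nbr), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(a)
  tri <- Matrix::which(shared > 0, arr.ind = TRUE)
  tri <- tri[tri[, 1] < tri[, 2], , drop = FALSE]
  s <- shared[tri]
  w <- s / (2 * (k + 1) - s)
  keep <- w > prune
  edges <- data.frame(from = tri[keep, 1], to = tri[keep, 2],
                      weight = as.numeric(w[keep]))
  structure(list(n_cells = n, k = k, prune_threshold = prune, edges = edges,
                 barcodes = colnames(m)),
            class = "snn_graph")
}

#' @export
print.snn_graph <- function(x, ...) {
  cat(sprintf("snn_graph: %d cells, k = %d, %d edges (prune > %.4f)\n",
              x$n_cells, x$k, nrow(x$edges), x$prune_threshold))
  invisible(x)
}

#' Partition an SNN graph by Louvain community detection
#'
#' Runs multi-resolution Louvain modularity optimization
#' (\eqn{Q = \sum_c e_c/m - \gamma (d_c/2m)^2}) on the weighted SNN graph.
#' The partition is deterministic given `seed`. An edgeless graph yields one
#' singleton community per cell.
#'
#' @param graph an [build_snn()] result.
#' @param resolution resolution \eqn{\gamma}; larger values give more, smaller
#'   communities.
#' @param seed integer seed for the (seeded, restored-after-use) RNG consumed
#'   by the community detection heuristic.
#' @return object of class `cluster_assignment`: list with `cluster` (integer
#'   vector, ids dense from 0), `n_clusters`, `resolution`, `k`, `seed`.
#' @export
louvain <- function(graph, resolution = 1, seed = 0L) {
  stopifnot(inherits(graph, "snn_graph"))
  if (nrow(graph$edges) == 0) {
    member <- seq_len(graph$n_cells) - 1L
  } else {
    g <- igraph::graph_from_data_frame(
      graph$edges[, c("from", "to")], directed = FALSE,
      vertices = data.frame(name = seq_len(graph$n_cells)))
    member <- with_seed(seed, {
      igraph::membership(igraph::cluster_louvain(
        g, weights = graph$edges$weight, resolution = resolution))
    })
    member <- as.integer(member[as.character(seq_len(graph$n_cells))]) - 1L
  }
  structure(list(cluster = member,
                 n_clusters = length(unique(member)),
                 resolution = resolution, k = graph$k, seed = as.integer(seed),
                 barcodes = graph$barcodes),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d cells in %d clusters (k = %d, resolution = %g)\n",
              length(x$cluster), x$n_clusters, x$k, x$resolution))
  invisible(x)
}
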