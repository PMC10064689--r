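# kNN graph construction, shared-nearest-neighbor Jaccard pruning, and
# Louvain community detection — used both for sample graphs (k = 12 on
# log2[CP1K+1] abundances) and taxon co-occurrence graphs (k = 5 on the
# transposed matrix).

#' k-nearest-neighbor lists by Euclidean distance
#'
#' @param features Numeric matrix with one row per node; neighbors are
#'   found by Euclidean distance between rows. Ties are broken
#'   deterministically by ascending node index.
#' @param k Number of neighbors (must be < number of nodes).
#' @return A `knn_neighbors` object: list with `neighbors` (n x k integer
#'   matrix of node indices), `nodes` (row names) and `k`.
#' @export
knn_graph <- function(features, k) {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (any(!is.finite(features))) ct_input_error("features must be finite")
  n <- nrow(features)
  if (k >= n) ct_input_error(sprintf("k = %d must be < number of nodes (%d)", k, n))
  if (is.null(rownames(features))) rownames(features) <- paste0("n", seq_len(n))
  d <- as.matrix(stats::dist(features))
  nb <- t(vapply(seq_len(n), function(i) {
    ord <- order(d[i, ], seq_len(n))       # tie-break by ascending index
    ord <- ord[ord != i]
    ord[seq_len(k)]
  }, integer(k)))
  if (k == 1L) nb <- matrix(nb, ncol = 1L)
  structure(list(neighbors = nb, nodes = rownames(features), k = k),
            class = "knn_neighbors")
}

#' Construct a shared-nearest-neighbor graph directly
#'
#' Low-level constructor used by [snn_prune()] and by simulations that
#' plant a known block structure.
#'
#' @param nodes Character vector of node names.
#' @param edges Data frame with columns `from`, `to` (node names) and
#'   `weight` (Jaccard weight in `[0, 1]`).
#' @param k,threshold Bookkeeping: the k and pruning threshold used.
#' @return An `snn_graph` object.
#' @export
snn_graph <- function(nodes, edges, k = NA_integer_, threshold = NA_real_) {
  if (nrow(edges)) {
    if (any(edges$from == edges$to)) ct_input_error("self-loops are not allowed")
    if (any(edges$weight < 0 | edges$weight > 1)) {
      ct_input_error("Jaccard weights must lie in [0, 1]")
    }
    if (!all(c(edges$from, edges$to) %in% nodes)) {
      ct_input_error("edge endpoints must be listed in `nodes`")
    }
  }
  structure(list(nodes = nodes, edges = edges, k = k, threshold = threshold),
            class = "snn_graph")
}

#' @export
print.snn_graph <- function(x, ...) {
  cat(sprintf("snn_graph: %d nodes, %d edges (k = %s, prune >= %s)\n",
              length(x$nodes), nrow(x$edges), x$k, format(x$threshold)))
  invisible(x)
}

#' Shared-nearest-neighbor pruning with Jaccard weights
#'
#' Builds the undirected SNN graph over all node pairs that share at least
#' one k-neighbor (or are neighbors of each other); the edge weight is the
#' Jaccard index of the two k-neighbor sets,
#' `J = |N(a) intersect N(b)| / |N(a) union N(b)|`. Edges with
#' `J < threshold` are removed.
#'
#' @param neighbors A `knn_neighbors` from [knn_graph()].
#' @param threshold Pruning threshold (default 1/15, the SNN-Louvain
#'   ecosystem convention).
#' @return An [snn_graph()].
#' @export
snn_prune <- function(neighbors, threshold = 1 / 15) {
  stopifnot(inherits(neighbors, "knn_neighbors"))
  nb <- neighbors$neighbors
  n <- nrow(nb)
  sets <- lapply(seq_len(n), function(i) nb[i, ])
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (i in seq_len(n - 1L)) {
    si <- sets[[i]]
    for (j in (i + 1L):n) {
      sj <- sets[[j]]
      inter <- length(intersect(si, sj))
      adjacent <- (j %in% si) || (i %in% sj)
      if (inter == 0L && !adjacent) next
      jac <- inter / length(union(si, sj))
      if (jac >= threshold) {
        from <- c(from, i); to <- c(to, j); w <- c(w, jac)
      }
    }
  }
  edges <- data.frame(from = neighbors$nodes[from], to = neighbors$nodes[to],
                      weight = w, stringsAsFactors = FALSE)
  snn_graph(neighbors$nodes, edges, k = neighbors$k, threshold = threshold)
}

as_igraph <- function(graph) {
  g <- igraph::graph_from_data_frame(graph$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = graph$nodes))
  igraph::E(g)$weight <- graph$edges$weight
  g
}

#' Louvain community detection on an SNN graph
#'
#' Two-phase Louvain (greedy local moving plus graph aggregation) on the
#' Jaccard-weighted edges, seeded for reproducibility. Isolated nodes
#' become singleton communities. An edgeless graph yields all-singleton
#' communities with Q = 0 and a warning.
#'
#' @param graph An [snn_graph()].
#' @param seed Integer seed controlling the node visit order.
#' @param resolution Resolution parameter (default 1).
#' @return A `partition` object: `membership` (named integer vector),
#'   `modularity` (Q), `n_communities`.
#' @export
louvain <- function(graph, seed = 1L, resolution = 1.0) {
  stopifnot(inherits(graph, "snn_graph"))
  if (nrow(graph$edges) == 0L) {
    warning("edgeless graph: every node is a singleton community, Q = 0")
    memb <- stats::setNames(seq_along(graph$nodes), graph$nodes)
    return(structure(list(membership = memb, modularity = 0,
                          n_communities = length(memb)), class = "partition"))
  }
  g <- as_igraph(graph)
  cl <- with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  memb <- stats::setNames(as.integer(igraph::membership(cl)), graph$nodes)
  structure(list(membership = memb,
                 modularity = modularity_q(graph, memb),
                 n_communities = length(unique(memb))),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d communities, Q = %.4f\n",
              x$n_communities, x$modularity))
  invisible(x)
}

#' Weighted modularity of a partition
#'
#' `Q = sum_c [ w_in(c)/W - (w_tot(c) / 2W)^2 ]` where `W` is the total
#' edge weight, `w_in(c)` the weight inside community `c`, and `w_tot(c)`
#' the summed weighted degree of its nodes. Q lies in `[-0.5, 1]`.
#'
#' @param graph An [snn_graph()].
#' @param membership Named integer vector covering every node.
#' @return Modularity Q.
#' @export
modularity_q <- function(graph, membership) {
  stopifnot(inherits(graph, "snn_graph"))
  miss <- setdiff(graph$nodes, names(membership))
  if (length(miss)) {
    ct_input_error(sprintf("node '%s' missing from partition", miss[1L]))
  }
  if (nrow(graph$edges) == 0L) return(0)
  g <- as_igraph(graph)
  igraph::modularity(g, membership[graph$nodes],
                     weights = igraph::E(g)$weight)
}

#' Build the SNN sample or taxon graph from a log-abundance matrix
#'
#' Convenience wrapper chaining [knn_graph()] and [snn_prune()] with the
#' defaults used throughout: k = 12 for sample graphs (nodes = samples),
#' k = 5 for taxon co-occurrence graphs (nodes = taxa, i.e. the transposed
#' matrix).
#'
#' @param log_matrix Samples x taxa matrix of log2[CP1K+1] values.
#' @param axis `"samples"` or `"taxa"`.
#' @param k Neighbors; default 12 for samples, 5 for taxa.
#' @param threshold Jaccard pruning threshold.
#' @return An [snn_graph()].
#' @export
build_snn <- function(log_matrix, axis = c("samples", "taxa"), k = NULL,
                      threshold = 1 / 15) {
  axis <- match.arg(axis)
  feats <- if (axis == "samples") log_matrix else t(log_matrix)
  if (is.null(k)) k <- if (axis == "samples") 12L else 5L
  snn_prune(knn_graph(feats, k), threshold = threshold)
}
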