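# Weighted social networks and the metrics compared across contexts:
# density, weighted degree, betweenness, closeness, eigenvector centrality,
# and walktrap community structure with modularity Q.
#
# HWI is a similarity, so geodesic computations use distance = 1/weight.

#' Build a weighted social network from an association matrix
#'
#' One edge per nonzero HWI entry (zero-HWI dyads are absent edges, not
#' zero-weight ones); directedness is inherited from the data type.
#'
#' @param matrix an \code{association_matrix}.
#' @return an igraph graph with vertex names, edge attribute \code{weight},
#'   and graph attributes \code{context} and \code{data_type}.
#' @export
build_network <- function(matrix) {
  stopifnot(inherits(matrix, "association_matrix"))
  mode <- if (matrix$directed) "directed" else "undirected"
  g <- igraph::graph_from_adjacency_matrix(matrix$hwi, mode = mode,
                                           weighted = TRUE, diag = FALSE)
  g <- igraph::set_graph_attr(g, "context", matrix$context)
  g <- igraph::set_graph_attr(g, "data_type", matrix$data_type)
  g
}

#' Network density
#'
#' Proportion of possible edges present: |E| / (n(n-1)) for directed graphs,
#' |E| / (n(n-1)/2) for undirected. Edge weights are ignored.
#'
#' @param net igraph graph with at least two vertices.
#' @return density in [0, 1].
#' @export
net_density <- function(net) {
  n <- igraph::vcount(net)
  if (n < 2) stop("density requires at least two nodes")
  possible <- if (igraph::is_directed(net)) n * (n - 1) else n * (n - 1) / 2
  igraph::ecount(net) / possible
}

#' Per-node centrality metrics
#'
#' Weighted degree is the sum of incident edge weights (in + out for directed
#' graphs). Betweenness counts weighted geodesics (distance = 1/weight)
#' passing through a node. Closeness is 1 / (sum of geodesic distances to all
#' reachable others); isolated nodes score 0 and, on disconnected graphs, the
#' sum runs over the reachable set only. Eigenvector centrality is the
#' dominant eigenvector of the weight matrix (right eigenvector for directed
#' graphs), normalised to max 1; see \code{\link{eigenvector_centrality}}.
#'
#' @param net igraph graph.
#' @param weighted use HWI weights (default); if \code{FALSE} the graph is
#'   binarised (all computations on unit weights).
#' @return data.frame with columns \code{id}, \code{degree},
#'   \code{betweenness}, \code{closeness}, \code{eigenvector}.
#' @export
node_metrics <- function(net, weighted = TRUE) {
  ids <- igraph::V(net)$name
  n <- length(ids)
  if (igraph::ecount(net) == 0) {
    warning("empty graph: all node metrics are zero")
    return(data.frame(id = ids, degree = 0, betweenness = 0, closeness = 0,
                      eigenvector = 0, stringsAsFactors = FALSE))
  }
  w <- if (weighted) igraph::E(net)$weight else rep(1, igraph::ecount(net))
  dist_w <- 1 / w
  directed <- igraph::is_directed(net)
  deg <- igraph::strength(net, mode = "all", weights = w)
  btw <- igraph::betweenness(net, directed = directed, weights = dist_w)
  dmat <- igraph::distances(net, mode = "out", weights = dist_w)
  clo <- apply(dmat, 1, function(d) {
    d <- d[is.finite(d) & d > 0]
    if (length(d) == 0) 0 else 1 / sum(d)
  })
  eig <- eigenvector_centrality(net, weighted = weighted)
  data.frame(id = ids, degree = as.numeric(deg), betweenness = as.numeric(btw),
             closeness = as.numeric(clo), eigenvector = as.numeric(eig),
             stringsAsFactors = FALSE)
}

#' Eigenvector centrality by deterministic power iteration
#'
#' Iterates x <- (W + sI) x from a uniform start, where W is the (weighted)
#' adjacency matrix and the small diagonal shift s > 0 guarantees convergence
#' on bipartite-like spectra without changing the eigenvectors. Directed
#' graphs use the right dominant eigenvector of W; if iteration fails to
#' converge there, W is symmetrised and the iteration rerun. The result is
#' normalised to max 1 and satisfies W x = lambda x at the returned x.
#'
#' @param net igraph graph.
#' @param weighted use edge weights (default) or the binary adjacency.
#' @param tol convergence tolerance on the iterate (default 1e-10).
#' @param max_iter iteration cap (default 10000).
#' @return named numeric vector with attribute \code{lambda}.
#' @export
eigenvector_centrality <- function(net, weighted = TRUE, tol = 1e-10,
                                   max_iter = 10000) {
  ids <- igraph::V(net)$name
  n <- length(ids)
  attr_name <- if (weighted) "weight" else NULL
  W <- igraph::as_adjacency_matrix(net, attr = attr_name, sparse = FALSE)
  out <- power_iterate(W, tol, max_iter)
  if (!out$converged && igraph::is_directed(net)) {
    out <- power_iterate((W + t(W)) / 2, tol, max_iter)
  }
  if (!out$converged)
    warning("eigenvector centrality: power iteration did not converge")
  x <- out$x
  names(x) <- ids
  attr(x, "lambda") <- out$lambda
  x
}

power_iterate <- function(W, tol, max_iter) {
  n <- nrow(W)
  if (all(W == 0))
    return(list(x = rep(0, n), lambda = 0, converged = TRUE))
  shift <- max(rowSums(W)) * 0.05 + 1e-8
  M <- W + diag(shift, n)
  x <- rep(1 / n, n)
  converged <- FALSE
  lambda <- 0
  for (k in seq_len(max_iter)) {
    y <- drop(M %*% x)
    nrm <- max(abs(y))
    if (nrm == 0) return(list(x = rep(0, n), lambda = 0, converged = TRUE))
    y <- y / nrm
    if (max(abs(y - x)) < tol) {
      x <- y
      lambda <- nrm - shift
      converged <- TRUE
      break
    }
    x <- y
  }
  if (!converged) lambda <- max(abs(drop(M %*% x))) - shift
  mx <- max(abs(x))
  if (mx > 0) x <- x / mx
  list(x = x, lambda = lambda, converged = converged)
}

#' Walktrap community structure with maximum-modularity cut
#'
#' Standard walktrap agglomeration (4-step random walks) on the weighted
#' graph, cutting the dendrogram at the partition maximising weighted
#' modularity Q. Directed graphs are first collapsed to undirected by summing
#' reciprocal edge weights. Cluster labels are renumbered deterministically in
#' order of first appearance along the sorted vertex ids. If the best
#' partition is no better than the trivial single community, the single
#' community (Q = 0) is returned; an edgeless graph yields one cluster per
#' node with Q = 0.
#'
#' @param net igraph graph.
#' @param steps random-walk length (default 4).
#' @return list with named integer vector \code{membership} and numeric
#'   \code{modularity}.
#' @export
walktrap_clusters <- function(net, steps = 4) {
  ids <- igraph::V(net)$name
  if (igraph::is_directed(net)) {
    net <- igraph::as_undirected(net, mode = "collapse",
                                 edge.attr.comb = list(weight = "sum"))
  }
  if (igraph::ecount(net) == 0) {
    mem <- seq_along(ids)
    names(mem) <- ids
    return(list(membership = mem, modularity = 0))
  }
  wt <- igraph::cluster_walktrap(net, weights = igraph::E(net)$weight,
                                 steps = steps)
  mem <- igraph::membership(wt)
  q <- igraph::modularity(net, mem, weights = igraph::E(net)$weight)
  if (q <= 0 || length(unique(mem)) == 1) {
    mem <- rep(1L, length(ids))
    names(mem) <- ids
    return(list(membership = mem, modularity = 0))
  }
  ord <- order(ids)
  relabel <- match(mem, unique(mem[ord]))
  names(relabel) <- ids
  list(membership = relabel, modularity = q)
}

#' Full metric table for one network
#'
#' Bundles global density, per-node centralities, and the walktrap clustering
#' for a network into one object (the unit compared across contexts).
#'
#' @param net igraph graph.
#' @param tag short label for the network (e.g. "road_proximity").
#' @param weighted use edge weights for the nodal metrics.
#' @param cluster run walktrap clustering (default TRUE).
#' @return object of class \code{metric_table}: list with \code{network},
#'   \code{density}, data.frame \code{nodes}, \code{membership},
#'   \code{modularity}.
#' @export
metric_table <- function(net, tag = "network", weighted = TRUE, cluster = TRUE) {
  cl <- if (cluster) walktrap_clusters(net) else
    list(membership = NULL, modularity = NA_real_)
  structure(list(network = tag,
                 density = net_density(net),
                 nodes = node_metrics(net, weighted = weighted),
                 membership = cl$membership,
                 modularity = cl$modularity),
            class = "metric_table")
}

#' @export
print.metric_table <- function(x, ...) {
  cat(sprintf("<metric_table> %s: %d nodes, density %.3f, Q = %.3f\n",
              x$network, nrow(x$nodes), x$density, x$modularity))
  print(utils::head(x$nodes, 5))
  if (nrow(x$nodes) > 5) cat("  ...\n")
  invisible(x)
}

#' Extract one metric column from a metric table as a named vector
#'
#' @param mt a \code{metric_table} (or plain data.frame with an \code{id}
#'   column).
#' @param metric one of \code{"degree"}, \code{"betweenness"},
#'   \code{"closeness"}, \code{"eigenvector"}.
#' @return named numeric vector.
#' @export
metric_vector <- function(mt, metric) {
  nodes <- if (inherits(mt, "metric_table")) mt$nodes else mt
  if (!metric %in% names(nodes)) stop("unknown metric: ", metric)
  out <- nodes[[metric]]
  names(out) <- nodes$id
  out
}

# Writers ----------------------------------------------------------------

#' Export a network as GraphML or a weighted edge-list CSV
#'
#' @param net igraph graph.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_network_edgelist <- function(net, path) {
  el <- igraph::as_data_frame(net, what = "edges")
  utils::write.csv(el[order(el$from, el$to), c("from", "to", "weight")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a metric table as tidy CSV (network, id, metric, value)
#'
#' @param mt a \code{metric_table}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_metric_table <- function(mt, path) {
  nodes <- mt$nodes
  long <- do.call(rbind, lapply(NETWORK_METRICS, function(m) {
    data.frame(network = mt$network, id = nodes$id, metric = m,
               value = nodes[[m]], stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
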