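#' Weighted miRNA graph
#'
#' Undirected weighted graph over a fixed miRNA node set, stored as a
#' symmetric weight matrix plus a logical adjacency matrix (so an edge of
#' weight zero is distinct from an absent edge). Nodes are kept in
#' lexicographic order, which makes index order the tie-break order used
#' throughout the package.
#'
#' @param nodes Character vector of node (feature) ids.
#' @param w Symmetric numeric matrix of edge weights (diagonal ignored).
#' @param adj Logical adjacency matrix; `NULL` means complete.
#' @param complete Whether the graph is complete.
#' @return A `mirna_graph` object.
#' @export
mirna_graph <- function(nodes, w, adj = NULL, complete = is.null(adj)) {
  if (anyDuplicated(nodes)) rlang::abort("duplicate node ids")
  m <- length(nodes)
  if (!all(dim(w) == c(m, m))) rlang::abort("weight matrix dimension mismatch")
  ord <- order(nodes)
  nodes <- nodes[ord]
  w <- w[ord, ord, drop = FALSE]
  dimnames(w) <- list(nodes, nodes)
  if (max(abs(w - t(w))) > 1e-12) rlang::abort("weight matrix must be symmetric")
  w <- (w + t(w)) / 2
  diag(w) <- 0
  if (any(!is.finite(w))) rlang::abort("edge weights must be finite")
  if (any(w < 0)) rlang::abort("edge weights must be >= 0")
  if (is.null(adj)) {
    adj <- matrix(TRUE, m, m)
  } else {
    adj <- adj[ord, ord, drop = FALSE]
    adj <- adj | t(adj)
  }
  diag(adj) <- FALSE
  dimnames(adj) <- list(nodes, nodes)
  w[!adj] <- 0
  structure(
    list(nodes = nodes, w = w, adj = adj, complete = complete),
    class = "mirna_graph"
  )
}

#' @export
print.mirna_graph <- function(x, ...) {
  cat(sprintf(
    "<mirna_graph> %d nodes, %d edges%s\n",
    length(x$nodes), n_edges(x), if (x$complete) " (complete)" else ""
  ))
  invisible(x)
}

#' Number of edges in a graph
#' @param g A `mirna_graph`.
#' @return Integer edge count.
#' @export
n_edges <- function(g) sum(g$adj[upper.tri(g$adj)])

#' Edge list of a graph as a tibble
#'
#' @param x A `mirna_graph`.
#' @param ... Unused.
#' @return Tibble with columns `from`, `to` (from < to lexicographically)
#'   and `weight`, ordered by `from` then `to`.
#' @method tidy mirna_graph
#' @export
tidy.mirna_graph <- function(x, ...) {
  ut <- which(upper.tri(x$adj) & x$adj, arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  tibble::tibble(
    from = x$nodes[ut[, 1]],
    to = x$nodes[ut[, 2]],
    weight = x$w[ut]
  )
}

#' @method glance mirna_graph
#' @export
glance.mirna_graph <- function(x, ...) {
  ew <- x$w[which(upper.tri(x$adj) & x$adj)]
  tibble::tibble(
    n_nodes = length(x$nodes),
    n_edges = n_edges(x),
    complete = x$complete,
    min_weight = if (length(ew)) min(ew) else NA_real_,
    max_weight = if (length(ew)) max(ew) else NA_real_
  )
}

#' Build a graph from an edge-list data frame
#'
#' Inverse of [tidy.mirna_graph()]; useful for round-tripping edge lists
#' through TSV files.
#'
#' @param edges Data frame with columns `from`, `to`, `weight`.
#' @param nodes Node set; defaults to the union of `from` and `to`.
#' @param complete Mark the graph complete.
#' @return A `mirna_graph`.
#' @export
graph_from_edges <- function(edges, nodes = NULL, complete = FALSE) {
  nodes <- sort(nodes %||% unique(c(edges$from, edges$to)))
  m <- length(nodes)
  w <- matrix(0, m, m, dimnames = list(nodes, nodes))
  adj <- matrix(FALSE, m, m, dimnames = list(nodes, nodes))
  i <- match(edges$from, nodes)
  j <- match(edges$to, nodes)
  if (anyNA(i) || anyNA(j)) rlang::abort("edge endpoint not in node set")
  w[cbind(i, j)] <- edges$weight
  w[cbind(j, i)] <- edges$weight
  adj[cbind(i, j)] <- TRUE
  adj[cbind(j, i)] <- TRUE
  mirna_graph(nodes, w, adj, complete = complete)
}

#' Write a graph edge list as delimited text
#' @param g A `mirna_graph`.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return Invisibly, `g`.
#' @export
write_edgelist <- function(g, path, delim = "\t") {
  df <- as.data.frame(tidy.mirna_graph(g))
  df$weight <- format(df$weight, digits = 15, trim = TRUE)
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(g)
}

#' Min-max normalize the edge weights of a graph
#'
#' Rescales all present edge weights to `[0, 1]` by the global edge-weight
#' range. If every weight is equal, all weights become 0 and a warning is
#' raised.
#'
#' @param g A `mirna_graph`.
#' @return A `mirna_graph` with rescaled weights.
#' @export
minmax_normalize <- function(g) {
  idx <- which(g$adj & upper.tri(g$adj))
  if (length(idx) < 1) rlang::abort("graph has no edges")
  ew <- minmax(g$w[idx], warn_constant = TRUE, what = "edge weights")
  w <- g$w
  w[idx] <- ew
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  mirna_graph(g$nodes, w, g$adj, complete = g$complete)
}

# igraph view of a mirna_graph (weights optional)
as_igraph <- function(g, weighted = TRUE) {
  igraph::graph_from_adjacency_matrix(
    if (weighted) g$w * g$adj else (g$adj * 1),
    mode = "undirected", weighted = if (weighted) TRUE else NULL
  )
}

#' Is the graph connected?
#' @param g A `mirna_graph`.
#' @return Logical.
#' @export
is_connected <- function(g) igraph::is_connected(as_igraph(g, weighted = FALSE))
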