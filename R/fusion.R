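# Fusing the cooperative-regulation and functional-similarity views and
# sparsifying the result: min-max normalize each view, average them,
# extract the maximum spanning tree for guaranteed connectivity, then add
# each node's k strongest fused edges, choosing k by how well the degree
# distribution follows a power law.

#' Fuse two network views by averaging normalized edge weights
#'
#' Both graphs are min-max normalized over their full edge sets (globally,
#' not per node) and the fused edge weight is the mean of the two
#' normalized weights, so fused weights lie in `[0, 1]`.
#'
#' @param g_cr,g_fs Complete `mirna_graph`s on the same node set.
#' @param normalize Apply [minmax_normalize()] to each view first
#'   (default `TRUE`; set `FALSE` if the inputs are already normalized).
#' @return A complete `mirna_graph` of fused weights.
#' @export
fuse_networks <- function(g_cr, g_fs, normalize = TRUE) {
  if (!identical(g_cr$nodes, g_fs$nodes)) {
    rlang::abort("node sets of the two views differ")
  }
  if (normalize) {
    g_cr <- minmax_normalize(g_cr)
    g_fs <- minmax_normalize(g_fs)
  }
  mirna_graph(g_cr$nodes, (g_cr$w + g_fs$w) / 2,
    adj = g_cr$adj & g_fs$adj, complete = g_cr$complete && g_fs$complete
  )
}

#' Maximum spanning tree of a weighted graph
#'
#' Kruskal's algorithm on weight-descending edges; ties are broken by the
#' lexicographic edge key (from, to), so the tree is deterministic even
#' with equal weights.
#'
#' @param g A connected `mirna_graph`.
#' @return A `mirna_graph` holding the `m - 1` tree edges (weights carried
#'   from `g`).
#' @export
maximum_spanning_tree <- function(g) {
  m <- length(g$nodes)
  if (m < 2) rlang::abort("need >=2 nodes for a spanning tree")
  edges <- tidy.mirna_graph(g)
  # sort by descending weight, then lexicographic endpoints
  ord <- order(-edges$weight, edges$from, edges$to)
  ei <- match(edges$from, g$nodes)[ord]
  ej <- match(edges$to, g$nodes)[ord]
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  adj <- matrix(FALSE, m, m)
  taken <- 0L
  for (e in seq_along(ei)) {
    ri <- find(ei[e])
    rj <- find(ej[e])
    if (ri != rj) {
      parent[ri] <- rj
      adj[ei[e], ej[e]] <- TRUE
      taken <- taken + 1L
      if (taken == m - 1L) break
    }
  }
  if (taken < m - 1L) rlang::abort("graph is not connected")
  mirna_graph(g$nodes, g$w, adj = adj, complete = FALSE)
}

#' Augment a spanning tree with each node's k nearest neighbours
#'
#' For every node, the k neighbours with the largest weights in the
#' complete base graph are linked (undirected union), with ties at the k-th
#' weight broken lexicographically; the tree edges are always kept, so the
#' result stays connected.
#'
#' @param tree A spanning tree (`mirna_graph`) of the base graph.
#' @param base The complete fused `mirna_graph` supplying weights.
#' @param k Number of nearest neighbours per node; must be `< m`.
#' @return A `mirna_graph` with between `m - 1` and `m - 1 + m * k` edges.
#' @export
knn_augment <- function(tree, base, k) {
  m <- length(base$nodes)
  if (k >= m) rlang::abort(sprintf("k (%d) must be smaller than the node count (%d)", k, m))
  if (k < 1) rlang::abort("k must be a positive integer")
  adj <- tree$adj
  for (i in seq_len(m)) {
    wts <- base$w[i, ]
    wts[i] <- -Inf
    # order by descending weight, lexicographic (= index) tie-break
    top <- order(-wts, seq_len(m))[seq_len(k)]
    adj[i, top] <- TRUE
    adj[top, i] <- TRUE
  }
  mirna_graph(base$nodes, base$w, adj = adj, complete = FALSE)
}

# R^2 of the log-log degree-frequency regression; NA when fewer than two
# distinct degrees are present.
powerlaw_fit_score <- function(degrees) {
  tab <- table(degrees[degrees > 0])
  if (length(tab) < 2) return(NA_real_)
  ld <- log(as.numeric(names(tab)))
  lf <- log(as.numeric(tab))
  fit <- stats::lm.fit(cbind(1, ld), lf)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((lf - mean(lf))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - ss_res / ss_tot
}

#' Select the neighbour count k by power-law fit
#'
#' For each candidate k the augmented graph is built and its degree
#' distribution regressed as log(frequency) on log(degree); the candidate
#' with the highest R-squared wins, ties going to the smallest k. If no
#' candidate yields at least two distinct degrees the smallest candidate is
#' used with a warning.
#'
#' @param tree Spanning tree of the fused graph.
#' @param base Complete fused graph.
#' @param candidates Integer candidates for k (default `c(3, 5, 7, 9)`).
#' @return A list with `k` (the winner) and `scores` (tibble of candidate,
#'   R-squared and edge count).
#' @export
select_k <- function(tree, base, candidates = c(3, 5, 7, 9)) {
  m <- length(base$nodes)
  candidates <- sort(unique(as.integer(candidates)))
  candidates <- candidates[candidates < m]
  if (length(candidates) == 0) rlang::abort("no valid k candidate (all >= node count)")
  scores <- purrr::map(candidates, function(k) {
    aug <- knn_augment(tree, base, k)
    deg <- rowSums(aug$adj)
    tibble::tibble(
      k = k, r_squared = powerlaw_fit_score(deg),
      n_edges = n_edges(aug)
    )
  })
  scores <- dplyr::bind_rows(scores)
  if (all(is.na(scores$r_squared))) {
    rlang::warn("degree distribution degenerate for every candidate; using smallest k")
    k_best <- candidates[1]
  } else {
    # max R^2; candidates are sorted, so which.max takes the smallest k on ties
    k_best <- scores$k[which.max(scores$r_squared)]
  }
  list(k = k_best, scores = scores)
}

#' Build the fused, sparsified miRNA interaction network
#'
#' Runs the full fusion stage: normalize and average the two views
#' ([fuse_networks()]), extract the maximum spanning tree, pick k by
#' power-law fit ([select_k()]) and augment the tree with each node's k
#' strongest fused edges.
#'
#' @param g_cr Cooperative-regulation network (complete `mirna_graph`).
#' @param g_fs Functional-similarity network (complete `mirna_graph`).
#' @param k_candidates Candidate neighbour counts (default `c(3, 5, 7, 9)`).
#' @param k Fix k directly, skipping selection (default `NULL`).
#' @return A `fused_network`: list with elements `base` (complete fused
#'   graph), `tree` (MST), `sparse` (final network), `k` and `fit_scores`.
#' @examples
#' d <- simulate_dataset(synth_spec(m = 12, n_per_class = 8, seed = 1))
#' fn <- build_fused_network(
#'   build_coop_network(d$expression),
#'   build_functional_network(features(d$expression), d$relations,
#'                            table_embedding_provider(d$embeddings))
#' )
#' glance(fn)
#' @export
build_fused_network <- function(g_cr, g_fs, k_candidates = c(3, 5, 7, 9), k = NULL) {
  base <- fuse_networks(g_cr, g_fs)
  tree <- maximum_spanning_tree(base)
  if (is.null(k)) {
    sel <- select_k(tree, base, k_candidates)
  } else {
    sel <- list(k = as.integer(k), scores = tibble::tibble(
      k = as.integer(k), r_squared = NA_real_, n_edges = NA_integer_
    ))
  }
  sparse <- knn_augment(tree, base, sel$k)
  structure(
    list(base = base, tree = tree, sparse = sparse, k = sel$k, fit_scores = sel$scores),
    class = "fused_network"
  )
}

#' @export
print.fused_network <- function(x, ...) {
  cat(sprintf(
    "<fused_network> %d nodes; k = %d; sparse edges = %d (tree %d)\n",
    length(x$base$nodes), x$k, n_edges(x$sparse), n_edges(x$tree)
  ))
  invisible(x)
}

#' Tidy the sparse fused network into an edge list
#' @param x A `fused_network`.
#' @param which Which layer to tidy: "sparse" (default), "base" or "tree".
#' @param ... Unused.
#' @return Edge-list tibble.
#' @method tidy fused_network
#' @export
tidy.fused_network <- function(x, which = c("sparse", "base", "tree"), ...) {
  which <- match.arg(which)
  tidy.mirna_graph(x[[which]])
}

#' @method glance fused_network
#' @export
glance.fused_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$base$nodes),
    k = x$k,
    n_edges_sparse = n_edges(x$sparse),
    n_edges_tree = n_edges(x$tree),
    best_r_squared = x$fit_scores$r_squared[match(x$k, x$fit_scores$k)]
  )
}
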