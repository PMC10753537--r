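# Shared fixture builders and independent oracles used across test files.

# Small expression matrix with named features/samples and two classes.
tiny_expr <- function(m = 6, n_per_class = 5, seed = 42, sd = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(m * 2 * n_per_class, sd = sd), m, 2 * n_per_class,
    dimnames = list(
      sprintf("mir%02d", seq_len(m)),
      sprintf("s%02d", seq_len(2 * n_per_class))
    )
  )
  expr_matrix(vals, rep(c("ctrl", "case"), each = n_per_class))
}

# Independent Mann-Whitney oracle: U statistic by direct pair counting,
# two-sided p from the normal approximation with tie correction (no
# continuity correction).
mw_pvalue_oracle <- function(g1, g2) {
  n1 <- length(g1)
  n2 <- length(g2)
  u <- 0
  for (a in g1) for (b in g2) u <- u + (a > b) + 0.5 * (a == b)
  mu <- n1 * n2 / 2
  ties <- table(c(g1, g2))
  tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
  sigma2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term)
  if (sigma2 == 0) return(1)
  z <- (u - mu) / sqrt(sigma2)
  2 * min(pnorm(z), pnorm(-z), 0.5)
}

# Naive double-loop evaluation of the weighted best-matching average over
# a cosine matrix built element by element.
bma_oracle <- function(Bi, Bj) {
  p <- nrow(Bi)
  q <- nrow(Bj)
  S <- matrix(0, p, q)
  for (u in seq_len(p)) {
    for (v in seq_len(q)) {
      S[u, v] <- sum(Bi[u, ] * Bj[v, ]) /
        (sqrt(sum(Bi[u, ]^2)) * sqrt(sum(Bj[v, ]^2)))
    }
  }
  term1 <- 0
  for (u in seq_len(p)) {
    den <- sum(exp(abs(S[u, ])))
    for (v in seq_len(q)) {
      term1 <- term1 + exp(abs(S[u, v])) / den * S[u, v]
    }
  }
  term2 <- 0
  for (v in seq_len(q)) {
    den <- sum(exp(abs(S[, v])))
    for (u in seq_len(p)) {
      term2 <- term2 + exp(abs(S[u, v])) / den * S[u, v]
    }
  }
  (term1 + term2) / (p + q)
}

# AUC oracle: concordant-pair counting with ties worth one half.
auc_pair_oracle <- function(scores, pos) {
  s1 <- scores[pos]
  s0 <- scores[!pos]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# Exhaustive maximum-spanning-tree oracle via Pruefer sequences: every
# labelled tree on m nodes corresponds to a sequence in {1..m}^(m-2).
mst_brute_force <- function(w) {
  m <- nrow(w)
  stopifnot(m >= 3, m <= 6)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(m)), m - 2)))
  best <- -Inf
  best_edges <- NULL
  for (r in seq_len(nrow(seqs))) {
    prufer <- seqs[r, ]
    degree <- rep(1L, m)
    for (v in prufer) degree[v] <- degree[v] + 1L
    edges <- matrix(0L, m - 1, 2)
    deg <- degree
    avail <- rep(TRUE, m)
    for (i in seq_along(prufer)) {
      leaf <- which(avail & deg == 1L)[1]
      edges[i, ] <- c(leaf, prufer[i])
      deg[leaf] <- 0L
      avail[leaf] <- FALSE
      deg[prufer[i]] <- deg[prufer[i]] - 1L
    }
    last <- which(avail & deg == 1L)
    edges[m - 1, ] <- last
    tot <- sum(w[edges])
    if (tot > best + 1e-12) {
      best <- tot
      best_edges <- edges
    }
  }
  list(weight = best, edges = best_edges)
}

# Complete random graph fixture.
random_complete_graph <- function(m, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(m))
  w <- matrix(0, m, m)
  w[upper.tri(w)] <- runif(m * (m - 1) / 2)
  w <- w + t(w)
  dimnames(w) <- list(nodes, nodes)
  mirna_graph(nodes, w, complete = TRUE)
}

# Reproduce cross_validate's internal fold assignment (repeat r = 1).
derive_fold_seed <- function(seed, r = 1) mirmod:::derive_seed(seed, 9000L, r)
fold_assignment_for <- function(labels, folds) {
  mirmod:::stratified_folds_random(labels, folds)
}

# Do the given nodes induce a connected subgraph of g?
is_connected_subgraph <- function(g, members) {
  idx <- match(members, g$nodes)
  sub <- g$adj[idx, idx, drop = FALSE]
  igraph::components(
    igraph::graph_from_adjacency_matrix(sub * 1, mode = "undirected")
  )$no == 1
}

# Default scaled search configuration for 30-feature synthetic runs:
# episodes and size limit proportional to the network size (the reference
# setting uses ~2.5 episodes per feature and a size limit of ~6% of nodes).
scaled_cfg <- function(seed, m = 30) {
  rl_config(
    episodes = ceiling(2.5 * m), size_limit = max(3, round(0.1 * m)),
    auc_mode = "cv5", seed = seed
  )
}
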