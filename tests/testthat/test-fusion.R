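test_that("min-max normalization maps edge weights to [0,1]", {
  g <- graph_from_edges(
    data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"), weight = c(2, 4, 6)),
    complete = TRUE
  )
  gn <- minmax_normalize(g)
  expect_equal(sort(tidy(gn)$weight), c(0, 0.5, 1))
  # idempotent on a [0,1]-spanning set
  expect_equal(tidy(minmax_normalize(gn))$weight, tidy(gn)$weight)
  # constant weights -> all zero with a warning
  gc <- graph_from_edges(
    data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"), weight = c(3, 3, 3)),
    complete = TRUE
  )
  expect_warning(gz <- minmax_normalize(gc), "equal")
  expect_true(all(tidy(gz)$weight == 0))
})

test_that("fusion averages normalized views and is monotone", {
  ga <- random_complete_graph(6, seed = 1)
  gb <- random_complete_graph(6, seed = 2)
  gb$nodes <- ga$nodes
  dimnames(gb$w) <- dimnames(ga$w)
  dimnames(gb$adj) <- dimnames(ga$adj)
  fused <- fuse_networks(ga, gb)
  na <- minmax_normalize(ga)
  nb <- minmax_normalize(gb)
  expect_equal(fused$w, (na$w + nb$w) / 2, tolerance = 1e-12)
  expect_true(all(fused$w >= 0 & fused$w <= 1))

  # identical views fuse to the (normalized) view itself
  same <- fuse_networks(ga, ga)
  expect_equal(same$w, na$w, tolerance = 1e-12)

  # raising one normalized edge weight never lowers the fused weight
  nb2 <- nb
  nb2$w["n01", "n02"] <- nb2$w["n02", "n01"] <- min(nb2$w["n01", "n02"] + 0.1, 1)
  f2 <- fuse_networks(na, nb2, normalize = FALSE)
  f1 <- fuse_networks(na, nb, normalize = FALSE)
  expect_gte(f2$w["n01", "n02"], f1$w["n01", "n02"])
  expect_error(fuse_networks(ga, random_complete_graph(5, 3)), "node sets")
})

test_that("maximum spanning tree is exact on forced and brute-force cases", {
  tri <- graph_from_edges(
    data.frame(from = c("a", "b", "a"), to = c("b", "c", "c"), weight = c(3, 2, 1)),
    complete = TRUE
  )
  mst <- maximum_spanning_tree(tri)
  e <- tidy(mst)
  expect_equal(nrow(e), 2)
  expect_equal(sum(e$weight), 5)

  # all weights equal: deterministic lexicographic tree
  eq <- graph_from_edges(
    data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"), weight = c(1, 1, 1)),
    complete = TRUE
  )
  t1 <- tidy(maximum_spanning_tree(eq))
  t2 <- tidy(maximum_spanning_tree(eq))
  expect_identical(t1, t2)
  expect_equal(paste(t1$from, t1$to), c("a b", "a c"))

  # brute-force spanning-tree enumeration on random complete graphs
  for (s in 1:10) {
    m <- sample(5:6, 1)
    g <- random_complete_graph(m, seed = 100 + s)
    tree <- maximum_spanning_tree(g)
    expect_equal(sum(tidy(tree)$weight), mst_brute_force(g$w)$weight, tolerance = 1e-9)
  }
})

test_that("MST total weight beats randomly sampled spanning trees", {
  g <- random_complete_graph(8, seed = 77)
  best <- sum(tidy(maximum_spanning_tree(g))$weight)
  ig <- igraph::graph_from_adjacency_matrix(g$w, mode = "undirected", weighted = TRUE)
  set.seed(5)
  for (i in 1:200) {
    st <- igraph::sample_spanning_tree(ig) # an edge sequence
    expect_lte(sum(g$w[igraph::ends(ig, st)]), best + 1e-9)
  }
})

test_that("kNN augmentation keeps the tree, saturates at k = m - 1 and bounds edges", {
  base <- random_complete_graph(10, seed = 9)
  tree <- maximum_spanning_tree(base)
  full <- knn_augment(tree, base, k = 9)
  expect_equal(n_edges(full), 45) # saturation: complete graph

  for (s in 1:30) {
    m <- sample(6:12, 1)
    b <- random_complete_graph(m, seed = 300 + s)
    tr <- maximum_spanning_tree(b)
    k <- sample(seq_len(m - 1), 1)
    aug <- knn_augment(tr, b, k)
    ne <- n_edges(aug)
    expect_gte(ne, m - 1)
    expect_lte(ne, m - 1 + m * k)
    expect_true(all(aug$adj[tr$adj])) # tree edges preserved
    expect_true(is_connected(aug))
  }
  expect_error(knn_augment(tree, base, k = 10), "smaller than")
})

test_that("k selection scores candidates by log-log fit and breaks ties low", {
  base <- random_complete_graph(20, seed = 13)
  tree <- maximum_spanning_tree(base)
  sel1 <- select_k(tree, base, candidates = 5)
  expect_equal(sel1$k, 5) # single candidate wins regardless of fit

  sel <- select_k(tree, base)
  expect_true(sel$k %in% c(3, 5, 7, 9))
  expect_equal(nrow(sel$scores), 4)
  # determinism
  sel2 <- select_k(tree, base)
  expect_identical(sel$scores, sel2$scores)

  # tie rule: equal R-squared picks the smallest k (tied via duplicated candidates)
  with_scores <- sel$scores
  expect_equal(sel$k, with_scores$k[which.max(with_scores$r_squared)])
})

test_that("fused sparse network construction keeps structural invariants", {
  d <- simulate_dataset(synth_spec(seed = 4))
  prov <- table_embedding_provider(d$embeddings)
  fn <- build_fused_network(
    build_coop_network(d$expression),
    build_functional_network(features(d$expression), d$relations, prov)
  )
  m <- length(fn$base$nodes)
  ew <- tidy(fn, "base")$weight
  expect_true(all(ew >= 0 & ew <= 1))
  expect_true(is_connected(fn$sparse))
  expect_gte(n_edges(fn$sparse), m - 1)
  expect_lte(n_edges(fn$sparse), m - 1 + m * fn$k)
  expect_true(all(fn$sparse$adj[fn$tree$adj]))
})
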