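test_that("cosine similarity handles the canonical cases", {
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(2, 2), c(1, 1)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(-1, 0)), -1)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  expect_error(cosine_similarity(c(1, 0), c(1, 0, 0)), "equal length")
})

make_table_provider <- function(vectors) {
  table_embedding_provider(embedding_table(vectors))
}

test_that("functional similarity matches hand-computable cases", {
  prov <- mock_embedding_provider(dim = 8)
  # identical singleton sets: (1 + 1) / 2 = 1
  expect_equal(mirna_functional_similarity("glioma", "glioma", prov), 1)

  # all pairwise cosines equal -> the weighted average collapses to that value
  v <- rbind(a = c(1, 0), b = c(0.5, sqrt(3) / 2), c = c(0.5, sqrt(3) / 2))
  prov2 <- make_table_provider(v)
  s <- mirna_functional_similarity(c("a"), c("b", "c"), prov2)
  expect_equal(s, 0.5, tolerance = 1e-12)

  # p = 2, q = 1 with cosine column [0.5, 1.0]:
  # row weights degenerate to 1 -> first term 1.5; softmax column term
  # (e^0.5*0.5 + e^1*1)/(e^0.5+e^1); total / 3
  th <- acos(0.5)
  v3 <- rbind(
    d1 = c(cos(th), sin(th)), # cos(d1, d3) = 0.5
    d2 = c(1, 0), # cos(d2, d3) = 1
    d3 = c(1, 0)
  )
  prov3 <- make_table_provider(v3)
  got <- mirna_functional_similarity(c("d1", "d2"), c("d3"), prov3)
  second <- (exp(0.5) * 0.5 + exp(1) * 1) / (exp(0.5) + exp(1))
  expect_equal(got, (1.5 + second) / 3, tolerance = 1e-12)
  expect_equal(got, 0.7704, tolerance = 1e-4)

  # empty set -> 0 by convention
  expect_equal(mirna_functional_similarity(character(0), "glioma", prov), 0)
})

test_that("functional similarity is symmetric, bounded and oracle-exact", {
  set.seed(21)
  for (i in 1:40) {
    p <- sample(1:6, 1)
    q <- sample(1:6, 1)
    dim <- sample(2:8, 1)
    terms <- sprintf("t%02d", seq_len(p + q))
    vecs <- matrix(rnorm((p + q) * dim), p + q, dimnames = list(terms, NULL))
    prov <- make_table_provider(vecs)
    d_i <- terms[seq_len(p)]
    d_j <- terms[p + seq_len(q)]
    s_ij <- mirna_functional_similarity(d_i, d_j, prov)
    s_ji <- mirna_functional_similarity(d_j, d_i, prov)
    expect_equal(s_ij, s_ji, tolerance = 1e-12)
    expect_gte(s_ij, -1)
    expect_lte(s_ij, 1)
    oracle <- bma_oracle(
      vecs[d_i, , drop = FALSE], vecs[d_j, , drop = FALSE]
    )
    expect_equal(s_ij, oracle, tolerance = 1e-12)
  }
})

test_that("functional network clamps, zeroes unknown features and caches embeddings", {
  d <- simulate_dataset(synth_spec(m = 10, n_per_class = 5, seed = 3))
  calls <- new.env()
  calls$terms <- character(0)
  base <- table_embedding_provider(d$embeddings)
  counting <- structure(list(
    fun = function(terms) {
      calls$terms <- c(calls$terms, terms)
      base$fun(terms)
    },
    dim = base$dim, label = "counting"
  ), class = "embedding_provider")

  feats <- features(d$expression)
  g <- build_functional_network(feats, d$relations, counting)
  expect_equal(n_edges(g), 45)
  expect_true(all(tidy(g)$weight >= 0 & tidy(g)$weight <= 1))
  # each distinct term embedded exactly once per build
  expect_equal(anyDuplicated(calls$terms), 0L)

  # a feature with no relations gets all-zero edges
  rel <- unclass(d$relations)
  rel[[feats[1]]] <- NULL
  g2 <- build_functional_network(feats, disease_relations(rel), base)
  expect_true(all(g2$w[feats[1], ] == 0))

  # identical singleton disease sets give edge weight 1
  rel3 <- disease_relations(list(a = "glioma", b = "glioma"))
  g3 <- build_functional_network(c("a", "b"), rel3, mock_embedding_provider(6))
  expect_equal(g3$w["a", "b"], 1)
})
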