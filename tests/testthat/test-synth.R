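test_that("generated data pass validation and are seed-deterministic", {
  spec <- synth_spec(seed = 23)
  d1 <- simulate_dataset(spec)
  d2 <- simulate_dataset(spec)
  expect_identical(d1$expression$values, d2$expression$values)
  expect_identical(unclass(d1$relations), unclass(d2$relations))
  expect_identical(unclass(d1$embeddings), unclass(d2$embeddings))

  # re-validating through the constructor succeeds (all invariants hold)
  x <- expr_matrix(d1$expression$values, d1$expression$labels)
  expect_equal(dim(x), c(30L, 40L))
  # planted modules are disjoint and within the feature set
  expect_equal(anyDuplicated(unlist(d1$truth$modules)), 0L)
  expect_true(all(unlist(d1$truth$modules) %in% features(x)))
  expect_error(
    synth_spec(m = 6, modules = list(list(size = 7, delta = 1, rho = 0))),
    "exceed"
  )
})

test_that("planted cooperative-regulation signal grows with the effect size", {
  planted_edge_mean <- function(delta, seed) {
    d <- simulate_dataset(synth_spec(
      modules = list(list(size = 5, delta = delta, rho = 0.8)), seed = seed
    ))
    tm <- d$truth$modules[[1]]
    pairs <- utils::combn(tm, 2)
    mean(vapply(seq_len(ncol(pairs)), function(i) {
      edge_weight(
        d$expression$values[pairs[1, i], ] - d$expression$values[pairs[2, i], ],
        d$expression$labels
      )
    }, numeric(1)))
  }
  deltas <- c(0, 0.5, 1, 2)
  means <- sapply(1:20, function(s) sapply(deltas, planted_edge_mean, seed = s))
  rho <- stats::cor(deltas, rowMeans(means), method = "spearman")
  expect_gte(rho, 0.9)
  # and at delta = 2 the planted edges clearly beat the background
  d <- simulate_dataset(synth_spec(seed = 2))
  g <- build_coop_network(d$expression)
  tm <- d$truth$modules[[1]]
  ew <- tidy(g)
  inside <- ew$from %in% tm & ew$to %in% tm
  expect_gt(mean(ew$weight[inside]), mean(ew$weight[!inside]))
})

test_that("disease overlap controls within-module functional similarity", {
  d_hi <- simulate_dataset(synth_spec(seed = 9))
  d_lo <- simulate_dataset(synth_spec(
    modules = list(list(size = 5, delta = 2, rho = 0)), seed = 9
  ))
  sim_in <- function(d) {
    g <- build_functional_network(
      features(d$expression), d$relations,
      table_embedding_provider(d$embeddings)
    )
    tm <- d$truth$modules[[1]]
    mean(g$w[tm, tm][upper.tri(matrix(0, 5, 5))])
  }
  expect_gt(sim_in(d_hi), sim_in(d_lo))
})

test_that("toy environment enumerates its connected subsets", {
  env <- toy_rl_environment()
  subs <- connected_subsets(env$graph)
  sizes <- lengths(subs)
  expect_equal(sum(sizes == 1), 5)
  # b-c-d triangle plus paths: spot-check membership
  keys <- vapply(subs, function(s) paste(sort(s), collapse = "+"), character(1))
  expect_true("b+c+d" %in% keys)
  expect_false("a+c" %in% keys) # not adjacent
  expect_true(all(vapply(subs, function(s) is_connected_subgraph(env$graph, s), logical(1))))
})
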