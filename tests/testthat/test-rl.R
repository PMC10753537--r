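test_that("exploration schedule, reward and Q-update follow the exact formulas", {
  expect_equal(epsilon_schedule(0, 2000), 1)
  expect_equal(epsilon_schedule(2000, 2000, 1e-5), 1e-5)
  expect_equal(epsilon_schedule(1000, 2000, 1e-5), sqrt(1e-5))

  expect_equal(reward(1, 1), 2)
  expect_equal(reward(0.8, 4), 1.2)
  # strictly decreasing in size at fixed AUC, increasing in AUC at fixed size
  rs <- sapply(c(1, 4, 16), function(sz) reward(0.9, sz))
  expect_true(all(diff(rs) < 0))
  expect_true(all(diff(sapply(seq(0.1, 1, 0.1), function(a) reward(a, 3))) > 0))

  expect_equal(q_update(0, 1.2, 0, alpha = 0.2, gamma = 0.8), 0.24)
  expect_equal(q_update(0.5, 3, 1, alpha = 1, gamma = 0), 3) # becomes exactly R
  # with gamma = 0 repeated updates converge geometrically to R
  q <- 0
  for (i in 1:60) q <- q_update(q, 1.5, 0, alpha = 0.3, gamma = 0)
  expect_equal(q, 1.5, tolerance = 1e-6)
})

test_that("importance scores combine test significance and closeness centrality", {
  # star graph: the hub has the highest closeness
  edges <- data.frame(from = "hub", to = c("n1", "n2", "n3", "n4"), weight = 1)
  star <- graph_from_edges(edges)
  set.seed(3)
  vals <- matrix(rnorm(50), 5, 10,
    dimnames = list(sort(c("hub", paste0("n", 1:4))), paste0("s", 1:10))
  )
  # make n1 strongly differential so i_e endpoints are exercised
  vals["n1", ] <- c(rnorm(5), rnorm(5, 6))
  x <- expr_matrix(vals, rep(c("a", "b"), each = 5))
  sc <- importance_scores(x, star)
  expect_equal(sc$i_t[sc$feature == "hub"], 1) # centrality max at hub
  expect_equal(sc$i_e[sc$feature == "n1"], 1) # significance max at n1
  expect_true(all(sc$importance >= 0 & sc$importance <= 1))
  expect_equal(sc$importance, (sc$i_e + sc$i_t) / 2)
})

test_that("module AUC agrees with perfect separators and the null", {
  x <- tiny_expr(m = 4, n_per_class = 8, seed = 1)
  x$values["mir01", ] <- c(rnorm(8), rnorm(8, 10)) # perfect separator
  x <- expr_matrix(x$values, x$labels)
  expect_equal(module_auc(x, "mir01", mode = "resub"), 1)

  # permuted labels: mean AUC near one half
  set.seed(99)
  aucs <- replicate(10, {
    y <- sample(as.character(x$labels))
    module_auc(expr_matrix(x$values, factor(y, levels(x$labels))),
      c("mir02", "mir03"),
      mode = "cv5"
    )
  })
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
})

test_that("toy environment is exhaustively characterized", {
  env <- toy_rl_environment()
  subs <- connected_subsets(env$graph)
  expect_true(length(subs) < 2^5)
  expect_true(all(vapply(subs, function(s) is_connected_subgraph(env$graph, s), logical(1))))
  # unique reward maximum over connected sets containing the seed
  with_seed <- Filter(function(s) env$seed_node %in% s, subs)
  rw <- vapply(with_seed, function(s) reward(env$auc_of_set(s), length(s)), numeric(1))
  expect_equal(sort(with_seed[[which.max(rw)]]), sort(env$optimal))
  expect_gt(max(rw), sort(rw, decreasing = TRUE)[2] + 0.5) # clear margin
})

test_that("training is seed-deterministic and respects the Q bound", {
  env <- toy_rl_environment()
  cfg <- rl_config(episodes = 300, seed = 5)
  set.seed(5)
  q1 <- train_qtable(env$graph, seed_node = "b", cfg = cfg, auc_fun = env$auc_fun)
  set.seed(5)
  q2 <- train_qtable(env$graph, seed_node = "b", cfg = cfg, auc_fun = env$auc_fun)
  expect_identical(q1$Q, q2$Q)
  # Q values bounded by R_max / (1 - gamma) = 2 / 0.2 = 10 under defaults
  expect_true(all(q1$Q <= 2 / (1 - cfg$gamma) + 1e-9))

  # single-episode training touches at most L - 1 state-action pairs
  set.seed(1)
  qk1 <- train_qtable(env$graph,
    seed_node = "b",
    cfg = rl_config(episodes = 1, size_limit = 4), auc_fun = env$auc_fun
  )
  expect_lte(sum(qk1$Q != 0), 4 - 1)
})

test_that("greedy extraction recovers the toy optimum after training", {
  env <- toy_rl_environment()
  hits <- 0
  for (s in 1:5) {
    set.seed(s)
    cfg <- rl_config(episodes = 400, seed = s)
    qt <- train_qtable(env$graph, seed_node = env$seed_node, cfg = cfg, auc_fun = env$auc_fun)
    mod <- extract_module(env$graph, qtab = qt, cfg = cfg, auc_fun = env$auc_fun)
    if (setequal(mod$members, env$optimal)) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("extracted modules induce connected subgraphs within the size limit", {
  d <- simulate_dataset(synth_spec(seed = 6))
  prov <- table_embedding_provider(d$embeddings)
  fn <- build_fused_network(
    build_coop_network(d$expression),
    build_functional_network(features(d$expression), d$relations, prov)
  )
  cfg <- scaled_cfg(seed = 6)
  mods <- identify_modules(d$expression, fn, cfg, keep_qtables = TRUE)
  expect_length(mods$modules, cfg$n_seeds)
  for (m in mods$modules) {
    expect_lte(length(m$members), cfg$size_limit)
    expect_true(is_connected_subgraph(fn$sparse, m$members))
    expect_equal(m$members[1], m$seed)
  }
  # g = 1 produces a single module from the top-importance seed
  cfg1 <- rl_config(
    episodes = 40, size_limit = 3, n_seeds = 1,
    auc_mode = "resub", seed = 2
  )
  mods1 <- identify_modules(d$expression, fn, cfg1)
  expect_length(mods1$modules, 1)
  expect_equal(mods1$modules[[1]]$seed, mods$scores$feature[1])
})

test_that("the full identification run is bit-reproducible under a fixed seed", {
  d <- simulate_dataset(synth_spec(m = 15, n_per_class = 8, seed = 8))
  prov <- table_embedding_provider(d$embeddings)
  fn <- build_fused_network(
    build_coop_network(d$expression),
    build_functional_network(features(d$expression), d$relations, prov)
  )
  cfg <- rl_config(episodes = 40, size_limit = 4, n_seeds = 3, auc_mode = "resub", seed = 31)
  m1 <- identify_modules(d$expression, fn, cfg, keep_qtables = TRUE)
  m2 <- identify_modules(d$expression, fn, cfg, keep_qtables = TRUE)
  expect_identical(lapply(m1$modules, `[[`, "members"), lapply(m2$modules, `[[`, "members"))
  expect_identical(
    lapply(m1$qtables, function(q) q$Q),
    lapply(m2$qtables, function(q) q$Q)
  )
})
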