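test_that("roc_auc matches the pair-counting oracle including ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.85, 0.7), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(roc_auc(rep(0.5, 6), rep(c(TRUE, FALSE), 3)), 0.5)

  set.seed(17)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    scores <- if (i %% 2 == 0) round(runif(n), 1) else rnorm(n) # forced ties half the time
    pos <- runif(n) < 0.5
    if (!any(pos) || all(pos)) next
    expect_equal(roc_auc(scores, pos), auc_pair_oracle(scores, pos), tolerance = 1e-9)
  }
})

test_that("roc_auc is invariant under strictly monotone score transforms", {
  set.seed(4)
  scores <- rnorm(30)
  pos <- runif(30) < 0.4
  a0 <- roc_auc(scores, pos)
  expect_equal(roc_auc(exp(scores), pos), a0)
  expect_equal(roc_auc(qnorm(pnorm(scores))^3 + 10, pos), a0, tolerance = 1e-9)
})

test_that("roc_auc agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  scores <- c(rnorm(20), rnorm(20, 1))
  pos <- rep(c(FALSE, TRUE), each = 20)
  ref <- as.numeric(pROC::auc(pROC::roc(pos, scores, quiet = TRUE, direction = "<")))
  expect_equal(roc_auc(scores, pos), ref, tolerance = 1e-12)
})

test_that("voting weights are normalized inner-CV AUCs", {
  d <- simulate_dataset(synth_spec(m = 12, n_per_class = 10, seed = 10))
  mods <- list(
    structure(list(seed = "mir001", members = c("mir001", "mir002"), auc = NA), class = "mirna_module"),
    structure(list(seed = "mir007", members = c("mir007", "mir008"), auc = NA), class = "mirna_module")
  )
  ens <- fit_ensemble(d$expression, mods)
  expect_equal(sum(ens$weights), 1, tolerance = 1e-12)
  aucs <- vapply(ens$classifiers, `[[`, numeric(1), "inner_auc")
  expect_equal(ens$weights, aucs / sum(aucs))
  # worked ratio: AUCs (0.9, 0.6) -> weights (0.6, 0.4)
  expect_equal(c(0.9, 0.6) / sum(c(0.9, 0.6)), c(0.6, 0.4))

  ens1 <- fit_ensemble(d$expression, mods[1])
  expect_equal(ens1$weights, 1)
  expect_error(
    fit_ensemble(d$expression, list(structure(
      list(seed = "zz", members = "zz", auc = NA),
      class = "mirna_module"
    ))),
    "absent"
  )
})

test_that("ensemble prediction is a weighted vote of per-module scores", {
  d <- simulate_dataset(synth_spec(m = 12, n_per_class = 10, seed = 12))
  mods <- list(
    structure(list(seed = "mir001", members = c("mir001", "mir002"), auc = NA), class = "mirna_module"),
    structure(list(seed = "mir009", members = c("mir009", "mir010"), auc = NA), class = "mirna_module")
  )
  ens <- fit_ensemble(d$expression, mods)
  preds <- predict(ens, d$expression)
  expect_equal(nrow(preds), ncol(d$expression$values))
  sc <- as.matrix(preds[, c("score_class0", "score_class1")])
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(preds$.pred, ens$class_levels[max.col(sc, ties.method = "first")])

  # degenerate weights (1, 0): the vote equals classifier 1 alone
  ens10 <- ens
  ens10$weights <- c(1, 0)
  ens1 <- fit_ensemble(d$expression, mods[1])
  p10 <- predict(ens10, d$expression)
  p1 <- predict(ens1, d$expression)
  expect_equal(p10$score_class1, p1$score_class1, tolerance = 1e-12)

  # equal weights average the two module scores
  enseq <- ens
  enseq$weights <- c(0.5, 0.5)
  pa <- predict(ens10, d$expression)$score_class1
  ens01 <- ens
  ens01$weights <- c(0, 1)
  pb <- predict(ens01, d$expression)$score_class1
  expect_equal(predict(enseq, d$expression)$score_class1, (pa + pb) / 2, tolerance = 1e-12)
})

test_that("three-class problems use macro one-vs-rest scoring end to end", {
  d <- simulate_dataset(synth_spec(
    m = 12, n_per_class = 8, n_classes = 3,
    modules = list(list(size = 3, delta = 2, rho = 0.8)), seed = 14
  ))
  x <- d$expression
  expect_equal(nlevels(x$labels), 3)
  auc <- module_auc(x, c("mir001", "mir002", "mir003"), mode = "cv5")
  expect_gt(auc, 0.7)
  mods <- list(structure(
    list(seed = "mir001", members = c("mir001", "mir002", "mir003"), auc = NA),
    class = "mirna_module"
  ))
  ens <- fit_ensemble(x, mods)
  preds <- predict(ens, x)
  expect_true(all(c("score_class0", "score_class1", "score_class2") %in% names(preds)))
  sc <- as.matrix(preds[, paste0("score_", ens$class_levels)])
  expect_gt(roc_auc(sc, x$labels), 0.7)
})

test_that("cross-validation is deterministic and leak-free", {
  d <- simulate_dataset(synth_spec(m = 15, n_per_class = 10, seed = 16))
  prov <- table_embedding_provider(d$embeddings)
  cfg <- rl_config(episodes = 25, size_limit = 3, n_seeds = 2, auc_mode = "resub", seed = 3)
  r1 <- cross_validate(d$expression, d$relations, prov, cfg,
    repeats = 1, folds = 3, keep_fits = TRUE
  )
  expect_equal(nrow(r1$folds), 3)
  expect_true(all(r1$folds$auc >= 0 & r1$folds$auc <= 1))
  r2 <- cross_validate(d$expression, d$relations, prov, cfg,
    repeats = 1, folds = 3, keep_fits = TRUE
  )
  expect_identical(r1$folds, r2$folds)

  # perturbing held-out samples must not change the fitted fold models:
  # recover fold 1's test set, corrupt it, re-run, compare fold-1 fit
  set.seed(derive_fold_seed(cfg$seed))
  assign_f <- fold_assignment_for(d$expression$labels, 3)
  x2 <- d$expression
  x2$values[, assign_f == 1] <- x2$values[, assign_f == 1] + 100
  r3 <- cross_validate(expr_matrix(x2$values, x2$labels), d$relations, prov, cfg,
    repeats = 1, folds = 3, keep_fits = TRUE
  )
  expect_identical(r1$fits$r1_f1$modules, r3$fits$r1_f1$modules)
  expect_equal(r1$fits$r1_f1$weights, r3$fits$r1_f1$weights, tolerance = 1e-12)
  # voting weights always sum to one
  for (f in r1$fits) expect_equal(sum(f$weights), 1, tolerance = 1e-12)
})

test_that("fold counts shrink with a warning when classes are small", {
  x <- tiny_expr(m = 5, n_per_class = 4, seed = 20)
  d <- simulate_dataset(synth_spec(m = 5, n_per_class = 4, modules = list(), seed = 20))
  prov <- mock_embedding_provider(8)
  cfg <- rl_config(episodes = 10, size_limit = 3, n_seeds = 1, auc_mode = "resub", seed = 1)
  expect_warning(
    r <- cross_validate(x, disease_relations(list()), prov, cfg, repeats = 1, folds = 10),
    "reducing folds"
  )
  expect_equal(r$n_folds, 4)
})
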