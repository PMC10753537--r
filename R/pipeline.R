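# End-to-end orchestration with a serializable run configuration and
# on-disk artifacts. Every run writes a manifest (configuration, its hash,
# seed, package version) sufficient to reproduce it exactly; outputs are
# deterministic given configuration and inputs.

#' Run configuration for the command-line pipeline
#'
#' Collects the search configuration ([rl_config()] fields), input paths,
#' sparsification candidates and evaluation protocol into one serializable
#' list. Defaults equal the reference settings (alpha 0.2, gamma 0.8, 2000
#' episodes, 5 seeds, size limit 50, k in {3, 5, 7, 9}, 10 x 10-fold CV).
#'
#' @param expression,labels,relations,embeddings,alias Input file paths
#'   (`relations`, `embeddings`, `alias` optional).
#' @param out_dir Output directory for artifacts.
#' @param alpha,gamma,episodes,epsilon_final,size_limit,n_seeds,auc_mode,svm_cost,seed
#'   See [rl_config()].
#' @param k_candidates Candidate neighbour counts.
#' @param cv_repeats,cv_folds Evaluation protocol.
#' @param weight_scheme Voting-weight normalization.
#' @param delim Field delimiter override for the readers (`NULL` =
#'   auto-detect).
#' @return A `run_config` list.
#' @export
run_config <- function(expression = NULL, labels = NULL, relations = NULL,
                       embeddings = NULL, alias = NULL, out_dir = "mirmod_out",
                       alpha = 0.2, gamma = 0.8, episodes = 2000,
                       epsilon_final = 1e-5, size_limit = 50, n_seeds = 5,
                       auc_mode = "cv5", svm_cost = 1, seed = 1L,
                       k_candidates = c(3, 5, 7, 9),
                       cv_repeats = 10, cv_folds = 10,
                       weight_scheme = "sum", delim = NULL) {
  cfg <- list(
    expression = expression, labels = labels, relations = relations,
    embeddings = embeddings, alias = alias, out_dir = out_dir,
    alpha = alpha, gamma = gamma, episodes = episodes,
    epsilon_final = epsilon_final, size_limit = size_limit,
    n_seeds = n_seeds, auc_mode = auc_mode, svm_cost = svm_cost,
    seed = seed, k_candidates = k_candidates,
    cv_repeats = cv_repeats, cv_folds = cv_folds,
    weight_scheme = weight_scheme, delim = delim
  )
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML or JSON file
#'
#' Fields present in the file override the defaults of [run_config()].
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    rlang::warn(sprintf("ignoring unknown config field(s): %s", paste(unknown, collapse = ", ")))
    vals <- vals[intersect(names(vals), known)]
  }
  do.call(run_config, vals)
}

rl_config_from_run <- function(config) {
  rl_config(
    alpha = config$alpha, gamma = config$gamma, episodes = config$episodes,
    epsilon_final = config$epsilon_final, size_limit = config$size_limit,
    n_seeds = config$n_seeds, auc_mode = config$auc_mode,
    svm_cost = config$svm_cost, seed = config$seed
  )
}

load_inputs <- function(config) {
  x <- read_expression(config$expression, config$labels, delim = config$delim)
  relations <- if (!is.null(config$relations) && file.exists(config$relations %||% "")) {
    read_relations(config$relations, alias_map = config$alias, delim = config$delim)
  } else {
    if (!is.null(config$relations)) {
      rlang::warn("relations file missing; functional similarities will all be 0")
    }
    disease_relations(list())
  }
  provider <- if (!is.null(config$embeddings) && file.exists(config$embeddings %||% "")) {
    table_embedding_provider(read_embeddings(config$embeddings, delim = config$delim))
  } else {
    mock_embedding_provider(seed = config$seed)
  }
  list(x = x, relations = relations, provider = provider)
}

write_manifest <- function(config, out_dir, stage) {
  ser <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, null = "null", digits = NA)
  manifest <- list(
    stage = stage,
    package = "mirmod",
    version = as.character(utils::packageVersion("mirmod")),
    seed = config$seed,
    config_hash = rlang::hash(as.character(ser)),
    config = jsonlite::fromJSON(ser, simplifyVector = TRUE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null"
  )
}

#' Build and write the network artifacts
#'
#' Reads the inputs, builds the cooperative-regulation, functional-
#' similarity and fused sparse networks, and writes `g_cr.tsv`,
#' `g_fs.tsv`, `g_fused_sparse.tsv`, a `k_selection.json` sidecar (chosen
#' k, per-candidate fit scores, normalization ranges) and the manifest.
#'
#' @param config A `run_config`.
#' @return Invisibly, the `fused_network`.
#' @export
run_build_network <- function(config) {
  inputs <- load_inputs(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  g_cr <- build_coop_network(inputs$x)
  g_fs <- build_functional_network(features(inputs$x), inputs$relations, inputs$provider)
  fn <- build_fused_network(g_cr, g_fs, k_candidates = config$k_candidates)
  write_edgelist(g_cr, file.path(config$out_dir, "g_cr.tsv"))
  write_edgelist(g_fs, file.path(config$out_dir, "g_fs.tsv"))
  write_edgelist(fn$sparse, file.path(config$out_dir, "g_fused_sparse.tsv"))
  cr_ew <- g_cr$w[upper.tri(g_cr$w)]
  fs_ew <- g_fs$w[upper.tri(g_fs$w)]
  jsonlite::write_json(
    list(
      k = fn$k,
      fit_scores = fn$fit_scores,
      normalization = list(
        g_cr = list(min = min(cr_ew), max = max(cr_ew)),
        g_fs = list(min = min(fs_ew), max = max(fs_ew))
      )
    ),
    file.path(config$out_dir, "k_selection.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  write_manifest(config, config$out_dir, "build-network")
  invisible(fn)
}

#' Identify modules and fit the ensemble, writing artifacts
#'
#' Runs the full pipeline on all samples and writes `modules.tsv` (module,
#' rank, miRNA), `importance.tsv`, `ensemble_weights.json`, one
#' `qtable_<seed>.tsv` per seed (sparse nonzero entries), `ensemble.rds`
#' (the fitted model, for [run_predict()]) and the manifest.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with `modules` and `ensemble`.
#' @export
run_identify <- function(config) {
  inputs <- load_inputs(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- rl_config_from_run(config)
  g_cr <- build_coop_network(inputs$x)
  g_fs <- build_functional_network(features(inputs$x), inputs$relations, inputs$provider)
  fn <- build_fused_network(g_cr, g_fs, k_candidates = config$k_candidates)
  mods <- identify_modules(inputs$x, fn, cfg, keep_qtables = TRUE)
  ens <- fit_ensemble(inputs$x, mods,
    cost = cfg$svm_cost, weight_scheme = config$weight_scheme
  )
  mt <- as.data.frame(tidy.mirna_modules(mods))
  utils::write.table(mt[, c("module", "rank", "feature")],
    file.path(config$out_dir, "modules.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  st <- as.data.frame(mods$scores)
  st[-1] <- lapply(st[-1], function(v) format(v, digits = 15, trim = TRUE))
  utils::write.table(st, file.path(config$out_dir, "importance.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  jsonlite::write_json(
    list(
      weights = ens$weights,
      inner_auc = vapply(ens$classifiers, `[[`, numeric(1), "inner_auc"),
      weight_scheme = config$weight_scheme
    ),
    file.path(config$out_dir, "ensemble_weights.json"),
    pretty = TRUE, digits = NA
  )
  for (s in names(mods$qtables)) {
    qt <- as.data.frame(tidy.q_table(mods$qtables[[s]]))
    qt$q <- format(qt$q, digits = 15, trim = TRUE)
    utils::write.table(qt,
      file.path(config$out_dir, sprintf("qtable_%s.tsv", s)),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  saveRDS(ens, file.path(config$out_dir, "ensemble.rds"))
  write_manifest(config, config$out_dir, "identify")
  invisible(list(modules = mods, ensemble = ens, network = fn))
}

#' Evaluate the pipeline by repeated stratified cross-validation
#'
#' Writes `cv_folds.tsv` (per-fold metrics), `cv_report.json` (aggregates)
#' and the manifest.
#'
#' @param config A `run_config`.
#' @return Invisibly, the `eval_report`.
#' @export
run_evaluate <- function(config) {
  inputs <- load_inputs(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- rl_config_from_run(config)
  rep_ <- cross_validate(inputs$x, inputs$relations, inputs$provider, cfg,
    repeats = config$cv_repeats, folds = config$cv_folds,
    k_candidates = config$k_candidates, weight_scheme = config$weight_scheme
  )
  ft <- as.data.frame(rep_$folds)
  num <- vapply(ft, is.numeric, logical(1)) & !(names(ft) %in% c("repeat_", "fold", "n_test"))
  ft[num] <- lapply(ft[num], function(v) format(v, digits = 15, trim = TRUE))
  utils::write.table(ft, file.path(config$out_dir, "cv_folds.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  jsonlite::write_json(as.list(glance.eval_report(rep_)),
    file.path(config$out_dir, "cv_report.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  write_manifest(config, config$out_dir, "evaluate")
  invisible(rep_)
}

#' Generate and write a synthetic dataset
#'
#' @param spec A [synth_spec()].
#' @param out_dir Output directory.
#' @return Invisibly, the `synth_data`.
#' @export
run_simulate <- function(spec, out_dir) {
  d <- simulate_dataset(spec)
  write_dataset(d, out_dir)
  invisible(d)
}

#' Predict new samples with a previously fitted ensemble
#'
#' @param model_path Path to the `ensemble.rds` written by
#'   [run_identify()].
#' @param expression,labels Expression table of the new samples and an
#'   optional label file (when given, an AUC against the known labels is
#'   reported to stderr).
#' @param out_path Output TSV of per-sample scores and predicted labels.
#' @param delim Delimiter override.
#' @return Invisibly, the prediction tibble.
#' @export
run_predict <- function(model_path, expression, labels = NULL,
                        out_path = "predictions.tsv", delim = NULL) {
  ens <- readRDS(model_path)
  tab <- read_delim_table(expression, delim)
  ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  mat <- matrix(as.numeric(mat), nrow(mat), dimnames = list(ids, colnames(mat)))
  if (anyDuplicated(ids)) {
    mat <- rowsum(mat, group = ids) / as.vector(table(ids)[sort(unique(ids))])
  }
  preds <- stats::predict(ens, mat)
  pf <- as.data.frame(preds)
  sc <- vapply(pf, is.numeric, logical(1))
  pf[sc] <- lapply(pf[sc], function(v) format(v, digits = 15, trim = TRUE))
  utils::write.table(pf, out_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(labels)) {
    labs <- read_delim_table(labels, delim)
    lab_map <- stats::setNames(as.character(labs[[2]]), as.character(labs[[1]]))
    y <- factor(lab_map[preds$sample], levels = ens$class_levels)
    sc_mat <- as.matrix(preds[, paste0("score_", ens$class_levels)])
    auc <- if (length(ens$class_levels) == 2) {
      roc_auc(sc_mat[, 2], y == ens$class_levels[2])
    } else {
      roc_auc(sc_mat, y)
    }
    rlang::inform(sprintf("AUC on labelled new samples: %.4f", auc))
  }
  invisible(preds)
}
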