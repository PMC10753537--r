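# Q-learning search for discriminative miRNA modules over the sparse fused
# network. An agent grows a node set from a seed; each added node yields a
# reward combining the set's classification AUC with a size factor that
# favours small modules, and the tabular Q-values are updated toward
# reward + discounted best future value.

#' Q-learning configuration
#'
#' Defaults follow the reference settings: learning rate 0.2, discount 0.8,
#' 2000 episodes, final exploration probability 1e-5, module size limit 50
#' and 5 initial seed nodes.
#'
#' @param alpha Learning rate in (0, 1].
#' @param gamma Discount rate in \[0, 1).
#' @param episodes Number of training episodes K.
#' @param epsilon_final Exploration probability at the last episode.
#' @param size_limit Maximum module size L.
#' @param n_seeds Number of initial seed nodes g.
#' @param auc_mode How module AUC is estimated during search: "cv5"
#'   (stratified 5-fold cross-validation, the default) or "resub"
#'   (resubstitution -- much faster, more optimistic).
#' @param svm_cost Regularization constant of the linear SVM.
#' @param seed RNG seed driving all stochasticity of the search.
#' @return An `rl_config` list.
#' @export
rl_config <- function(alpha = 0.2, gamma = 0.8, episodes = 2000,
                      epsilon_final = 1e-5, size_limit = 50, n_seeds = 5,
                      auc_mode = c("cv5", "resub"), svm_cost = 1, seed = 1L) {
  auc_mode <- match.arg(auc_mode)
  stopifnot(
    alpha > 0, alpha <= 1, gamma >= 0, gamma < 1, episodes >= 1,
    epsilon_final > 0, epsilon_final < 1, size_limit >= 2, n_seeds >= 1,
    svm_cost > 0
  )
  structure(
    list(
      alpha = alpha, gamma = gamma, episodes = as.integer(episodes),
      epsilon_final = epsilon_final, size_limit = as.integer(size_limit),
      n_seeds = as.integer(n_seeds), auc_mode = auc_mode,
      svm_cost = svm_cost, seed = as.integer(seed)
    ),
    class = "rl_config"
  )
}

#' Exploration probability schedule
#'
#' Decays exponentially from 1 at episode 0 to `epsilon_final` at episode
#' `episodes`: `epsilon_final^(e / episodes)`.
#'
#' @param e Current episode index (0 to `episodes`).
#' @param episodes Total episode count K.
#' @param epsilon_final Final exploration probability.
#' @return Exploration probability in (0, 1].
#' @examples
#' epsilon_schedule(0, 2000)
#' epsilon_schedule(1000, 2000)
#' @export
epsilon_schedule <- function(e, episodes, epsilon_final = 1e-5) {
  epsilon_final^(e / episodes)
}

#' Module reward: AUC times size factor
#'
#' `R = auc * (1 + sqrt(1 / size))`; strictly increasing in AUC at fixed
#' size and strictly decreasing in size at fixed AUC, so small accurate
#' modules earn the most.
#'
#' @param auc Classification AUC of the module, in `[0, 1]`.
#' @param size Module size (>= 1).
#' @return The reward value.
#' @examples
#' reward(0.8, 4)
#' @export
reward <- function(auc, size) {
  stopifnot(size >= 1)
  auc * (1 + sqrt(1 / size))
}

#' One tabular Q-learning update
#'
#' `q + alpha * (r + gamma * max_next - q)`, where `max_next` is the
#' maximum Q-value over the next state's action space (0 for an empty
#' action space).
#'
#' @param q Current Q-value of the (state, action) pair.
#' @param r Immediate reward.
#' @param max_next Maximum Q-value at the successor state.
#' @param alpha Learning rate.
#' @param gamma Discount rate.
#' @return Updated Q-value.
#' @examples
#' q_update(0, 1.2, 0, alpha = 0.2, gamma = 0.8)
#' @export
q_update <- function(q, r, max_next, alpha = 0.2, gamma = 0.8) {
  q + alpha * (r + gamma * max_next - q)
}

# -- linear SVM scoring ------------------------------------------------------

uv_scale_params <- function(mat) {
  mu <- colMeans(mat)
  sdev <- apply(mat, 2, stats::sd)
  sdev[sdev == 0] <- 1
  list(mean = mu, sd = sdev)
}

uv_apply <- function(mat, params) {
  sweep(sweep(mat, 2, params$mean), 2, params$sd, "/")
}

# Fit linear-kernel SVM(s) and return a closure producing an
# n x n_classes matrix of decision scores (one-vs-rest for >= 3 classes).
fit_svm_scorer <- function(train, y, cost = 1) {
  lev <- levels(y)
  if (length(lev) == 2) {
    fit <- e1071::svm(train, y,
      kernel = "linear", cost = cost, scale = FALSE, probability = FALSE
    )
    # decision column "A/B": positive values favour class A
    pos_first <- startsWith(
      colnames(attr(stats::predict(fit, train[1, , drop = FALSE],
        decision.values = TRUE
      ), "decision.values")), paste0(lev[1], "/")
    )
    function(newx) {
      d <- as.numeric(attr(
        stats::predict(fit, newx, decision.values = TRUE), "decision.values"
      ))
      s2 <- if (pos_first) -d else d # score for the second level
      cbind(-s2, s2, deparse.level = 0)
    }
  } else {
    fits <- lapply(lev, function(cl) {
      yb <- factor(ifelse(y == cl, "pos", "rest"), levels = c("rest", "pos"))
      fit <- e1071::svm(train, yb,
        kernel = "linear", cost = cost, scale = FALSE
      )
      pos_first <- startsWith(colnames(attr(stats::predict(fit, train[1, , drop = FALSE],
        decision.values = TRUE
      ), "decision.values")), "pos/")
      list(fit = fit, pos_first = pos_first)
    })
    function(newx) {
      vapply(fits, function(f) {
        d <- as.numeric(attr(
          stats::predict(f$fit, newx, decision.values = TRUE), "decision.values"
        ))
        if (f$pos_first) d else -d
      }, numeric(nrow(newx)))
    }
  }
}

# Macro one-vs-rest AUC from a score matrix (n x n_classes).
macro_auc_from_scores <- function(scores, y) {
  lev <- levels(y)
  if (length(lev) == 2) {
    return(roc_auc(scores[, 2], y == lev[2]))
  }
  aucs <- vapply(seq_along(lev), function(ci) {
    pos <- y == lev[ci]
    if (!any(pos) || all(pos)) return(NA_real_)
    roc_auc(scores[, ci], pos)
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Classification AUC of a candidate module
#'
#' Trains a linear-kernel SVM on the unit-variance-scaled expression of the
#' module's features and reports AUC: either the mean over a deterministic
#' stratified 5-fold cross-validation (`mode = "cv5"`) or the
#' resubstitution AUC of the decision scores on the training samples
#' (`mode = "resub"`). Multi-class problems are scored macro one-vs-rest.
#'
#' @param x An [expr_matrix()].
#' @param members Character vector of module feature ids.
#' @param mode "cv5" or "resub".
#' @param cost SVM regularization constant.
#' @return AUC in `[0, 1]`.
#' @export
module_auc <- function(x, members, mode = c("cv5", "resub"), cost = 1) {
  mode <- match.arg(mode)
  if (length(members) == 0) rlang::abort("module must be nonempty")
  mat <- t(x$values[members, , drop = FALSE])
  y <- x$labels
  if (mode == "resub") {
    params <- uv_scale_params(mat)
    sc <- uv_apply(mat, params)
    scorer <- fit_svm_scorer(sc, y, cost)
    macro_auc_from_scores(scorer(sc), y)
  } else {
    n_folds <- min(5L, min(table(y)))
    fold <- stratified_folds_fixed(y, n_folds)
    aucs <- vapply(seq_len(n_folds), function(f) {
      tr <- fold != f
      params <- uv_scale_params(mat[tr, , drop = FALSE])
      scorer <- fit_svm_scorer(uv_apply(mat[tr, , drop = FALSE], params),
        droplevels(y[tr]),
        cost = cost
      )
      sc_te <- scorer(uv_apply(mat[!tr, , drop = FALSE], params))
      macro_auc_from_scores(sc_te, droplevels(y[!tr]))
    }, numeric(1))
    mean(aucs)
  }
}

# Memoizing wrapper: node-index sets -> AUC. Used inside the episode loop
# so repeated visits to the same set cost one SVM evaluation in total.
make_auc_fun <- function(x, mode, cost) {
  cache <- new.env(parent = emptyenv())
  ids <- features(x)
  function(idx) {
    key <- paste(idx, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    v <- module_auc(x, ids[idx], mode = mode, cost = cost)
    assign(key, v, envir = cache)
    v
  }
}

# -- training and extraction -------------------------------------------------

# Core episodic Q-learning loop on an adjacency structure with an
# arbitrary AUC oracle; all randomness comes from the current RNG stream.
rl_train <- function(adj, auc_fun, seed_idx, cfg) {
  m <- nrow(adj)
  nbrs <- lapply(seq_len(m), function(i) which(adj[i, ]))
  Q <- matrix(0, m, m)
  K <- cfg$episodes
  log_steps <- integer(K)
  log_auc <- numeric(K)
  for (e in seq_len(K)) {
    eps <- epsilon_schedule(e, K, cfg$epsilon_final)
    in_set <- logical(m)
    in_set[seed_idx] <- TRUE
    frontier <- logical(m)
    frontier[nbrs[[seed_idx]]] <- TRUE
    f_s <- seed_idx
    size <- 1L
    auc <- NA_real_
    steps <- 0L
    repeat {
      action_space <- which(frontier & !in_set)
      if (length(action_space) == 0) break
      f_a <- if (stats::runif(1) < eps) {
        action_space[sample.int(length(action_space), 1)]
      } else {
        # which.max returns the first (lowest-index = lexicographic) maximum
        action_space[which.max(Q[f_s, action_space])]
      }
      in_set[f_a] <- TRUE
      frontier[nbrs[[f_a]]] <- TRUE
      size <- size + 1L
      steps <- steps + 1L
      auc <- auc_fun(which(in_set))
      r <- reward(auc, size)
      nxt_space <- which(frontier & !in_set)
      max_next <- if (length(nxt_space) == 0) 0 else max(Q[f_a, nxt_space])
      Q[f_s, f_a] <- q_update(Q[f_s, f_a], r, max_next, cfg$alpha, cfg$gamma)
      f_s <- f_a
      if (auc >= 1 - 1e-9 || size >= cfg$size_limit) break
    }
    log_steps[e] <- steps
    log_auc[e] <- auc
  }
  list(Q = Q, episode_log = tibble::tibble(
    episode = seq_len(K), steps = log_steps, terminal_auc = log_auc
  ))
}

# Greedy (epsilon = 0) module extraction from a learned Q-table. Candidate
# actions are the sparse-graph neighbours of the current module (members
# included, so revisiting a member is observable and stops the walk).
rl_extract <- function(adj, auc_fun, Q, seed_idx, cfg) {
  m <- nrow(adj)
  nbrs <- lapply(seq_len(m), function(i) which(adj[i, ]))
  members <- seed_idx
  in_set <- logical(m)
  in_set[seed_idx] <- TRUE
  frontier <- logical(m)
  frontier[nbrs[[seed_idx]]] <- TRUE
  f_s <- seed_idx
  auc <- auc_fun(seed_idx)
  repeat {
    if (auc >= 1 - 1e-9 || length(members) >= cfg$size_limit) break
    cand <- which(frontier) # may include members
    if (length(cand) == 0) break
    qv <- Q[f_s, cand]
    if (max(qv) <= 0) break # no positive-Q action learned
    f_a <- cand[which.max(qv)]
    if (in_set[f_a]) break # action already a member: stop extension
    members <- c(members, f_a)
    in_set[f_a] <- TRUE
    frontier[nbrs[[f_a]]] <- TRUE
    f_s <- f_a
    auc <- auc_fun(sort(members))
  }
  list(members = members, auc = auc)
}

#' Comprehensive importance scores for seed selection
#'
#' Combines each feature's individual distinguishing ability (min-max
#' normalized `-log p` of its own group-difference rank test) with its
#' topological importance (min-max normalized closeness centrality in the
#' unweighted sparse network): `I = (I_e + I_t) / 2`.
#'
#' @param x An [expr_matrix()].
#' @param sparse The sparse fused `mirna_graph` (connected).
#' @return Tibble with columns `feature`, `p_value`, `i_e`, `i_t`,
#'   `importance`, ordered by decreasing importance (feature id breaks
#'   ties).
#' @export
importance_scores <- function(x, sparse) {
  ids <- features(x)
  if (!identical(ids, sparse$nodes)) {
    rlang::abort("expression features and network nodes differ")
  }
  pvals <- vapply(
    seq_along(ids),
    function(i) group_test_pvalue(x$values[i, ], x$labels), numeric(1)
  )
  i_e <- minmax(-log(pmax(pvals, P_FLOOR)))
  cc <- igraph::closeness(as_igraph(sparse, weighted = FALSE), normalized = TRUE)
  i_t <- minmax(as.numeric(cc))
  out <- tibble::tibble(
    feature = ids, p_value = pvals, i_e = i_e, i_t = i_t,
    importance = (i_e + i_t) / 2
  )
  dplyr::arrange(out, dplyr::desc(.data$importance), .data$feature)
}

#' Train a Q-table for one seed node
#'
#' Runs `cfg$episodes` episodes of epsilon-greedy search from `seed_node`
#' over the sparse network. Each episode restarts the visited set at the
#' seed; the action space is the set of sparse-graph neighbours of any
#' visited node minus the visited nodes; an episode ends when the module
#' AUC reaches 1, the size limit is hit or the action space empties.
#'
#' Stochasticity comes only from the current RNG stream; call
#' `set.seed()` (or use [identify_modules()], which does) for reproducible
#' training.
#'
#' @param sparse Sparse fused `mirna_graph`.
#' @param x An [expr_matrix()] (scoring data).
#' @param seed_node Feature id of the initial state node.
#' @param cfg An [rl_config()].
#' @param auc_fun Optional AUC oracle `function(node_indices) -> auc`
#'   overriding the SVM-based module AUC (used for toy environments).
#' @return A `q_table` object.
#' @export
train_qtable <- function(sparse, x = NULL, seed_node, cfg = rl_config(),
                         auc_fun = NULL) {
  seed_idx <- match(seed_node, sparse$nodes)
  if (is.na(seed_idx)) rlang::abort(sprintf("seed node '%s' not in network", seed_node))
  if (is.null(auc_fun)) {
    auc_fun <- make_auc_fun(x, cfg$auc_mode, cfg$svm_cost)
  }
  res <- rl_train(sparse$adj, auc_fun, seed_idx, cfg)
  structure(
    list(
      Q = res$Q, nodes = sparse$nodes, seed_node = seed_node,
      episode_log = res$episode_log, cfg = cfg
    ),
    class = "q_table"
  )
}

#' @export
print.q_table <- function(x, ...) {
  cat(sprintf(
    "<q_table> seed '%s', %d nodes, %d nonzero entries over %d episodes\n",
    x$seed_node, length(x$nodes), sum(x$Q != 0), nrow(x$episode_log)
  ))
  invisible(x)
}

#' Tidy a Q-table into its nonzero (state, action) entries
#' @param x A `q_table`.
#' @param ... Unused.
#' @return Tibble with columns `state`, `action`, `q`, ordered by state
#'   then action.
#' @method tidy q_table
#' @export
tidy.q_table <- function(x, ...) {
  nz <- which(x$Q != 0, arr.ind = TRUE)
  nz <- nz[order(nz[, 1], nz[, 2]), , drop = FALSE]
  tibble::tibble(
    state = x$nodes[nz[, 1]],
    action = x$nodes[nz[, 2]],
    q = x$Q[nz]
  )
}

#' Extract a module by greedy walk over a learned Q-table
#'
#' Starting from the seed node, repeatedly takes the argmax-Q action among
#' the sparse-graph neighbours of the current module (deterministic,
#' exploration turned off; ties break lexicographically). The walk stops
#' when the module AUC reaches 1, when the chosen action is already a
#' member, when no action has positive Q, or at the size limit.
#'
#' @param sparse Sparse fused `mirna_graph`.
#' @param x An [expr_matrix()], or `NULL` when `auc_fun` is given.
#' @param qtab A `q_table` from [train_qtable()].
#' @param cfg An [rl_config()].
#' @param auc_fun Optional AUC oracle as in [train_qtable()].
#' @return A `mirna_module`: list with `seed`, `members` (in addition
#'   order) and `auc`.
#' @export
extract_module <- function(sparse, x = NULL, qtab, cfg = rl_config(),
                           auc_fun = NULL) {
  seed_idx <- match(qtab$seed_node, sparse$nodes)
  if (is.null(auc_fun)) {
    auc_fun <- make_auc_fun(x, cfg$auc_mode, cfg$svm_cost)
  }
  res <- rl_extract(sparse$adj, auc_fun, qtab$Q, seed_idx, cfg)
  structure(
    list(
      seed = qtab$seed_node,
      members = sparse$nodes[res$members],
      auc = res$auc
    ),
    class = "mirna_module"
  )
}

#' @export
print.mirna_module <- function(x, ...) {
  cat(sprintf(
    "<mirna_module> seed '%s', %d members, AUC %.3f\n  %s\n",
    x$seed, length(x$members), x$auc, paste(x$members, collapse = ", ")
  ))
  invisible(x)
}

#' Identify miRNA modules by Q-learning from the top-importance seeds
#'
#' Selects the `cfg$n_seeds` features with the highest comprehensive
#' importance ([importance_scores()]) as seeds, trains one Q-table per seed
#' and extracts one module per seed by greedy walk. Duplicate or
#' overlapping modules are kept; the downstream weighted-voting ensemble
#' handles redundancy. The entire search is reproducible from `cfg$seed`.
#'
#' @param x An [expr_matrix()].
#' @param network A `fused_network` (its sparse layer is used) or a sparse
#'   `mirna_graph`.
#' @param cfg An [rl_config()].
#' @param keep_qtables Keep the per-seed Q-tables in the result.
#' @return A `mirna_modules` object: list of modules plus the importance
#'   table and configuration.
#' @examples
#' \donttest{
#' d <- simulate_dataset(synth_spec(m = 15, n_per_class = 10, seed = 1))
#' fn <- build_fused_network(
#'   build_coop_network(d$expression),
#'   build_functional_network(features(d$expression), d$relations,
#'                            table_embedding_provider(d$embeddings))
#' )
#' mods <- identify_modules(d$expression, fn,
#'   cfg = rl_config(episodes = 30, size_limit = 6, n_seeds = 2,
#'                   auc_mode = "resub"))
#' tidy(mods)
#' }
#' @export
identify_modules <- function(x, network, cfg = rl_config(), keep_qtables = TRUE) {
  sparse <- if (inherits(network, "fused_network")) network$sparse else network
  if (cfg$n_seeds > length(sparse$nodes)) {
    rlang::abort("more seeds requested than network nodes")
  }
  scores <- importance_scores(x, sparse)
  seeds <- scores$feature[seq_len(cfg$n_seeds)]
  auc_fun <- make_auc_fun(x, cfg$auc_mode, cfg$svm_cost)
  set.seed(cfg$seed)
  qtabs <- list()
  modules <- vector("list", length(seeds))
  for (si in seq_along(seeds)) {
    qt <- train_qtable(sparse, x, seeds[si], cfg, auc_fun = auc_fun)
    modules[[si]] <- extract_module(sparse, x, qt, cfg, auc_fun = auc_fun)
    if (keep_qtables) qtabs[[seeds[si]]] <- qt
  }
  structure(
    list(
      modules = modules, seeds = seeds, scores = scores, cfg = cfg,
      qtables = if (keep_qtables) qtabs else NULL
    ),
    class = "mirna_modules"
  )
}

#' @export
print.mirna_modules <- function(x, ...) {
  cat(sprintf("<mirna_modules> %d modules\n", length(x$modules)))
  for (i in seq_along(x$modules)) {
    m <- x$modules[[i]]
    cat(sprintf(
      "  %d. seed '%s' (%d members, AUC %.3f): %s\n",
      i, m$seed, length(m$members), m$auc, paste(m$members, collapse = ", ")
    ))
  }
  invisible(x)
}

#' Tidy identified modules into a long membership table
#' @param x A `mirna_modules` object.
#' @param ... Unused.
#' @return Tibble with columns `module`, `rank`, `feature`, `seed`, `auc`.
#' @method tidy mirna_modules
#' @export
tidy.mirna_modules <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$modules), function(i) {
    m <- x$modules[[i]]
    tibble::tibble(
      module = i, rank = seq_along(m$members), feature = m$members,
      seed = m$seed, auc = m$auc
    )
  }))
}

#' @method glance mirna_modules
#' @export
glance.mirna_modules <- function(x, ...) {
  sizes <- lengths(lapply(x$modules, `[[`, "members"))
  tibble::tibble(
    n_modules = length(x$modules),
    mean_size = mean(sizes),
    max_size = max(sizes),
    mean_auc = mean(vapply(x$modules, `[[`, numeric(1), "auc"))
  )
}

#' All features used by a set of modules
#' @param mods A `mirna_modules` object.
#' @return Sorted character vector of the union of module members.
#' @export
module_features <- function(mods) {
  sort(unique(unlist(lapply(mods$modules, `[[`, "members"))))
}
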