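# Synthetic data with planted discriminative modules, plus matching
# relation tables and disease-term embeddings, so every pipeline stage is
# testable offline. The defaults emulate the shape of the real microarray
# case the pipeline targets at desk scale: tens of features, tens of
# samples per class, one planted module.

#' Specification for a synthetic dataset
#'
#' Background features are identically distributed across classes. Each
#' planted module's members receive class-specific mean shifts `c * delta *
#' mult_r`, where `c` is the 0-based class index and the member-specific
#' multipliers `mult_r` are evenly spaced in `[0.5, 1.5]`. The multipliers
#' make the members' pairwise differences group-differential too (shifted
#' identically, they would cancel), matching the relative-expression signal
#' the cooperative-regulation network is built to detect. Members of a
#' planted module share a fraction `rho` of their disease terms, drawn from
#' one disease "family"; family structure in the embeddings makes shared
#' terms mutually similar, so functional-similarity edges inside planted
#' modules are strong.
#'
#' @param m Total feature count.
#' @param n_per_class Samples per class.
#' @param n_classes 2 or 3.
#' @param modules List of planted module specs, each a list with `size`,
#'   `delta` (shift effect size, >= 0) and `rho` (within-module disease
#'   overlap in `[0, 1]`).
#' @param noise_sd Residual standard deviation of all features.
#' @param n_families Number of disease families in the vocabulary.
#' @param diseases_per_family Terms per family.
#' @param terms_per_mirna Disease terms attached to each miRNA.
#' @param emb_dim Embedding dimensionality.
#' @param seed RNG seed; the same spec always generates identical data.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(m = 30, n_per_class = 20, n_classes = 2,
                       modules = list(list(size = 5, delta = 2, rho = 0.8)),
                       noise_sd = 1, n_families = 4, diseases_per_family = 10,
                       terms_per_mirna = 4, emb_dim = 16, seed = 1L) {
  stopifnot(
    m >= 2, n_per_class >= 2, n_classes %in% c(2, 3),
    noise_sd > 0, emb_dim >= 2, terms_per_mirna >= 1
  )
  sizes <- vapply(modules, `[[`, numeric(1), "size")
  if (sum(sizes) > m) rlang::abort("planted module sizes exceed feature count")
  for (mod in modules) {
    stopifnot(mod$delta >= 0, mod$rho >= 0, mod$rho <= 1, mod$size >= 1)
  }
  structure(
    list(
      m = as.integer(m), n_per_class = as.integer(n_per_class),
      n_classes = as.integer(n_classes), modules = modules,
      noise_sd = noise_sd, n_families = as.integer(n_families),
      diseases_per_family = as.integer(diseases_per_family),
      terms_per_mirna = as.integer(terms_per_mirna),
      emb_dim = as.integer(emb_dim), seed = as.integer(seed)
    ),
    class = "synth_spec"
  )
}

#' Generate a synthetic dataset from a specification
#'
#' @param spec A [synth_spec()].
#' @return A `synth_data` list: `expression` ([expr_matrix()]),
#'   `relations` (`disease_relations`), `embeddings` (`embedding_table`)
#'   and `truth` (planted module memberships and the spec).
#' @examples
#' d <- simulate_dataset(synth_spec(m = 12, n_per_class = 6, seed = 7))
#' d$truth$modules
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  m <- spec$m
  n <- spec$n_per_class * spec$n_classes
  feat_ids <- sprintf("mir%03d", seq_len(m))
  sample_ids <- sprintf("s%03d", seq_len(n))
  classes <- rep(seq_len(spec$n_classes) - 1L, each = spec$n_per_class)
  labels <- paste0("class", classes)

  vals <- matrix(stats::rnorm(m * n, sd = spec$noise_sd), m, n,
    dimnames = list(feat_ids, sample_ids)
  )

  # planted modules occupy the first features, in order
  truth_modules <- list()
  nxt <- 1L
  for (mi in seq_along(spec$modules)) {
    mod <- spec$modules[[mi]]
    members <- feat_ids[seq(nxt, nxt + mod$size - 1L)]
    nxt <- nxt + mod$size
    mult <- if (mod$size == 1) 1 else 0.5 + (seq_len(mod$size) - 1) / (mod$size - 1)
    for (r in seq_along(members)) {
      vals[members[r], ] <- vals[members[r], ] + classes * mod$delta * mult[r]
    }
    truth_modules[[mi]] <- members
  }

  # disease vocabulary organized in families
  vocab <- outer(
    seq_len(spec$n_families), seq_len(spec$diseases_per_family),
    function(f, d) sprintf("disease f%02d t%02d", f, d)
  )
  family_of <- rep(seq_len(spec$n_families), times = spec$diseases_per_family)
  dim(family_of) <- dim(vocab)

  # relations: planted members share round(rho * terms) family terms;
  # everything else draws uniformly from the vocabulary
  rel <- list()
  all_terms <- as.vector(vocab)
  for (fid in feat_ids) {
    rel[[fid]] <- sample(all_terms, spec$terms_per_mirna)
  }
  for (mi in seq_along(spec$modules)) {
    mod <- spec$modules[[mi]]
    fam <- 1L + ((mi - 1L) %% spec$n_families)
    fam_terms <- vocab[fam, ]
    n_shared <- round(mod$rho * spec$terms_per_mirna)
    shared <- if (n_shared > 0) sample(fam_terms, min(n_shared, length(fam_terms))) else character(0)
    for (fid in truth_modules[[mi]]) {
      extra <- sample(setdiff(all_terms, shared), spec$terms_per_mirna - length(shared))
      rel[[fid]] <- c(shared, extra)
    }
  }
  relations <- disease_relations(rel)

  # embeddings: unit-normalized family centre + isotropic noise
  centres <- matrix(stats::rnorm(spec$n_families * spec$emb_dim), spec$n_families)
  centres <- centres / sqrt(rowSums(centres^2))
  emb <- t(vapply(seq_along(all_terms), function(ti) {
    fam <- family_of[ti]
    v <- centres[fam, ] + stats::rnorm(spec$emb_dim, sd = 0.15)
    v / sqrt(sum(v^2))
  }, numeric(spec$emb_dim)))
  rownames(emb) <- all_terms

  structure(
    list(
      expression = expr_matrix(vals, labels),
      relations = relations,
      embeddings = embedding_table(emb),
      truth = list(modules = truth_modules, spec = spec)
    ),
    class = "synth_data"
  )
}

#' @export
print.synth_data <- function(x, ...) {
  cat(sprintf(
    "<synth_data> %d features x %d samples, %d planted module(s)\n",
    nrow(x$expression$values), ncol(x$expression$values),
    length(x$truth$modules)
  ))
  invisible(x)
}

#' Write a synthetic dataset to disk in the formats the readers consume
#'
#' Writes `expression.tsv`, `labels.tsv`, `relations.tsv`,
#' `embeddings.tsv` and `truth.json` under `dir`.
#'
#' @param d A `synth_data` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_dataset <- function(d, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(
    d$expression,
    file.path(dir, "expression.tsv"), file.path(dir, "labels.tsv")
  )
  write_relations(d$relations, file.path(dir, "relations.tsv"))
  write_embeddings(d$embeddings, file.path(dir, "embeddings.tsv"))
  jsonlite::write_json(
    list(modules = d$truth$modules),
    file.path(dir, "truth.json"),
    auto_unbox = FALSE, pretty = TRUE
  )
  invisible(dir)
}

#' Fixed toy environment for the Q-learning search
#'
#' A 5-node graph (`a`--`e`; edges a-b, b-c, b-d, c-d, d-e) with a
#' hand-specified AUC for every connected node set, small enough that the
#' optimal module (by reward = AUC x size factor) is known exactly: from
#' seed `b` it is `{b, c}`, whose AUC of 1 also terminates episodes. All
#' other multi-node sets have low AUC, so accumulating many small rewards
#' along a long episode is worth less than the single large terminal
#' reward -- the property the designed optimum relies on.
#'
#' @return A list with `graph` (a `mirna_graph`), `auc_fun` (maps a sorted
#'   node-index vector to AUC), `auc_of_set` (same, by node names),
#'   `seed_node` (`"b"`) and `optimal` (`c("b", "c")`).
#' @export
toy_rl_environment <- function() {
  nodes <- c("a", "b", "c", "d", "e")
  edges <- rbind(c(1, 2), c(2, 3), c(2, 4), c(3, 4), c(4, 5))
  adj <- matrix(FALSE, 5, 5)
  adj[edges] <- TRUE
  adj <- adj | t(adj)
  w <- matrix(0, 5, 5)
  w[adj] <- 1
  graph <- mirna_graph(nodes, w, adj = adj, complete = FALSE)

  auc_of_set <- function(members) {
    key <- paste(sort(members), collapse = "+")
    if (key == "b") return(0.55)
    if (key == "b+c") return(1.0)
    if (length(members) == 1) return(0.5)
    0.3
  }
  auc_fun <- function(idx) auc_of_set(nodes[idx])
  list(
    graph = graph, auc_fun = auc_fun, auc_of_set = auc_of_set,
    seed_node = "b", optimal = c("b", "c")
  )
}

#' Enumerate the connected node subsets of a small graph
#'
#' Exhaustive (2^m) enumeration; intended for toy-scale oracles.
#'
#' @param g A `mirna_graph` with at most 20 nodes.
#' @param max_size Largest subset size to keep (default all).
#' @return List of character vectors (sorted node names).
#' @export
connected_subsets <- function(g, max_size = length(g$nodes)) {
  m <- length(g$nodes)
  if (m > 20) rlang::abort("exhaustive enumeration limited to 20 nodes")
  out <- list()
  for (code in seq_len(2^m - 1)) {
    idx <- which(bitwAnd(code, 2^(seq_len(m) - 1)) > 0)
    if (length(idx) > max_size) next
    sub <- g$adj[idx, idx, drop = FALSE]
    comp <- igraph::components(igraph::graph_from_adjacency_matrix(
      sub * 1,
      mode = "undirected"
    ))
    if (comp$no == 1) out[[length(out) + 1]] <- g$nodes[idx]
  }
  out
}
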