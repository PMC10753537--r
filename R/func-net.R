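# Functional-similarity view: miRNAs that regulate semantically similar
# disease sets are functionally similar. Disease terms are embedded as
# numeric vectors by a pluggable provider; set-to-set similarity is a
# softmax-weighted best-matching average over the pairwise cosine matrix.

#' Cosine similarity of two vectors
#'
#' @param a,b Numeric vectors of equal length; both must be nonzero.
#' @return `dot(a, b) / (|a| |b|)`, in `[-1, 1]`.
#' @examples
#' cosine_similarity(c(1, 0), c(0, 1))
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) rlang::abort("vectors must have equal length")
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) rlang::abort("cosine similarity undefined for a zero vector")
  min(max(sum(a * b) / (na * nb), -1), 1)
}

#' Embedding providers
#'
#' An embedding provider maps disease terms to fixed-length numeric
#' vectors, deterministically within a run. `table_embedding_provider()`
#' looks terms up in an [embedding_table()] (for example one read with
#' [read_embeddings()], standing in for a biomedical language model's
#' output). `mock_embedding_provider()` derives a deterministic
#' unit-length vector from a hash of the term itself -- self-contained and
#' reproducible, intended for tests and examples.
#'
#' @param table An `embedding_table`.
#' @param dim Embedding dimensionality of the mock provider.
#' @param seed Integer mixed into the mock hash.
#' @return An `embedding_provider`: call [embed_terms()] to use it.
#' @name embedding_provider
NULL

new_embedding_provider <- function(fun, dim, label) {
  structure(list(fun = fun, dim = dim, label = label), class = "embedding_provider")
}

#' @export
print.embedding_provider <- function(x, ...) {
  cat(sprintf("<embedding_provider> %s, dimension %d\n", x$label, x$dim))
  invisible(x)
}

#' @rdname embedding_provider
#' @export
table_embedding_provider <- function(table) {
  stopifnot(inherits(table, "embedding_table"))
  new_embedding_provider(function(terms) {
    miss <- setdiff(terms, rownames(table))
    if (length(miss) > 0) {
      rlang::abort(sprintf(
        "no embedding for term(s): %s", paste(utils::head(miss, 5), collapse = ", ")
      ))
    }
    out <- table[terms, , drop = FALSE]
    zero <- rowSums(out^2) == 0
    if (any(zero)) {
      rlang::abort(sprintf("all-zero embedding for term '%s'", terms[zero][1]))
    }
    unclass(out)
  }, dim = ncol(table), label = "table-backed")
}

#' @rdname embedding_provider
#' @export
mock_embedding_provider <- function(dim = 16, seed = 0) {
  fun <- function(terms) {
    out <- t(vapply(terms, function(tm) {
      # polynomial rolling hash -> tiny LCG stream; no global RNG touched
      h <- (sum(utf8ToInt(tm) * (31^(seq_along(utf8ToInt(tm)) %% 8)))) %% 2147483647
      h <- (h + seed * 104729) %% 2147483647
      if (h == 0) h <- 1
      v <- numeric(dim)
      s <- h
      for (d in seq_len(dim)) {
        s <- (s * 48271) %% 2147483647
        v[d] <- stats::qnorm((s + 1) / 2147483649)
      }
      v / sqrt(sum(v^2))
    }, numeric(dim)))
    rownames(out) <- terms
    out
  }
  new_embedding_provider(fun, dim = dim, label = "deterministic mock")
}

#' Embed a set of terms
#'
#' Terms are canonicalized and each distinct term embedded exactly once.
#'
#' @param provider An `embedding_provider`.
#' @param terms Character vector of disease terms.
#' @return Numeric matrix, one row per input term.
#' @export
embed_terms <- function(provider, terms) {
  terms <- canonical_term(terms)
  uniq <- unique(terms)
  mat <- provider$fun(uniq)
  mat[match(terms, uniq), , drop = FALSE]
}

# Weighted best-matching average of a p x q cosine-similarity matrix:
# softmax row weights (over columns) plus softmax column weights (over
# rows), each weighted sum of similarities, divided by p + q.
best_matching_average <- function(S) {
  p <- nrow(S)
  q <- ncol(S)
  E <- exp(abs(S))
  eta <- E / rowSums(E)              # each row sums to 1
  xi <- sweep(E, 2, colSums(E), "/") # each column sums to 1
  (sum(eta * S) + sum(xi * S)) / (p + q)
}

#' MiRNA functional similarity from two disease sets
#'
#' Embeds both disease sets, forms the p x q cosine-similarity matrix and
#' aggregates it by the weighted best-matching average: each disease in one
#' set is softly matched to its most similar diseases in the other set
#' (softmax weights on `exp(abs(sim))`), in both directions, and the
#' weighted sums are divided by `p + q`. Either set being empty yields
#' similarity 0.
#'
#' @param d_i,d_j Character vectors of disease terms.
#' @param provider An `embedding_provider`.
#' @return Similarity in `[-1, 1]` (in `[0, 1]` when all cosines are
#'   non-negative).
#' @examples
#' prov <- mock_embedding_provider(dim = 8)
#' mirna_functional_similarity(c("colon cancer"), c("colon cancer"), prov)
#' @export
mirna_functional_similarity <- function(d_i, d_j, provider) {
  d_i <- unique(canonical_term(d_i))
  d_j <- unique(canonical_term(d_j))
  if (length(d_i) == 0 || length(d_j) == 0) return(0)
  all_terms <- unique(c(d_i, d_j))
  emb <- embed_terms(provider, all_terms)
  emb <- emb / sqrt(rowSums(emb^2))
  S <- emb[match(d_i, all_terms), , drop = FALSE] %*%
    t(emb[match(d_j, all_terms), , drop = FALSE])
  S[S > 1] <- 1
  S[S < -1] <- -1
  best_matching_average(S)
}

#' Build the functional-similarity network
#'
#' Complete graph on the feature set with edge weights given by
#' [mirna_functional_similarity()] of the two features' disease sets.
#' Features absent from the relation map contribute edges of weight 0 (their
#' fused weight then comes entirely from the cooperative-regulation view).
#' Negative similarities, possible for arbitrary embeddings, are clamped to
#' 0 so the graph's non-negativity invariant holds; set `clamp = FALSE` to
#' inspect raw values in the returned graph's `raw` attribute.
#'
#' Each distinct disease term is embedded exactly once per build.
#'
#' @param feature_ids Character vector of miRNA accessions (the expression
#'   features).
#' @param relations A `disease_relations` map.
#' @param provider An `embedding_provider`.
#' @param clamp Clamp negative similarities to 0 (default `TRUE`).
#' @return A complete `mirna_graph`; when `clamp = TRUE` the unclamped
#'   weights are kept in `attr(, "raw")`.
#' @export
build_functional_network <- function(feature_ids, relations, provider, clamp = TRUE) {
  feature_ids <- sort(feature_ids)
  m <- length(feature_ids)
  if (m < 2) rlang::abort("need >=2 features to build a network")
  sets <- lapply(feature_ids, function(f) {
    if (f %in% names(relations)) relations[[f]] else character(0)
  })
  terms <- unique(unlist(sets))
  w <- matrix(0, m, m, dimnames = list(feature_ids, feature_ids))
  if (length(terms) > 0) {
    emb <- embed_terms(provider, terms) # one embedding call per distinct term
    emb <- emb / sqrt(rowSums(emb^2))
    cos_all <- tcrossprod(emb)
    cos_all[cos_all > 1] <- 1
    cos_all[cos_all < -1] <- -1
    idx <- lapply(sets, function(s) match(s, terms))
    for (i in seq_len(m - 1)) {
      if (length(idx[[i]]) == 0) next
      for (j in seq((i + 1), m)) {
        if (length(idx[[j]]) == 0) next
        S <- cos_all[idx[[i]], idx[[j]], drop = FALSE]
        w[i, j] <- best_matching_average(S)
      }
    }
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
  }
  raw <- w
  if (clamp) w[w < 0] <- 0 else if (any(w < 0)) {
    rlang::abort("negative similarities present; use clamp = TRUE for a valid graph")
  }
  g <- mirna_graph(feature_ids, w, complete = TRUE)
  attr(g, "raw") <- raw
  g
}
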