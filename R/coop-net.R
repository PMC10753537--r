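#' Pairwise combination feature
#'
#' The relative-expression feature of two miRNAs: the element-wise
#' difference of their sample vectors. Dysregulation of this difference
#' between sample groups is read as a change in the pair's cooperative
#' regulation.
#'
#' @param x_i,x_j Numeric sample vectors of equal length.
#' @return `x_i - x_j`.
#' @examples
#' combination_feature(c(1, 2, 3), c(1, 1, 1))
#' @export
combination_feature <- function(x_i, x_j) {
  if (length(x_i) != length(x_j)) {
    rlang::abort(sprintf("length mismatch: %d vs %d", length(x_i), length(x_j)))
  }
  x_i - x_j
}

# Smallest p-value kept; caps edge weights at -log(1e-16) ~ 36.8
P_FLOOR <- 1e-16

# Group-difference p-value of a numeric vector: two-sided Mann-Whitney U
# for two classes (exact when both groups <= 8 and tie-free, otherwise the
# normal approximation with tie correction and no continuity correction),
# Kruskal-Wallis for three or more. A vector constant across all samples
# carries no information: p = 1 by convention.
group_test_pvalue <- function(v, labels) {
  if (max(v) == min(v)) return(1)
  if (nlevels(labels) == 2) {
    g1 <- v[labels == levels(labels)[1]]
    g2 <- v[labels == levels(labels)[2]]
    exact_ok <- length(g1) <= 8 && length(g2) <= 8 && !anyDuplicated(v)
    p <- suppressWarnings(stats::wilcox.test(
      g1, g2,
      exact = exact_ok, correct = FALSE
    ))$p.value
  } else {
    p <- suppressWarnings(stats::kruskal.test(v, labels))$p.value
  }
  if (!is.finite(p)) p <- 1
  min(max(p, 0), 1)
}

#' Rank-test edge weight for a combination feature
#'
#' Weight of the cooperative-regulation edge between two miRNAs: the
#' negative natural logarithm of the two-sided Mann-Whitney U p-value of
#' their difference vector between the two sample groups (Kruskal-Wallis
#' for three or more classes). The p-value is floored at `1e-16` so weights
#' stay finite; a difference vector constant across samples gets p = 1 and
#' weight 0.
#'
#' @param diff Numeric vector (a combination feature over samples).
#' @param labels Factor of class labels (>=2 classes, >=2 samples each).
#' @return Non-negative edge weight `-log(p)`.
#' @examples
#' edge_weight(c(1, 2, 3, 4, 5, 6), factor(rep(c("a", "b"), each = 3)))
#' @export
edge_weight <- function(diff, labels) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) rlang::abort(">=2 classes required")
  if (min(table(labels)) < 2) rlang::abort(">=2 samples per class required")
  if (length(diff) != length(labels)) rlang::abort("length mismatch between diff and labels")
  -log(max(group_test_pvalue(diff, labels), P_FLOOR))
}

#' Build the cooperative-regulation network
#'
#' Complete graph on the feature set whose edge weight between features
#' `f_i` and `f_j` is [edge_weight()] of the combination feature
#' `f_i - f_j`. Large weights mark pairs whose relative expression differs
#' strongly between sample groups.
#'
#' @param x An [expr_matrix()].
#' @return A complete `mirna_graph`.
#' @examples
#' d <- simulate_dataset(synth_spec(m = 10, n_per_class = 6, seed = 1))
#' g <- build_coop_network(d$expression)
#' tidy(g)
#' @export
build_coop_network <- function(x) {
  vals <- x$values
  m <- nrow(vals)
  if (m < 2) rlang::abort("need >=2 features to build a network")
  labels <- x$labels
  w <- matrix(0, m, m, dimnames = list(rownames(vals), rownames(vals)))
  for (i in seq_len(m - 1)) {
    vi <- vals[i, ]
    for (j in seq((i + 1), m)) {
      w[i, j] <- -log(max(group_test_pvalue(vi - vals[j, ], labels), P_FLOOR))
    }
  }
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  mirna_graph(rownames(vals), w, complete = TRUE)
}
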