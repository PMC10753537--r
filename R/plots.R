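# ggplot2 views of the main result types.

#' Plot a weighted miRNA graph
#'
#' Fruchterman-Reingold layout (deterministic via a fixed igraph RNG seed)
#' with edge alpha proportional to weight; optionally highlights module
#' membership.
#'
#' @param object A `mirna_graph`.
#' @param highlight Optional character vector of node ids to colour.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mirna_graph
#' @export
autoplot.mirna_graph <- function(object, highlight = NULL, ...) {
  ig <- as_igraph(object, weighted = FALSE)
  layout <- withr_seed_layout(ig)
  nodes <- tibble::tibble(
    name = object$nodes, x = layout[, 1], y = layout[, 2],
    highlighted = object$nodes %in% (highlight %||% character(0))
  )
  edges <- tidy.mirna_graph(object)
  edges <- dplyr::mutate(edges,
    x = nodes$x[match(.data$from, nodes$name)],
    y = nodes$y[match(.data$from, nodes$name)],
    xend = nodes$x[match(.data$to, nodes$name)],
    yend = nodes$y[match(.data$to, nodes$name)]
  )
  wrange <- range(edges$weight)
  edges$alpha <- if (wrange[1] == wrange[2]) 0.6 else 0.15 + 0.75 * minmax(edges$weight)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
        alpha = .data$alpha),
      colour = "grey40"
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$highlighted),
      size = 3
    ) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "steelblue", `TRUE` = "firebrick"), guide = "none"
    ) +
    ggplot2::scale_alpha_identity() +
    ggplot2::theme_void()
}

# deterministic layout without touching the caller's RNG
withr_seed_layout <- function(ig) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(42)
  igraph::layout_with_fr(ig)
}

#' Plot the degree distribution and power-law fit of a fused network
#'
#' Log-log degree-frequency scatter of the sparse network with the fitted
#' regression line, annotated with the selected k and its R-squared.
#'
#' @param object A `fused_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fused_network
#' @export
autoplot.fused_network <- function(object, ...) {
  deg <- rowSums(object$sparse$adj)
  tab <- table(deg[deg > 0])
  df <- tibble::tibble(
    degree = as.numeric(names(tab)),
    frequency = as.numeric(tab)
  )
  r2 <- object$fit_scores$r_squared[match(object$k, object$fit_scores$k)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$frequency)) +
    ggplot2::geom_point(size = 2, colour = "steelblue") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
      colour = "firebrick", linewidth = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "node degree", y = "frequency",
      title = sprintf("degree distribution, k = %d (R² = %.3f)", object$k, r2)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-fold AUCs of an evaluation report
#'
#' One boxplot of fold AUC per repeat, with the overall mean as a dashed
#' line.
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  f <- object$folds
  ggplot2::ggplot(f, ggplot2::aes(x = factor(.data$repeat_), y = .data$auc)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.4, outlier.size = 0.8) +
    ggplot2::geom_hline(yintercept = mean(f$auc), linetype = "dashed",
      colour = "firebrick") +
    ggplot2::labs(x = "repeat", y = "held-out AUC") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
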