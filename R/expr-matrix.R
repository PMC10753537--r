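#' Construct a validated miRNA expression matrix
#'
#' The central expression container: a features-by-samples numeric matrix
#' with an integer-coded class label per sample. Class labels keep the order
#' in which they first appear, so downstream integer codes are reproducible.
#' Feature rows are stored in lexicographic order of feature id.
#'
#' @param values Numeric matrix, rows = features (miRNA accessions), columns
#'   = samples. Must carry rownames and colnames.
#' @param labels Class label per sample, same length as `ncol(values)`.
#'   Coerced to a factor whose levels follow first appearance.
#' @return An `expr_matrix` object.
#' @examples
#' vals <- matrix(rnorm(12), 3, 4,
#'   dimnames = list(c("mirA", "mirB", "mirC"), paste0("s", 1:4)))
#' x <- expr_matrix(vals, c("ctrl", "ctrl", "case", "case"))
#' x
#' @export
expr_matrix <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values)) {
    rlang::abort("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    rlang::abort("`values` must have feature rownames and sample colnames")
  }
  if (length(labels) != ncol(values)) {
    rlang::abort(sprintf(
      "label length (%d) does not match sample count (%d)",
      length(labels), ncol(values)
    ))
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    rlang::abort(sprintf(
      "missing value at feature '%s', sample '%s'",
      rownames(values)[bad[1]], colnames(values)[bad[2]]
    ))
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1]
    rlang::abort(sprintf("duplicate feature id '%s' after preprocessing", dup))
  }
  if (anyNA(labels)) rlang::abort("every sample must have a label")
  labels <- if (is.factor(labels)) {
    droplevels(labels)
  } else {
    # code classes by first appearance order
    factor(as.character(labels), levels = unique(as.character(labels)))
  }
  if (nlevels(labels) < 2) rlang::abort(">=2 classes required")
  cnt <- table(labels)
  if (any(cnt < 2)) {
    rlang::abort(sprintf(
      ">=2 samples per class required (class '%s' has %d)",
      names(cnt)[which(cnt < 2)[1]], min(cnt)
    ))
  }
  values <- values[order(rownames(values)), , drop = FALSE]
  structure(
    list(values = values, labels = labels),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d features x %d samples, %d classes (%s)\n",
    nrow(x$values), ncol(x$values), nlevels(x$labels),
    paste(sprintf("%s: %d", levels(x$labels), table(x$labels)), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Feature ids of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of feature ids in stored (lexicographic) order.
#' @export
features <- function(x) rownames(x$values)

#' Subset an expression matrix by samples and/or features
#'
#' Subsetting by samples revalidates the class-size invariants.
#'
#' @param x An `expr_matrix`.
#' @param samples Sample names or indices to keep (default all).
#' @param keep_features Feature ids to keep (default all).
#' @return A new `expr_matrix`.
#' @export
subset_samples <- function(x, samples = NULL, keep_features = NULL) {
  vals <- x$values
  labs <- x$labels
  if (!is.null(samples)) {
    vals <- vals[, samples, drop = FALSE]
    labs <- labs[if (is.character(samples)) match(samples, colnames(x$values)) else samples]
  }
  if (!is.null(keep_features)) vals <- vals[keep_features, , drop = FALSE]
  expr_matrix(vals, labs)
}

#' Tidy an expression matrix into long format
#'
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `feature`, `sample`, `label`, `value`.
#' @method tidy expr_matrix
#' @export
tidy.expr_matrix <- function(x, ...) {
  tibble::tibble(
    feature = rep(rownames(x$values), times = ncol(x$values)),
    sample = rep(colnames(x$values), each = nrow(x$values)),
    label = rep(as.character(x$labels), each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

#' @method glance expr_matrix
#' @export
glance.expr_matrix <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$values),
    n_samples = ncol(x$values),
    n_classes = nlevels(x$labels)
  )
}
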