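# Reading and writing the plain-text table formats the pipeline consumes:
# expression matrices, sample labels, miRNA-disease relation tables,
# disease-term embedding tables and alias maps. All are delimited text with
# the delimiter auto-detected between tab and comma (GEO exports vary);
# every reader takes a `delim` override.

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (lengths(regmatches(first, gregexpr("\t", first))) >=
      lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
}

read_delim_table <- function(path, delim = NULL, header = TRUE) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  delim <- delim %||% detect_delim(path)
  utils::read.table(path,
    sep = delim, header = header, check.names = FALSE,
    stringsAsFactors = FALSE, quote = "\"", comment.char = ""
  )
}

#' Read an expression matrix and its sample labels
#'
#' Expects delimited text with the feature id in the first column and one
#' column per sample; the label file maps sample id to class (two columns,
#' with header). Rows whose feature id repeats (multiple probes for the same
#' miRNA) are averaged per feature. Class codes follow first appearance
#' order in the label file.
#'
#' @param path Expression table path.
#' @param label_path Label table path (columns: sample id, class).
#' @param delim Field delimiter; `NULL` auto-detects tab vs comma.
#' @return A validated [expr_matrix()].
#' @examples
#' d <- simulate_dataset(synth_spec(m = 8, n_per_class = 3, seed = 1))
#' dir <- tempfile(); write_dataset(d, dir)
#' x <- read_expression(file.path(dir, "expression.tsv"),
#'                      file.path(dir, "labels.tsv"))
#' @export
read_expression <- function(path, label_path, delim = NULL) {
  tab <- read_delim_table(path, delim)
  if (ncol(tab) < 2) rlang::abort("expression table needs a feature column and >=1 sample column")
  ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(mat), nrow(mat)))) &
      !is.na(mat), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      rlang::abort(sprintf(
        "non-numeric value '%s' at row %d (feature '%s'), column '%s'",
        mat[bad[1, 1], bad[1, 2]], bad[1, 1], ids[bad[1, 1]], colnames(mat)[bad[1, 2]]
      ))
    }
    mat <- matrix(as.numeric(mat), nrow(mat), dimnames = dimnames(mat))
  }
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    rlang::abort(sprintf(
      "missing value at row %d (feature '%s'), column '%s'",
      bad[1], ids[bad[1]], colnames(mat)[bad[2]]
    ))
  }
  # collapse duplicate probes by per-feature mean
  if (anyDuplicated(ids)) {
    mat <- rowsum(mat, group = ids) / as.vector(table(ids)[sort(unique(ids))])
  } else {
    rownames(mat) <- ids
  }

  labs <- read_delim_table(label_path, delim)
  if (ncol(labs) < 2) rlang::abort("label table needs columns: sample id, class")
  lab_map <- stats::setNames(as.character(labs[[2]]), as.character(labs[[1]]))
  missing <- setdiff(colnames(mat), names(lab_map))
  if (length(missing) > 0) {
    rlang::abort(sprintf("unlabeled sample(s): %s", paste(missing, collapse = ", ")))
  }
  # keep label coding order = first appearance in the label file
  lab_order <- unique(as.character(labs[[2]]))
  labels <- droplevels(factor(lab_map[colnames(mat)], levels = lab_order))
  expr_matrix(mat, labels)
}

#' Write an expression matrix and labels in the format [read_expression()] reads
#' @param x An `expr_matrix`.
#' @param path,label_path Output paths.
#' @param delim Field delimiter (default tab).
#' @return Invisibly, `x`.
#' @export
write_expression <- function(x, path, label_path, delim = "\t") {
  df <- data.frame(feature = rownames(x$values), x$values, check.names = FALSE)
  utils::write.table(df, path,
    sep = delim, quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    data.frame(sample = colnames(x$values), label = as.character(x$labels)),
    label_path,
    sep = delim, quote = FALSE, row.names = FALSE
  )
  invisible(x)
}

#' Read a miRNA-disease relation table
#'
#' Two-column delimited text (miRNA id, disease term). Disease terms are
#' canonicalized (trimmed, case-folded) and exact duplicate pairs dropped.
#' An optional alias map (two columns: alias, accession) translates miRNA
#' names to standard accessions before deduplication; aliases without a
#' mapping are kept as-is with a warning.
#'
#' @param path Relation table path.
#' @param alias_map Optional alias table path, or a named character vector
#'   (alias -> accession).
#' @param delim Field delimiter; `NULL` auto-detects.
#' @return A `disease_relations` object: a named list mapping each miRNA
#'   accession to its set of canonical disease terms.
#' @export
read_relations <- function(path, alias_map = NULL, delim = NULL) {
  tab <- read_delim_table(path, delim, header = TRUE)
  if (nrow(tab) == 0) return(disease_relations(list()))
  if (ncol(tab) < 2) rlang::abort("relation table needs columns: miRNA, disease")
  mirna <- as.character(tab[[1]])
  disease <- canonical_term(as.character(tab[[2]]))
  if (!is.null(alias_map)) {
    map <- if (is.character(alias_map) && !is.null(names(alias_map))) {
      alias_map
    } else {
      at <- read_delim_table(alias_map, delim, header = TRUE)
      stats::setNames(as.character(at[[2]]), as.character(at[[1]]))
    }
    hit <- mirna %in% names(map)
    if (any(!hit)) {
      unknown <- unique(mirna[!hit])
      rlang::warn(sprintf(
        "%d miRNA id(s) missing from alias map kept as-is (e.g. %s)",
        length(unknown), paste(utils::head(unknown, 3), collapse = ", ")
      ))
    }
    mirna[hit] <- map[mirna[hit]]
  }
  keep <- !duplicated(paste(mirna, disease, sep = "\r"))
  mirna <- mirna[keep]
  disease <- disease[keep]
  disease_relations(split(disease, mirna))
}

#' Construct a disease-relation map from a named list
#' @param x Named list: miRNA accession -> character vector of disease terms.
#' @return A `disease_relations` object with deduplicated, canonicalized sets.
#' @export
disease_relations <- function(x) {
  if (length(x) == 0) {
    return(structure(stats::setNames(list(), character(0)), class = "disease_relations"))
  }
  x <- lapply(x, function(d) sort(unique(canonical_term(d))))
  structure(x[order(names(x))], class = "disease_relations")
}

#' @export
print.disease_relations <- function(x, ...) {
  cat(sprintf(
    "<disease_relations> %d miRNAs, %d distinct diseases\n",
    length(x), length(unique(unlist(x)))
  ))
  invisible(x)
}

#' @method tidy disease_relations
#' @export
tidy.disease_relations <- function(x, ...) {
  tibble::tibble(
    mirna = rep(names(x), lengths(x)),
    disease = unlist(x, use.names = FALSE)
  )
}

#' Write a relation map in the format [read_relations()] reads
#' @param x A `disease_relations` object.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return Invisibly, `x`.
#' @export
write_relations <- function(x, path, delim = "\t") {
  df <- as.data.frame(tidy.disease_relations(x))
  names(df) <- c("mirna", "disease")
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Read a disease-term embedding table
#'
#' Delimited text: first column the term, remaining columns the vector
#' components. All rows must have the same dimensionality; a term repeated
#' with an identical vector collapses to one entry, while conflicting
#' repeats are an error.
#'
#' @param path Embedding table path.
#' @param delim Field delimiter; `NULL` auto-detects.
#' @return An `embedding_table`: numeric matrix with term rownames.
#' @export
read_embeddings <- function(path, delim = NULL) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  delim <- delim %||% detect_delim(path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, delim, fixed = TRUE)
  lens <- lengths(parts)
  if (length(unique(lens)) > 1) {
    bad <- which(lens != lens[1])[1]
    rlang::abort(sprintf(
      "ragged embedding row for term '%s' (%d columns, expected %d)",
      parts[[bad]][1], lens[bad], lens[1]
    ))
  }
  terms <- canonical_term(vapply(parts, `[[`, character(1), 1))
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(lens[1] - 1)))
  if (anyNA(vecs)) {
    bad <- which(rowSums(is.na(vecs)) > 0)[1]
    rlang::abort(sprintf("non-numeric embedding component for term '%s'", terms[bad]))
  }
  if (anyDuplicated(terms)) {
    for (tm in unique(terms[duplicated(terms)])) {
      rows <- vecs[terms == tm, , drop = FALSE]
      if (max(abs(sweep(rows, 2, rows[1, ]))) > 0) {
        rlang::abort(sprintf("term '%s' repeated with conflicting vectors", tm))
      }
    }
    keep <- !duplicated(terms)
    vecs <- vecs[keep, , drop = FALSE]
    terms <- terms[keep]
  }
  rownames(vecs) <- terms
  embedding_table(vecs)
}

#' Construct an embedding table from a matrix
#' @param m Numeric matrix with term rownames.
#' @return An `embedding_table` object.
#' @export
embedding_table <- function(m) {
  if (is.null(rownames(m))) rlang::abort("embedding matrix needs term rownames")
  rownames(m) <- canonical_term(rownames(m))
  structure(m[order(rownames(m)), , drop = FALSE], class = c("embedding_table", "matrix"))
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d terms, dimension %d\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Write an embedding table in the format [read_embeddings()] reads
#' @param x An `embedding_table`.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return Invisibly, `x`.
#' @export
write_embeddings <- function(x, path, delim = "\t") {
  lines <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], format(x[i, ], digits = 15, trim = TRUE, scientific = FALSE)),
      collapse = delim
    )
  }, character(1))
  writeLines(lines, path)
  invisible(x)
}
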