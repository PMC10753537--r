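# Per-module linear SVM classifiers combined by weighted voting, and the
# repeated stratified cross-validation protocol used to evaluate the whole
# pipeline.

#' ROC AUC from scores
#'
#' Binary: the probability that a random positive outscores a random
#' negative, ties counted one half (rank-based, equivalent to concordant
#' pair counting). Multi-class: scores must be a matrix with one column per
#' class level; the unweighted mean of per-class one-vs-rest AUCs is
#' returned (macro averaging).
#'
#' @param scores Numeric vector (binary; higher = more positive) or a
#'   matrix with one column per class.
#' @param labels Logical/two-level factor (binary) or factor with
#'   `ncol(scores)` levels.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.85, 0.7), c(TRUE, TRUE, FALSE, FALSE))
#' @export
roc_auc <- function(scores, labels) {
  if (is.matrix(scores)) {
    y <- as.factor(labels)
    lev <- levels(y)
    if (ncol(scores) != length(lev)) {
      rlang::abort("score matrix must have one column per class level")
    }
    aucs <- vapply(seq_along(lev), function(ci) {
      roc_auc(scores[, ci], y == lev[ci])
    }, numeric(1))
    return(mean(aucs))
  }
  pos <- if (is.logical(labels)) labels else as.factor(labels) == levels(as.factor(labels))[2]
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) rlang::abort("need at least one positive and one negative")
  r <- rank(scores) # average ranks give ties a weight of 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Youden-optimal threshold of binary scores on training data: maximizes
# sensitivity + specificity - 1 over observed score cut-offs.
youden_threshold <- function(scores, pos) {
  cuts <- sort(unique(scores))
  if (length(cuts) > 1) {
    cuts <- (cuts[-1] + cuts[-length(cuts)]) / 2
  }
  j <- vapply(cuts, function(th) {
    sens <- mean(scores[pos] > th)
    spec <- mean(scores[!pos] <= th)
    sens + spec - 1
  }, numeric(1))
  cuts[which.max(j)]
}

mcc_from_confusion <- function(tab) {
  # multi-class Matthews correlation coefficient from a confusion matrix
  tab <- as.matrix(tab)
  n <- sum(tab)
  trace <- sum(diag(tab))
  rs <- rowSums(tab)
  cs <- colSums(tab)
  num <- trace * n - sum(rs * cs)
  den <- sqrt(n^2 - sum(rs^2)) * sqrt(n^2 - sum(cs^2))
  if (den == 0) return(0)
  num / den
}

#' Fit the weighted-voting module ensemble
#'
#' Unit-variance scaling parameters are learned on the training samples;
#' one linear-kernel SVM is fitted per module on the scaled training data.
#' Voting weights are the modules' mean AUCs in a stratified inner 5-fold
#' cross-validation on the training samples, normalized to sum to 1
#' (`weight_scheme = "sum"`, the default) or min-max normalized then
#' rescaled to sum to 1 (`"minmax"`).
#'
#' @param x_train An [expr_matrix()] of training samples.
#' @param modules A `mirna_modules` object or list of `mirna_module`s.
#' @param cost SVM regularization constant.
#' @param weight_scheme "sum" or "minmax".
#' @return A `module_ensemble` object.
#' @export
fit_ensemble <- function(x_train, modules, cost = 1,
                         weight_scheme = c("sum", "minmax")) {
  weight_scheme <- match.arg(weight_scheme)
  mods <- if (inherits(modules, "mirna_modules")) modules$modules else modules
  if (length(mods) == 0) rlang::abort("no modules to fit")
  miss <- setdiff(unique(unlist(lapply(mods, `[[`, "members"))), features(x_train))
  if (length(miss) > 0) {
    rlang::abort(sprintf(
      "module feature(s) absent from training data: %s",
      paste(utils::head(miss, 5), collapse = ", ")
    ))
  }
  y <- x_train$labels
  classifiers <- lapply(mods, function(m) {
    mat <- t(x_train$values[m$members, , drop = FALSE])
    params <- uv_scale_params(mat)
    sc <- uv_apply(mat, params)
    scorer <- fit_svm_scorer(sc, y, cost)
    train_scores <- scorer(sc)
    # per-class min-max ranges of training decision scores, for mapping
    # decision values to [0, 1] vote scores
    rng <- apply(train_scores, 2, range)
    list(
      members = m$members, params = params, scorer = scorer,
      score_range = rng,
      inner_auc = module_auc(x_train, m$members, mode = "cv5", cost = cost)
    )
  })
  aucs <- vapply(classifiers, `[[`, numeric(1), "inner_auc")
  weights <- if (weight_scheme == "sum") {
    if (sum(aucs) == 0) rep(1 / length(aucs), length(aucs)) else aucs / sum(aucs)
  } else {
    mm <- minmax(aucs)
    if (sum(mm) == 0) rep(1 / length(mm), length(mm)) else mm / sum(mm)
  }
  structure(
    list(
      classifiers = classifiers, weights = weights,
      class_levels = levels(y), cost = cost, weight_scheme = weight_scheme
    ),
    class = "module_ensemble"
  )
}

#' @export
print.module_ensemble <- function(x, ...) {
  cat(sprintf(
    "<module_ensemble> %d module classifiers over classes {%s}\n",
    length(x$classifiers), paste(x$class_levels, collapse = ", ")
  ))
  for (i in seq_along(x$classifiers)) {
    cl <- x$classifiers[[i]]
    cat(sprintf(
      "  %d. %d features, inner-CV AUC %.3f, weight %.3f\n",
      i, length(cl$members), cl$inner_auc, x$weights[i]
    ))
  }
  invisible(x)
}

#' Tidy ensemble voting weights
#' @param x A `module_ensemble`.
#' @param ... Unused.
#' @return Tibble with columns `module`, `n_features`, `inner_auc`,
#'   `weight`.
#' @method tidy module_ensemble
#' @export
tidy.module_ensemble <- function(x, ...) {
  tibble::tibble(
    module = seq_along(x$classifiers),
    n_features = vapply(x$classifiers, function(cl) length(cl$members), integer(1)),
    inner_auc = vapply(x$classifiers, `[[`, numeric(1), "inner_auc"),
    weight = x$weights
  )
}

#' @method glance module_ensemble
#' @export
glance.module_ensemble <- function(x, ...) {
  tibble::tibble(
    n_modules = length(x$classifiers),
    n_classes = length(x$class_levels),
    mean_inner_auc = mean(vapply(x$classifiers, `[[`, numeric(1), "inner_auc"))
  )
}

#' Predict class scores with a module ensemble
#'
#' Each module classifier produces per-class decision scores, mapped
#' monotonically to `[0, 1]` by the min-max range of its training decision
#' scores (clipped at the ends); the ensemble score is the voting-weighted
#' sum and the predicted label the argmax.
#'
#' @param object A `module_ensemble`.
#' @param newdata An [expr_matrix()] or a features-by-samples numeric
#'   matrix containing every module feature.
#' @param ... Unused.
#' @return Tibble with `sample`, one `score_<class>` column per class and
#'   `.pred`.
#' @export
predict.module_ensemble <- function(object, newdata, ...) {
  vals <- if (inherits(newdata, "expr_matrix")) newdata$values else newdata
  miss <- setdiff(
    unique(unlist(lapply(object$classifiers, `[[`, "members"))),
    rownames(vals)
  )
  if (length(miss) > 0) {
    rlang::abort(sprintf(
      "feature(s) missing from new data: %s", paste(utils::head(miss, 5), collapse = ", ")
    ))
  }
  n <- ncol(vals)
  lev <- object$class_levels
  total <- matrix(0, n, length(lev))
  for (i in seq_along(object$classifiers)) {
    cl <- object$classifiers[[i]]
    mat <- uv_apply(t(vals[cl$members, , drop = FALSE]), cl$params)
    raw <- cl$scorer(mat)
    mapped <- vapply(seq_along(lev), function(ci) {
      rng <- cl$score_range[, ci]
      if (rng[1] == rng[2]) {
        rep(0.5, n)
      } else {
        pmin(pmax((raw[, ci] - rng[1]) / (rng[2] - rng[1]), 0), 1)
      }
    }, numeric(n))
    if (n == 1) mapped <- matrix(mapped, nrow = 1)
    total <- total + object$weights[i] * mapped
  }
  colnames(total) <- paste0("score_", lev)
  out <- tibble::as_tibble(total)
  out$sample <- colnames(vals) %||% as.character(seq_len(n))
  out$.pred <- lev[max.col(total, ties.method = "first")]
  dplyr::select(out, "sample", dplyr::everything())
}

# Ensemble score matrix (n x classes) without the tibble wrapper.
ensemble_score_matrix <- function(object, vals) {
  p <- predict.module_ensemble(object, vals)
  as.matrix(p[, paste0("score_", object$class_levels)])
}
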