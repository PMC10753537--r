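# Leak-free evaluation protocol: within each cross-validation fold the
# cooperative-regulation network, importance scores, Q-learning search and
# classifier fitting all see training samples only. The functional-
# similarity view may be built from the global relation table because it
# uses no sample labels or expression values.

#' Fit the full module-discovery pipeline on training data
#'
#' Builds both network views from the training expression matrix and the
#' (label-free) relation table, fuses and sparsifies them, identifies
#' modules by Q-learning and fits the weighted-voting ensemble. The result
#' depends only on the inputs and `cfg` (including `cfg$seed`), which is
#' what makes per-fold evaluation leak-free and reproducible.
#'
#' @param x_train Training [expr_matrix()].
#' @param relations A `disease_relations` map (may be empty).
#' @param provider An `embedding_provider`.
#' @param cfg An [rl_config()].
#' @param k_candidates Candidate neighbour counts for [select_k()].
#' @param weight_scheme Voting-weight normalization, see [fit_ensemble()].
#' @return List with `network` (a `fused_network`), `modules`
#'   (`mirna_modules`) and `ensemble` (`module_ensemble`).
#' @export
fit_pipeline <- function(x_train, relations, provider, cfg = rl_config(),
                         k_candidates = c(3, 5, 7, 9),
                         weight_scheme = c("sum", "minmax")) {
  weight_scheme <- match.arg(weight_scheme)
  g_cr <- build_coop_network(x_train)
  g_fs <- build_functional_network(features(x_train), relations, provider)
  fn <- build_fused_network(g_cr, g_fs, k_candidates)
  mods <- identify_modules(x_train, fn, cfg, keep_qtables = FALSE)
  ens <- fit_ensemble(x_train, mods, cost = cfg$svm_cost, weight_scheme = weight_scheme)
  list(network = fn, modules = mods, ensemble = ens)
}

fold_metrics <- function(ens, x_train, x_test) {
  lev <- ens$class_levels
  sc_test <- ensemble_score_matrix(ens, x_test$values)
  y_test <- factor(as.character(x_test$labels), levels = lev)
  if (length(lev) == 2) {
    pos_te <- y_test == lev[2]
    auc <- roc_auc(sc_test[, 2], pos_te)
    # operating threshold chosen on the training scores (Youden index)
    sc_tr <- ensemble_score_matrix(ens, x_train$values)
    th <- youden_threshold(sc_tr[, 2], x_train$labels == lev[2])
    pred <- ifelse(sc_test[, 2] > th, lev[2], lev[1])
    sens <- if (any(pos_te)) mean(sc_test[pos_te, 2] > th) else NA_real_
    spec <- if (any(!pos_te)) mean(sc_test[!pos_te, 2] <= th) else NA_real_
    tab <- table(factor(y_test, lev), factor(pred, lev))
    mcc <- mcc_from_confusion(tab)
  } else {
    auc <- roc_auc(sc_test, y_test)
    pred <- lev[max.col(sc_test, ties.method = "first")]
    tab <- table(factor(y_test, lev), factor(pred, lev))
    # macro one-vs-rest sensitivity/specificity at the argmax decision
    sens_c <- spec_c <- numeric(length(lev))
    for (ci in seq_along(lev)) {
      tp <- tab[ci, ci]
      fn_ <- sum(tab[ci, ]) - tp
      fp <- sum(tab[, ci]) - tp
      tn <- sum(tab) - tp - fn_ - fp
      sens_c[ci] <- if (tp + fn_ > 0) tp / (tp + fn_) else NA
      spec_c[ci] <- if (tn + fp > 0) tn / (tn + fp) else NA
    }
    sens <- mean(sens_c, na.rm = TRUE)
    spec <- mean(spec_c, na.rm = TRUE)
    mcc <- mcc_from_confusion(tab)
  }
  tibble::tibble(auc = auc, sensitivity = sens, specificity = spec, mcc = mcc)
}

#' Repeated stratified cross-validation of the full pipeline
#'
#' Splits the samples into stratified folds, fits the entire pipeline
#' (networks, modules, ensemble) on the training folds and scores the
#' held-out fold; repeats with fresh fold assignments. Reports AUC (macro
#' one-vs-rest for 3+ classes), sensitivity and specificity at the
#' training-Youden threshold (argmax decision for 3+ classes) and the
#' Matthews correlation coefficient per fold, plus aggregate mean and SD.
#'
#' @param x An [expr_matrix()].
#' @param relations A `disease_relations` map.
#' @param provider An `embedding_provider`.
#' @param cfg An [rl_config()]; `cfg$seed` drives fold assignment and the
#'   per-fold searches.
#' @param repeats Number of repetitions (reference protocol: 10).
#' @param folds Folds per repetition (reference protocol: 10); reduced with
#'   a warning if some class has fewer members.
#' @param k_candidates,weight_scheme Passed to [fit_pipeline()].
#' @param keep_fits Keep each fold's fitted modules and ensemble weights
#'   (for audits; default `FALSE`).
#' @return An `eval_report` with per-fold metrics and aggregates.
#' @export
cross_validate <- function(x, relations, provider, cfg = rl_config(),
                           repeats = 10, folds = 10,
                           k_candidates = c(3, 5, 7, 9),
                           weight_scheme = c("sum", "minmax"),
                           keep_fits = FALSE) {
  weight_scheme <- match.arg(weight_scheme)
  min_class <- min(table(x$labels))
  if (folds > min_class) {
    rlang::warn(sprintf(
      "reducing folds from %d to %d (smallest class size)", folds, min_class
    ))
    folds <- min_class
  }
  if (folds < 2) rlang::abort("too few samples per class for stratified folds")
  rows <- list()
  fits <- list()
  for (r in seq_len(repeats)) {
    set.seed(derive_seed(cfg$seed, 9000L, r))
    assign_f <- stratified_folds_random(x$labels, folds)
    for (f in seq_len(folds)) {
      x_tr <- subset_samples(x, samples = which(assign_f != f))
      x_te <- subset_samples_unchecked(x, which(assign_f == f))
      cfg_f <- cfg
      cfg_f$seed <- derive_seed(cfg$seed, r, f)
      fit <- fit_pipeline(x_tr, relations, provider, cfg_f,
        k_candidates = k_candidates, weight_scheme = weight_scheme
      )
      met <- fold_metrics(fit$ensemble, x_tr, x_te)
      rows[[length(rows) + 1]] <- dplyr::mutate(met,
        repeat_ = r, fold = f, n_test = ncol(x_te$values), .before = 1
      )
      if (keep_fits) {
        fits[[sprintf("r%d_f%d", r, f)]] <- list(
          modules = lapply(fit$modules$modules, `[[`, "members"),
          weights = fit$ensemble$weights,
          k = fit$network$k
        )
      }
    }
  }
  folds_tbl <- dplyr::bind_rows(rows)
  structure(
    list(
      folds = folds_tbl,
      repeats = repeats, n_folds = folds,
      fits = if (keep_fits) fits else NULL
    ),
    class = "eval_report"
  )
}

# Test-fold container: single-class folds are legitimate here, so skip the
# class-balance validation that expr_matrix enforces.
subset_samples_unchecked <- function(x, idx) {
  structure(
    list(
      values = x$values[, idx, drop = FALSE],
      labels = x$labels[idx]
    ),
    class = "expr_matrix"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  g <- glance.eval_report(x)
  cat(sprintf(
    "<eval_report> %d repeats x %d folds\n  AUC %.3f +/- %.3f; sens %.3f; spec %.3f; MCC %.3f\n",
    x$repeats, x$n_folds, g$mean_auc, g$sd_auc, g$mean_sensitivity,
    g$mean_specificity, g$mean_mcc
  ))
  invisible(x)
}

#' Per-fold metrics of an evaluation report
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Tibble with one row per (repeat, fold).
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$folds

#' Aggregate metrics of an evaluation report
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return One-row tibble of means and SDs across folds.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  f <- x$folds
  tibble::tibble(
    n_folds_total = nrow(f),
    mean_auc = mean(f$auc), sd_auc = stats::sd(f$auc),
    mean_sensitivity = mean(f$sensitivity, na.rm = TRUE),
    mean_specificity = mean(f$specificity, na.rm = TRUE),
    mean_mcc = mean(f$mcc)
  )
}
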