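# Internal helpers shared across the pipeline.

# Min-max rescale a numeric vector to [0, 1]; constant input maps to all 0.
minmax <- function(x, warn_constant = FALSE, what = "values") {
  rng <- range(x)
  if (rng[1] == rng[2]) {
    if (warn_constant) {
      rlang::warn(sprintf("all %s are equal; min-max normalization maps them to 0", what))
    }
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

# Canonical disease-term form: trimmed, case-folded, inner whitespace collapsed.
canonical_term <- function(x) {
  x <- tolower(trimws(x))
  gsub("\\s+", " ", x)
}

# Deterministic stratified fold assignment (no RNG): samples of each class,
# in their stored order, are dealt round-robin over folds. Used where fold
# membership must not consume random numbers (memoized inner CV).
stratified_folds_fixed <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# Randomized stratified fold assignment drawing from the current RNG stream.
stratified_folds_random <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

# Small deterministic sub-seed derivation, kept below 2^31.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + as.numeric(p) + 1) %% 2147483629
  as.integer(s)
}

`%||%` <- rlang::`%||%`
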