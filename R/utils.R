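# Internal helpers: seeding, fold assignment, simplex utilities.

# Deterministic sub-seed derivation. A single user seed is expanded into
# component seeds (per fold, per pair, per subsample) by hashing a tag path,
# so no two components share a stream and every run is reproducible from the
# top-level seed alone. Kept below 2^31 - 1.
derive_seed <- function(seed, ...) {
  tags <- unlist(lapply(list(...), as.character))
  h <- as.double(seed) %% 2147483647
  for (tag in tags) {
    for (code in utf8ToInt(tag)) {
      h <- (h * 31 + code) %% 2147483647
    }
  }
  as.integer(h)
}

# Round half away from zero; base round() rounds half to even, which would
# make window lengths depend on parity of t * fs.
round_half_up <- function(x) {
  trunc(x + sign(x) * 0.5)
}

# Stratified fold assignment: within each class, indices are shuffled with a
# seeded RNG and dealt round-robin, so every fold holds every class whenever
# class counts allow. Returns an integer vector of fold ids (1..k).
stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  stopifnot(k >= 2, n >= k)
  counts <- table(labels)
  if (any(counts < k)) {
    stop("stratification error: class '", names(counts)[which.min(counts)],
         "' has fewer samples (", min(counts), ") than folds (", k, ")")
  }
  folds <- integer(n)
  with_seed(derive_seed(seed, "strat", k), {
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Evaluate an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Order arbitrary class labels canonically: known classes first in
# (R, I, L) order, then any pseudo-classes (superclass labels) alphabetically.
canonical_classes <- function(labels) {
  u <- unique(as.character(labels))
  c(intersect(CLASS_ORDER, u), sort(setdiff(u, CLASS_ORDER)))
}

# First-maximum argmax over a named probability vector whose names are in
# canonical order: equal probabilities resolve to the earlier class.
argmax_label <- function(p) {
  names(p)[which.max(p)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
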