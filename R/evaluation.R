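# Evaluation: confusion-matrix bookkeeping, Cohen's kappa, the trial-level
# 10-chunk cross-validation protocol and its result table.

#' Build a confusion matrix
#'
#' Rows are the correct class, columns the predicted class, in canonical
#' (R, I, L) order.
#'
#' @param truth Character vector of true labels.
#' @param predicted Character vector of predicted labels.
#' @param classes Class order (default `c("R", "I", "L")`).
#' @return Integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, predicted, classes = CLASS_ORDER) {
  stopifnot(length(truth) == length(predicted))
  cm <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  cm <- matrix(as.integer(cm), length(classes), length(classes),
               dimnames = list(correct = classes, predicted = classes))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

as_confusion_matrix <- function(m, classes = CLASS_ORDER) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m), all(m >= 0))
  dimnames(m) <- list(correct = classes[seq_len(nrow(m))],
                      predicted = classes[seq_len(nrow(m))])
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement
#' `k = (N * sum(h_ii) - sum(Tr_i * Tc_i)) / (N^2 - sum(Tr_i * Tc_i))`
#' with `h` the count matrix, `N` its total and `Tr`, `Tc` the row and column
#' marginals. Ranges from -1 (total disagreement) through 0 (chance level)
#' to 1 (perfect agreement); preferred over the accuracy rate when class
#' counts are unbalanced, as they are here (idle epochs outnumber each
#' movement class two to one).
#'
#' @param cm A `confusion_matrix` (or any square count matrix).
#' @return Kappa, a number in `[-1, 1]`.
#' @export
cohen_kappa <- function(cm) {
  h <- unclass(as.matrix(cm))
  n <- sum(h)
  if (n <= 0) stop("empty confusion matrix")
  tr <- rowSums(h)
  tc <- colSums(h)
  denom <- n^2 - sum(tr * tc)
  if (denom == 0) {
    stop("kappa undefined: all mass in a single row/column combination")
  }
  (n * sum(diag(h)) - sum(tr * tc)) / denom
}

#' Per-class accuracy from a confusion matrix
#'
#' @param cm A `confusion_matrix`.
#' @return Named numeric vector `diag(h) / rowSums(h)`.
#' @export
per_class_accuracy <- function(cm) {
  h <- unclass(as.matrix(cm))
  diag(h) / rowSums(h)
}

#' Overall accuracy from a confusion matrix
#'
#' @param cm A `confusion_matrix`.
#' @return `sum(diag(h)) / sum(h)`.
#' @export
accuracy <- function(cm) {
  h <- unclass(as.matrix(cm))
  sum(diag(h)) / sum(h)
}

#' Split trials into equal disjoint chunks for cross-validation
#'
#' Chunking operates at the trial level, so the idle and movement epochs of
#' one trial always share a chunk, and chunks are contiguous in trial order
#' by default (conservative under slow drifts; set `shuffle = TRUE` for a
#' seeded random assignment). Each fold trains on all chunks but one and
#' tests on the held-out chunk.
#'
#' @param es An `epoch_set` with `trial_index` set.
#' @param n_chunks Number of chunks (default 10).
#' @param seed Seed used when `shuffle = TRUE`.
#' @param shuffle Randomize trial-to-chunk assignment.
#' @return An object of class `fold_plan`: `n_chunks`, `trial_ids`,
#'   `chunk_of_trial` and a list `folds` of `(train_trials, test_trials)`.
#' @export
make_folds <- function(es, n_chunks = 10L, seed = 1L, shuffle = FALSE) {
  trial_ids <- unique(es$trial_index)
  n <- length(trial_ids)
  if (n < n_chunks) {
    stop("need at least ", n_chunks, " trials; got ", n)
  }
  if (shuffle) {
    trial_ids <- with_seed(derive_seed(seed, "chunks"),
                           trial_ids[sample.int(n)])
  }
  sizes <- rep(n %/% n_chunks, n_chunks)
  rem <- n %% n_chunks
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  chunk <- rep(seq_len(n_chunks), times = sizes)
  chunk_of_trial <- stats::setNames(chunk, trial_ids)
  folds <- lapply(seq_len(n_chunks), function(f) {
    list(train_trials = trial_ids[chunk != f],
         test_trials = trial_ids[chunk == f])
  })
  structure(list(n_chunks = n_chunks, trial_ids = trial_ids,
                 chunk_of_trial = chunk_of_trial, folds = folds),
            class = "fold_plan")
}

# Validate a fold plan against an epoch set and abort on any leakage: chunks
# must be disjoint, cover every trial, differ in size by at most one, and no
# test trial may appear in its fold's training side.
check_fold_plan <- function(plan, es) {
  trial_ids <- unique(es$trial_index)
  all_test <- unlist(lapply(plan$folds, `[[`, "test_trials"))
  if (anyDuplicated(all_test)) {
    stop("leakage guard: overlapping test chunks in fold plan")
  }
  if (!setequal(all_test, trial_ids)) {
    stop("leakage guard: test chunks do not cover all trials exactly")
  }
  sizes <- vapply(plan$folds, function(f) length(f$test_trials), integer(1))
  if (max(sizes) - min(sizes) > 1L) {
    stop("fold plan chunks are not equal size (max diff 1)")
  }
  for (f in plan$folds) {
    if (length(intersect(f$train_trials, f$test_trials)) > 0L) {
      stop("leakage guard: test trial present in training chunks")
    }
    if (!setequal(union(f$train_trials, f$test_trials), trial_ids)) {
      stop("fold plan: train + test do not partition the trials")
    }
  }
  invisible(TRUE)
}

#' Run the full cross-validation protocol
#'
#' For each fold of the plan, fits the requested ternary model on the
#' training trials' epochs (balancing by subsampling happens inside the fit,
#' with a fold-derived seed) and predicts every epoch of the untouched test
#' chunk — test data are never subsampled, so the natural ~2:1:1
#' idle:left:right imbalance is preserved, which is why kappa rather than
#' raw accuracy is the headline score. A leakage guard aborts if any test
#' trial appears on the training side.
#'
#' @param es An `epoch_set` (one idle + one movement epoch per trial).
#' @param method,algorithm,odcs_m_best,ddag_order,grid,fs_target Passed to
#'   [fit_ternary()].
#' @param n_chunks Number of outer chunks (default 10).
#' @param seed Integer seed expanded per fold.
#' @param plan Optional pre-built [make_folds()] plan.
#' @param shuffle Shuffle trial-to-chunk assignment.
#' @return An object of class `result_table`: a per-fold data frame
#'   (`fold`, `kappa`, `accuracy`, confusion counts `h_RR` ... `h_LL`), the
#'   pooled confusion matrix, mean/SD of fold kappas and the pooled kappa.
#' @export
run_protocol <- function(es, method = "ddag", algorithm = "FLDA",
                         odcs_m_best = NULL, ddag_order = "RIL",
                         grid = pstf_grid(), fs_target = 100,
                         n_chunks = 10L, seed = 1L, plan = NULL,
                         shuffle = FALSE) {
  stopifnot(inherits(es, "epoch_set"))
  if (is.null(plan)) plan <- make_folds(es, n_chunks, seed, shuffle)
  check_fold_plan(plan, es)
  # downsampling is a fixed per-epoch operation; doing it once up front is
  # identical to doing it inside every fold's fit and far cheaper
  es <- downsample(es, fs_target)
  rows <- vector("list", plan$n_chunks)
  pooled <- matrix(0L, 3, 3, dimnames = list(correct = CLASS_ORDER,
                                             predicted = CLASS_ORDER))
  for (f in seq_len(plan$n_chunks)) {
    fold <- plan$folds[[f]]
    if (length(intersect(fold$train_trials, fold$test_trials)) > 0L) {
      stop("leakage guard: aborting fold ", f)
    }
    train_idx <- which(es$trial_index %in% fold$train_trials)
    test_idx <- which(es$trial_index %in% fold$test_trials)
    fit <- fit_ternary(subset_epochs(es, train_idx), method = method,
                       algorithm = algorithm, odcs_m_best = odcs_m_best,
                       ddag_order = ddag_order, grid = grid,
                       fs_target = fs_target,
                       seed = derive_seed(seed, "fold", f))
    pred <- predict(fit, subset_epochs(es, test_idx))
    cm <- confusion_matrix(es$labels[test_idx], pred)
    pooled <- pooled + unclass(cm)
    h <- as.integer(t(unclass(cm))) # row-major: h_RR, h_RI, h_RL, h_IR, ...
    names(h) <- paste0("h_", rep(CLASS_ORDER, each = 3), rep(CLASS_ORDER, 3))
    rows[[f]] <- data.frame(participant = es$participant_id, method = method,
                            fold = f, kappa = cohen_kappa(cm),
                            accuracy = accuracy(cm), t(h))
  }
  folds_df <- do.call(rbind, rows)
  structure(list(
    folds = folds_df,
    pooled_confusion = as_confusion_matrix(pooled),
    mean_kappa = mean(folds_df$kappa),
    sd_kappa = sd(folds_df$kappa),
    pooled_kappa = cohen_kappa(pooled),
    method = method, seed = seed
  ), class = "result_table")
}

#' @export
print.result_table <- function(x, ...) {
  cat("<result_table> method=", x$method, ": mean fold kappa = ",
      sprintf("%.4f", x$mean_kappa), " (SD ", sprintf("%.4f", x$sd_kappa),
      "), pooled kappa = ", sprintf("%.4f", x$pooled_kappa), "\n", sep = "")
  print(x$pooled_confusion)
  invisible(x)
}

#' Write a result table to CSV files
#'
#' @param rt A `result_table`.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Paths of the written files, invisibly.
#' @export
write_results <- function(rt, dir, prefix = rt$method) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, paste0(prefix, "_folds.csv"))
  data.table::fwrite(rt$folds, f1)
  summ <- data.frame(method = rt$method, mean_kappa = rt$mean_kappa,
                     sd_kappa = rt$sd_kappa, pooled_kappa = rt$pooled_kappa)
  f2 <- file.path(dir, paste0(prefix, "_summary.csv"))
  data.table::fwrite(summ, f2)
  invisible(c(f1, f2))
}
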