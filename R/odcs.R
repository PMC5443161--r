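# Ordered diversified classifier system: per-subproblem ordering of the
# candidate algorithms by validation accuracy, top-1 selection and
# reliability-weighted-average fusion of the top-m posteriors.

#' Order candidate classification algorithms by validation accuracy
#'
#' Every candidate algorithm is trained on the subproblem's feature table and
#' scored by seeded stratified cross-validation (the same fold split for all
#' candidates). The list is sorted by decreasing validation accuracy, ties
#' resolving to the canonical algorithm order (LPGM, SVM, FLDA, LR, RLS).
#' The validation accuracy stored per entry is the same estimate later used
#' as the reliability weight in fusion.
#'
#' @param X Feature table, samples x features (typically PSTF output).
#' @param y Labels of the (balanced) subproblem.
#' @param algorithms Character vector of candidate algorithm ids.
#' @param n_val_folds Validation folds (default 5).
#' @param seed Integer seed.
#' @param rls_lambda Ridge candidates forwarded to RLS.
#' @return An object of class `ordered_classifier_list`: a list of entries
#'   `(algorithm_id, model, validation_accuracy)` sorted by decreasing
#'   accuracy.
#' @export
order_classifiers <- function(X, y, algorithms = ALGORITHM_ORDER,
                              n_val_folds = 5L, seed = 1L,
                              rls_lambda = RLS_LAMBDA_DEFAULT) {
  stopifnot(length(algorithms) >= 1)
  algorithms <- match.arg(algorithms, ALGORITHM_ORDER, several.ok = TRUE)
  va <- vapply(algorithms, function(a) {
    cv_accuracy(a, X, y, n_val_folds, derive_seed(seed, "va"),
                rls_lambda = rls_lambda)
  }, numeric(1))
  ord <- order(-va, match(algorithms, ALGORITHM_ORDER))
  entries <- lapply(ord, function(i) {
    m <- train_classifier(algorithms[i], X, y,
                          seed = derive_seed(seed, "full", algorithms[i]),
                          rls_lambda = rls_lambda)
    m$validation_accuracy <- va[i]
    list(algorithm_id = algorithms[i], model = m,
         validation_accuracy = va[i])
  })
  structure(entries, class = "ordered_classifier_list")
}

#' @export
print.ordered_classifier_list <- function(x, ...) {
  cat("<ordered_classifier_list>\n")
  for (e in x) {
    cat(sprintf("  %-4s VA = %.4f\n", e$algorithm_id, e$validation_accuracy))
  }
  invisible(x)
}

#' Reliability-weighted average fusion of posterior probabilities
#'
#' Fuses `M` posterior estimates with weights
#' `omega_i = exp(VA_i) / sum_j exp(VA_j)` (softmax of the validation
#' accuracies), so more reliable classifiers contribute more while every
#' classifier retains positive weight. Equal accuracies reduce to plain
#' averaging; a single classifier is returned unchanged. The fusion is a
#' convex combination, so fused probabilities never leave the range spanned
#' by the inputs.
#'
#' @param prob_list List of probability vectors (or matrices with one row per
#'   test case) over the same class set.
#' @param vas Numeric vector of validation accuracies, one per element of
#'   `prob_list`.
#' @return Fused probabilities with the same shape as the inputs.
#' @export
rwa_fuse <- function(prob_list, vas) {
  if (length(prob_list) == 0L) stop("empty classifier list")
  stopifnot(length(prob_list) == length(vas))
  dims <- lapply(prob_list, dim)
  if (length(unique(vapply(prob_list, length, integer(1)))) != 1L) {
    stop("probability vectors must have equal length")
  }
  omega <- softmax(vas)
  fused <- Reduce(`+`, Map(`*`, prob_list, omega))
  fused
}

# Node posterior of an ordered classifier list: RWA fusion of the top-m
# entries (m = 1 reduces to selection of the best algorithm).
odcs_node_posterior <- function(ocl, X, m_best) {
  m <- min(m_best, length(ocl))
  if (m_best > length(ocl)) {
    warning("m_best = ", m_best, " exceeds the ", length(ocl),
            " candidates; clipped")
  }
  top <- ocl[seq_len(m)]
  rwa_fuse(lapply(top, function(e) predict_proba(e$model, X)),
           vapply(top, `[[`, numeric(1), "validation_accuracy"))
}
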