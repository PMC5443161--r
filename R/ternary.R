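# Top-level model: fit a ternary classifier (any scheme, single-algorithm or
# ODCS) on a training epoch set, and predict labels for held-out epochs.

#' Fit a ternary readiness-potential classifier
#'
#' Builds the scheme's balanced subproblems ([build_binary_problems()]),
#' fits one PSTF feature chain per subproblem by grid search ([fit_pstf()];
#' ternary-form scatter for `mcs`, binary form otherwise), then trains either
#' a single classification algorithm per subproblem or — with `odcs_m_best`
#' set — all candidate algorithms, ordered by validation accuracy, whose
#' top-`m` posteriors are fused at prediction time (reliability-weighted
#' averaging; `m = 1` is selection of the best algorithm). `method = "ddag"`
#' with `odcs_m_best = 3` is the ODCS3-DDAG configuration.
#'
#' @param train Training `epoch_set` with all three classes.
#' @param method One of `"mcs"`, `"oao"`, `"oaa"`, `"dbt"`, `"ddag"`.
#' @param algorithm Single algorithm id used when `odcs_m_best` is `NULL`
#'   (also the grid-search surrogate in that case).
#' @param odcs_m_best `NULL` for a single algorithm, or an integer 1..5: the
#'   number of top-ranked algorithms fused per subproblem.
#' @param odcs_algorithms Candidate algorithm set for ODCS.
#' @param ddag_order `"RIL"`, `"ILR"` or `"RLI"` (root = first vs last).
#' @param grid A [pstf_grid()].
#' @param fs_target Working sampling rate (Hz) for the PSTF.
#' @param n_inner_folds Inner CV folds of the PSTF grid search.
#' @param n_val_folds Validation folds for ODCS algorithm ordering.
#' @param grid_classifier Grid-search surrogate classifier for ODCS fits
#'   (default `"FLDA"`, the strongest closed-form candidate).
#' @param seed Integer seed; every internal draw derives from it.
#' @return An object of class `ternary_model`.
#' @export
fit_ternary <- function(train, method = "ddag", algorithm = "FLDA",
                        odcs_m_best = NULL,
                        odcs_algorithms = ALGORITHM_ORDER,
                        ddag_order = "RIL", grid = pstf_grid(),
                        fs_target = 100, n_inner_folds = 5L,
                        n_val_folds = 5L, grid_classifier = "FLDA",
                        seed = 1L) {
  method <- match.arg(method, TERNARY_METHODS)
  problems <- build_binary_problems(method, train, seed = derive_seed(seed, "bp"))
  surrogate <- if (is.null(odcs_m_best)) algorithm else grid_classifier
  fitted <- lapply(problems, function(p) {
    pseed <- derive_seed(seed, "prob", p$id)
    pstf <- fit_pstf(p$es, grid, classifier_id = surrogate,
                     n_inner_folds = n_inner_folds, fs_target = fs_target,
                     seed = pseed)
    feats <- pstf_transform(pstf, p$es)
    if (is.null(odcs_m_best)) {
      clf <- train_classifier(algorithm, feats, p$es$labels,
                              seed = derive_seed(pseed, "clf"))
      list(id = p$id, classes = p$classes, pstf = pstf, classifier = clf)
    } else {
      ocl <- order_classifiers(feats, p$es$labels,
                               algorithms = odcs_algorithms,
                               n_val_folds = n_val_folds,
                               seed = derive_seed(pseed, "odcs"))
      list(id = p$id, classes = p$classes, pstf = pstf, ordered = ocl)
    }
  })
  structure(list(method = method, ddag_order = ddag_order,
                 algorithm = algorithm, odcs_m_best = odcs_m_best,
                 problems = fitted, seed = seed),
            class = "ternary_model")
}

# Posterior matrix of one subproblem's node for an epoch set.
node_probs <- function(problem, model, es) {
  feats <- pstf_transform(problem$pstf, es)
  if (!is.null(problem$classifier)) {
    predict_proba(problem$classifier, feats)
  } else {
    odcs_node_posterior(problem$ordered, feats, model$odcs_m_best)
  }
}

#' Predict class labels from a fitted ternary model
#'
#' Each subproblem's PSTF transforms the test epochs and its (possibly fused)
#' classifier emits binary posteriors; the scheme's combination rule —
#' argmax for `mcs`, pairwise coupling for `oao`, maximum target probability
#' for `oaa`, tree/graph routing for `dbt`/`ddag` — produces exactly one of
#' `R`, `I`, `L` per epoch. Test epochs are never subsampled.
#'
#' @param object A `ternary_model`.
#' @param es An `epoch_set` of test epochs.
#' @param details If `TRUE`, also return the per-node posterior matrices.
#' @param ... Unused.
#' @return Character vector of predicted labels (or, with
#'   `details = TRUE`, a list with `labels` and `node_probs`).
#' @export
predict.ternary_model <- function(object, es, details = FALSE, ...) {
  stopifnot(inherits(es, "epoch_set"))
  k <- n_epochs(es)
  probs <- lapply(object$problems, node_probs, model = object, es = es)
  labels <- switch(
    object$method,
    mcs = {
      p <- probs[["R-I-L"]][, CLASS_ORDER, drop = FALSE]
      CLASS_ORDER[max.col(p, ties.method = "first")]
    },
    oao = {
      vapply(seq_len(k), function(i) {
        r <- matrix(0, 3, 3, dimnames = list(CLASS_ORDER, CLASS_ORDER))
        for (p in object$problems) {
          a <- p$classes[1]; b <- p$classes[2]
          r[a, b] <- probs[[p$id]][i, a]
          r[b, a] <- probs[[p$id]][i, b]
        }
        argmax_label(pairwise_couple(r))
      }, character(1))
    },
    oaa = {
      vapply(seq_len(k), function(i) {
        tp <- vapply(CLASS_ORDER, function(cl) {
          probs[[paste0(cl, "-A")]][i, cl]
        }, numeric(1))
        oaa_combine(tp)
      }, character(1))
    },
    dbt = {
      vapply(seq_len(k), function(i) {
        dbt_route(probs[["I-M"]][i, "I"], probs[["R-L"]][i, "R"])
      }, character(1))
    },
    ddag = {
      ord <- ddag_order_vec(object$ddag_order)
      vapply(seq_len(k), function(i) {
        ddag_route(ord, function(a, b) {
          id <- paste0(canonical_classes(c(a, b)), collapse = "-")
          probs[[id]][i, a]
        })
      }, character(1))
    }
  )
  if (details) list(labels = labels, node_probs = probs) else labels
}

#' @export
print.ternary_model <- function(x, ...) {
  cat("<ternary_model> method=", x$method,
      if (x$method == "ddag") paste0(" (", x$ddag_order, ")"),
      if (is.null(x$odcs_m_best)) paste0(", algorithm=", x$algorithm)
      else paste0(", ODCS m_best=", x$odcs_m_best),
      "\n", sep = "")
  for (p in x$problems) {
    cat("  node ", p$id, ": LPB=", p$pstf$filter_spec$low_pass_hz,
        " HPB=", p$pstf$filter_spec$high_pass_hz %||% "none",
        " gamma=", p$pstf$gamma, " w=", p$pstf$window, "\n", sep = "")
  }
  invisible(x)
}
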