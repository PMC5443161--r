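# The five candidate classification algorithms (LPGM, SVM, FLDA, LR, RLS)
# behind one fit/predict-probability contract. The decomposition and ensemble
# layers never branch on the algorithm id.

RLS_LAMBDA_DEFAULT <- c(0, 0.5, 1, 10, 1e2, 1e3, 1e4, 1e5)

# Pooled within-class covariance with trace-scaled ridge so near-degenerate
# feature sets (few features, subsampled folds) never crash.
pooled_covariance <- function(X, y, classes) {
  d <- ncol(X)
  s <- matrix(0, d, d)
  for (cl in classes) {
    xc <- X[y == cl, , drop = FALSE]
    xc <- sweep(xc, 2, colMeans(xc))
    s <- s + crossprod(xc)
  }
  s <- s / max(1L, nrow(X) - length(classes))
  tr <- sum(diag(s))
  if (tr <= 0) tr <- 1
  s + (1e-6 * tr / d) * diag(d)
}

gaussian_posterior <- function(X, means, sigma, priors, classes) {
  ch <- chol(sigma)
  logp <- vapply(classes, function(cl) {
    dx <- sweep(X, 2, means[[cl]])
    z <- backsolve(ch, t(dx), transpose = TRUE)
    -0.5 * colSums(z^2) + log(priors[[cl]])
  }, numeric(nrow(X)))
  logp <- matrix(logp, nrow = nrow(X),
                 dimnames = list(NULL, classes))
  p <- exp(logp - apply(logp, 1, max))
  p / rowSums(p)
}

fit_lpgm <- function(X, y, classes) {
  means <- lapply(classes, function(cl) colMeans(X[y == cl, , drop = FALSE]))
  names(means) <- classes
  priors <- vapply(classes, function(cl) mean(y == cl), numeric(1))
  list(means = means, sigma = pooled_covariance(X, y, classes),
       priors = as.list(priors))
}

# Fisher 1-D projection direction on the feature space; for two classes this
# is solve(S_w) (m1 - m2), generally the leading eigenvector of S_w^-1 S_b.
fisher_direction <- function(X, y, classes) {
  sw <- pooled_covariance(X, y, classes)
  if (length(classes) == 2L) {
    m1 <- colMeans(X[y == classes[1], , drop = FALSE])
    m2 <- colMeans(X[y == classes[2], , drop = FALSE])
    w <- solve(sw, m1 - m2)
  } else {
    gm <- colMeans(X)
    sb <- matrix(0, ncol(X), ncol(X))
    for (cl in classes) {
      dm <- colMeans(X[y == cl, , drop = FALSE]) - gm
      sb <- sb + mean(y == cl) * tcrossprod(dm)
    }
    eg <- eigen(solve(sw, sb))
    w <- Re(eg$vectors[, which.max(Re(eg$values))])
  }
  as.numeric(w / sqrt(sum(w^2)))
}

median_heuristic_gamma <- function(X) {
  n <- nrow(X)
  idx <- if (n > 200) sample.int(n, 200) else seq_len(n)
  d2 <- as.numeric(stats::dist(X[idx, , drop = FALSE]))^2
  m <- stats::median(d2[d2 > 0])
  if (!is.finite(m) || m <= 0) 1 / max(1L, ncol(X)) else 1 / m
}

fit_rls <- function(X, y, classes, lambda_candidates, seed) {
  n <- nrow(X)
  d <- ncol(X)
  xa <- cbind(1, X)
  targets <- outer(y, classes, `==`) * 1
  solve_rls <- function(xtr, ttr, lambda) {
    pen <- diag(c(0, rep(lambda, d)))  # intercept unpenalized
    solve(crossprod(xtr) + pen, crossprod(xtr, ttr))
  }
  lambda_candidates <- sort(unique(lambda_candidates))
  if (length(lambda_candidates) > 1L) {
    k <- min(5L, min(table(y)))
    folds <- stratified_folds(y, k, derive_seed(seed, "rls-cv"))
    acc <- vapply(lambda_candidates, function(lam) {
      hits <- 0L
      for (f in seq_len(k)) {
        tr <- folds != f
        w <- tryCatch(solve_rls(xa[tr, , drop = FALSE],
                                targets[tr, , drop = FALSE], lam),
                      error = function(e) NULL)
        if (is.null(w)) return(-1)
        pred <- classes[max.col(xa[!tr, , drop = FALSE] %*% w,
                                ties.method = "first")]
        hits <- hits + sum(pred == y[!tr])
      }
      hits / n
    }, numeric(1))
    # ties favour the larger lambda (stronger shrinkage)
    lambda <- lambda_candidates[max(which(acc == max(acc)))]
  } else {
    lambda <- lambda_candidates[1]
  }
  w <- tryCatch(solve_rls(xa, targets, lambda), error = function(e) {
    solve_rls(xa, targets, lambda + 1e-8 * sum(diag(crossprod(xa))))
  })
  list(weights = w, lambda = lambda)
}

#' Train one of the five candidate classification algorithms
#'
#' All five algorithms share the same contract: fit on a feature table with
#' class labels, then emit posterior class probabilities via
#' [predict_proba()].
#'
#' * `LPGM` — linear probabilistic Gaussian model: class-conditional
#'   Gaussians with a common (pooled, lightly ridged) covariance and
#'   empirical priors; Bayes posterior.
#' * `SVM` — RBF-kernel support vector machine (`e1071`), kernel width by the
#'   median heuristic, cost 1, Platt-calibrated probabilities.
#' * `FLDA` — Fisher linear discriminant: project features on the 1-D Fisher
#'   direction, then an LPGM on the projected scalars.
#' * `LR` — logistic regression by maximum likelihood (multinomial for more
#'   than two classes).
#' * `RLS` — regularized least squares on one-vs-rest indicators with the
#'   ridge weight `lambda` selected by seeded stratified 5-fold
#'   cross-validation (ties to the larger `lambda`); softmax over scores.
#'
#' @param algorithm_id One of `"LPGM"`, `"SVM"`, `"FLDA"`, `"LR"`, `"RLS"`.
#' @param X Numeric feature matrix, samples x features.
#' @param y Character labels, at least two classes with two samples each.
#' @param seed Integer seed controlling every internal source of randomness.
#' @param rls_lambda Candidate ridge weights for `RLS`.
#' @return An object of class `trained_classifier`.
#' @export
train_classifier <- function(algorithm_id, X, y,
                             seed = 1L, rls_lambda = RLS_LAMBDA_DEFAULT) {
  algorithm_id <- match.arg(algorithm_id, ALGORITHM_ORDER)
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- canonical_classes(y)
  if (length(classes) < 2L) stop("need at least two classes")
  if (min(table(y)) < 2L) stop("need at least two samples per class")
  fit <- switch(
    algorithm_id,
    LPGM = fit_lpgm(X, y, classes),
    FLDA = {
      w <- fisher_direction(X, y, classes)
      z <- matrix(X %*% w, ncol = 1)
      list(direction = w, lpgm = fit_lpgm(z, y, classes))
    },
    SVM = with_seed(derive_seed(seed, "svm"), {
      g <- median_heuristic_gamma(X)
      m <- e1071::svm(x = X, y = factor(y, levels = classes),
                      kernel = "radial", gamma = g, cost = 1,
                      probability = TRUE, scale = FALSE)
      list(svm = m)
    }),
    LR = with_seed(derive_seed(seed, "lr"), {
      df <- data.frame(.y = factor(y, levels = classes), X)
      m <- nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 500)
      list(multinom = m, feature_names = colnames(df)[-1])
    }),
    RLS = fit_rls(X, y, classes, rls_lambda, seed)
  )
  structure(list(algorithm_id = algorithm_id, fit = fit, classes = classes,
                 n_features = ncol(X), validation_accuracy = NA_real_),
            class = "trained_classifier")
}

#' Posterior class probabilities from a trained classifier
#'
#' @param model A `trained_classifier`.
#' @param X Numeric feature matrix with the training feature dimension.
#' @return Matrix, samples x classes (columns named and ordered as
#'   `model$classes`); every row sums to 1.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "trained_classifier"))
  X <- as.matrix(X)
  if (ncol(X) != model$n_features) {
    stop("feature dimension ", ncol(X), " does not match training (",
         model$n_features, ")")
  }
  classes <- model$classes
  fit <- model$fit
  p <- switch(
    model$algorithm_id,
    LPGM = gaussian_posterior(X, fit$means, fit$sigma, fit$priors, classes),
    FLDA = {
      z <- matrix(X %*% fit$direction, ncol = 1)
      gaussian_posterior(z, fit$lpgm$means, fit$lpgm$sigma, fit$lpgm$priors,
                         classes)
    },
    SVM = {
      pr <- attr(predict(fit$svm, X, probability = TRUE), "probabilities")
      pr[, classes, drop = FALSE]
    },
    LR = {
      df <- data.frame(X)
      colnames(df) <- fit$feature_names
      pr <- predict(fit$multinom, newdata = df, type = "probs")
      if (is.null(dim(pr))) { # binary: vector of P(class 2)
        pr <- cbind(1 - pr, pr)
        colnames(pr) <- classes
      }
      pr[, classes, drop = FALSE]
    },
    RLS = {
      scores <- cbind(1, X) %*% fit$weights
      e <- exp(scores - apply(scores, 1, max))
      pr <- e / rowSums(e)
      colnames(pr) <- classes
      pr
    }
  )
  p <- matrix(p, nrow = nrow(X), dimnames = list(NULL, classes))
  p / rowSums(p)
}

#' Hard labels from a trained classifier
#'
#' Argmax of [predict_proba()] with ties resolved to the earlier class in
#' canonical order.
#'
#' @param model A `trained_classifier`.
#' @param X Feature matrix.
#' @return Character vector of predicted labels.
#' @export
predict_label <- function(model, X) {
  p <- predict_proba(model, X)
  colnames(p)[max.col(p, ties.method = "first")]
}

# Mean stratified-CV accuracy of one algorithm on a feature table; the shared
# validation-accuracy estimate used by the PSTF grid search and ODCS.
cv_accuracy <- function(algorithm_id, X, y, n_folds, seed,
                        rls_lambda = RLS_LAMBDA_DEFAULT) {
  folds <- stratified_folds(y, n_folds, seed)
  accs <- vapply(seq_len(n_folds), function(f) {
    tr <- folds != f
    m <- train_classifier(algorithm_id, X[tr, , drop = FALSE], y[tr],
                          seed = derive_seed(seed, "cvfit", f),
                          rls_lambda = rls_lambda)
    mean(predict_label(m, X[!tr, , drop = FALSE]) == y[!tr])
  }, numeric(1))
  mean(accs)
}
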