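# Fisher-criterion spatial beamformer: class scatter matrices, the
# regularized generalized eigenproblem, and filter application.

#' Compute spatial class statistics and scatter matrices
#'
#' For epochs `X_{i,k}` (channels x samples) of class `C_i`, with class means
#' `M_i` and grand mean `M`:
#' between-class scatter `S_b = sum_i p_i (M_i - M)(M_i - M)'` with empirical
#' priors `p_i = K_i / K`, and within-class scatter
#' `S_w = sum_i sum_k (X_{i,k} - M_i)(X_{i,k} - M_i)'` (raw pooled scatter,
#' no normalization). Both are channels x channels, symmetric and positive
#' semi-definite.
#'
#' @param es An `epoch_set` with at least two classes, each with at least two
#'   epochs.
#' @return A list with `stats` (class means, grand mean, priors, counts) and
#'   `scatter` (matrices `S_b`, `S_w`).
#' @export
compute_scatter <- function(es) {
  stopifnot(inherits(es, "epoch_set"))
  cls <- canonical_classes(es$labels)
  if (length(cls) < 2L) {
    stop("scatter needs at least 2 classes; got ", length(cls))
  }
  counts <- vapply(cls, function(cl) sum(es$labels == cl), integer(1))
  if (any(counts < 2L)) stop("every class needs at least 2 epochs")
  nc <- n_channels(es)
  nt <- n_samples_es(es)
  k <- n_epochs(es)
  class_means <- lapply(cls, function(cl) {
    idx <- which(es$labels == cl)
    matrix(rowMeans(matrix(es$data[, , idx, drop = FALSE], nc * nt)), nc, nt)
  })
  names(class_means) <- cls
  priors <- counts / k
  grand <- Reduce(`+`, Map(`*`, class_means, priors))
  s_b <- matrix(0, nc, nc)
  for (i in seq_along(cls)) {
    d <- class_means[[i]] - grand
    s_b <- s_b + priors[i] * tcrossprod(d)
  }
  s_w <- matrix(0, nc, nc)
  for (i in seq_along(cls)) {
    idx <- which(es$labels == cls[i])
    # stack centred epochs side by side: S_w contribution is one tcrossprod
    centred <- es$data[, , idx, drop = FALSE] -
      array(class_means[[i]], c(nc, nt, length(idx)))
    s_w <- s_w + tcrossprod(matrix(centred, nrow = nc))
  }
  s_b <- (s_b + t(s_b)) / 2
  s_w <- (s_w + t(s_w)) / 2
  list(
    stats = list(class_means = class_means, grand_mean = grand,
                 class_priors = priors, class_counts = counts),
    scatter = list(S_b = s_b, S_w = s_w)
  )
}

#' Fit the regularized Fisher-criterion beamformer
#'
#' Finds the spatial filter `W` maximizing the Fisher quotient
#' `J(W) = (W' S_b W) / (W' (S_w + gamma I) W)`, i.e. the leading eigenvector
#' of `(S_w + gamma I)^-1 S_b`. Solved on the symmetrized form via Cholesky
#' whitening of `S_w + gamma I` for numerical stability. `W` is returned with
#' unit Euclidean norm and its largest-magnitude entry positive.
#'
#' @param scatter A list with `S_b` and `S_w` as from [compute_scatter()].
#' @param gamma Regularization coefficient, >= 0. Larger values shrink toward
#'   the leading eigenvector of `S_b` alone and enforce invertibility.
#' @return An object of class `beamformer_model` with fields `W`, `gamma` and
#'   `eigenvalues` (sorted decreasing).
#' @export
fit_beamformer <- function(scatter, gamma = 0) {
  stopifnot(gamma >= 0)
  s_b <- scatter$S_b
  s_w <- scatter$S_w
  n <- nrow(s_w)
  s_wr <- s_w + gamma * diag(n)
  ch <- tryCatch(chol(s_wr), error = function(e) NULL)
  if (is.null(ch)) {
    stop("S_w + gamma*I is not positive definite; use gamma > 0")
  }
  # whiten: with S_w + gamma I = R'R, solve symmetric eig of R'^-1 S_b R^-1
  ri <- backsolve(ch, diag(n))
  m <- crossprod(ri, s_b %*% ri)
  m <- (m + t(m)) / 2
  eg <- eigen(m, symmetric = TRUE)
  w <- ri %*% eg$vectors[, 1]
  w <- w / sqrt(sum(w^2))
  if (w[which.max(abs(w))] < 0) w <- -w
  structure(list(W = as.numeric(w), gamma = gamma, eigenvalues = eg$values),
            class = "beamformer_model")
}

#' Apply a beamformer to a spatio-temporal epoch
#'
#' The spatial filter output is `y = W' X`, a single virtual-channel time
#' course per epoch.
#'
#' @param x Numeric matrix, channels x samples.
#' @param model A `beamformer_model`.
#' @return Numeric vector of length `ncol(x)`.
#' @export
apply_beamformer <- function(x, model) {
  stopifnot(inherits(model, "beamformer_model"))
  x <- as.matrix(x)
  if (nrow(x) != length(model$W)) {
    stop("epoch has ", nrow(x), " channels but the filter expects ",
         length(model$W))
  }
  as.numeric(crossprod(model$W, x))
}

# Fisher quotient at a given direction (used by tests and diagnostics).
fisher_quotient <- function(w, scatter, gamma = 0) {
  denom <- as.numeric(crossprod(w, (scatter$S_w + gamma * diag(length(w))) %*% w))
  as.numeric(crossprod(w, scatter$S_b %*% w)) / denom
}
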