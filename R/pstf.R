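# PSTF assembly: temporal window averaging and the per-problem hyperparameter
# grid search over filter cut-offs, beamformer regularization and window size.

#' PSTF hyperparameter grid
#'
#' Candidate values searched exhaustively by [fit_pstf()]. Defaults are the
#' standard candidate sets: low-pass cut-offs 1-7 Hz, high-pass
#' none/0.1/0.3/0.5 Hz (`NA` = none), beamformer regularization
#' `{0, 1, 10, 1e3, 1e4, 1e5, 1e6}` and averaging windows `{5, 10, 25}`
#' samples.
#'
#' @param low_pass Numeric vector of low-pass cut-offs (Hz).
#' @param high_pass Numeric vector of high-pass cut-offs (Hz); `NA` means no
#'   high-pass filter.
#' @param gamma Numeric vector of regularization coefficients (>= 0).
#' @param window Integer vector of window sizes (samples).
#' @return An object of class `pstf_grid`.
#' @export
pstf_grid <- function(low_pass = 1:7,
                      high_pass = c(NA, 0.1, 0.3, 0.5),
                      gamma = c(0, 1, 10, 1e3, 1e4, 1e5, 1e6),
                      window = c(5L, 10L, 25L)) {
  stopifnot(length(low_pass) > 0, length(high_pass) > 0,
            length(gamma) > 0, length(window) > 0,
            all(gamma >= 0), all(window >= 1))
  structure(list(low_pass = sort(low_pass),
                 high_pass = c(if (anyNA(high_pass)) NA,
                               sort(high_pass[!is.na(high_pass)])),
                 gamma = sort(gamma), window = sort(as.integer(window))),
            class = "pstf_grid")
}

#' Average a signal over consecutive non-overlapping windows
#'
#' Feature `j` is the mean of samples `[j*w, (j+1)*w)`; trailing samples that
#' do not fill a window are dropped, so the output length is `floor(T/w)`.
#' This captures the slow temporal evolution of the readiness potential while
#' reducing dimensionality.
#'
#' @param y Numeric vector (a spatially filtered epoch).
#' @param w Window size in samples, `1 <= w <= length(y)`.
#' @return Numeric vector of length `floor(length(y)/w)`.
#' @export
window_average <- function(y, w) {
  w <- as.integer(w)
  if (w < 1L) stop("window size must be a positive integer")
  if (w > length(y)) stop("window size exceeds the signal length")
  tp <- length(y) %/% w
  colMeans(matrix(y[seq_len(tp * w)], nrow = w))
}

# Window-average each row of a K x T matrix; always returns K x T'.
# One matrix product against the block-averaging operator.
window_average_rows <- function(Y, w) {
  w <- as.integer(w)
  nt <- ncol(Y)
  tp <- nt %/% w
  a <- matrix(0, nt, tp)
  for (j in seq_len(tp)) a[(j - 1L) * w + seq_len(w), j] <- 1 / w
  Y %*% a
}

# Enumerate grid combinations in deterministic tie-break order: lower
# low-pass first, then no-high-pass first, then lower gamma, then LARGER
# window. which.max over this order realises the tie rule.
grid_combos <- function(grid) {
  g <- expand.grid(window = rev(grid$window), gamma = grid$gamma,
                   high_pass = grid$high_pass, low_pass = grid$low_pass,
                   KEEP.OUT.ATTRS = FALSE)
  g[, c("low_pass", "high_pass", "gamma", "window")]
}

#' Fit the full PSTF chain by exhaustive grid search
#'
#' Searches the cartesian product of the grid by seeded stratified inner
#' cross-validation. For each combination the chain
#' downsample -> EOG regression -> band filtering -> Fisher beamformer ->
#' window averaging -> classifier is fitted on the inner-training folds and
#' scored on the inner-validation folds; the combination with the highest
#' mean validation accuracy wins, ties resolved toward lower low-pass, absent
#' high-pass, lower regularization and larger window. EOG regression is
#' always fitted on (inner-)training epochs only. Combinations whose
#' unregularized beamformer fails on a singular within-class scatter score 0
#' rather than aborting the search.
#'
#' The returned model freezes the winning filter spec, an EOG model refitted
#' on all supplied training epochs, the refitted beamformer and the window
#' size.
#'
#' @param train Training `epoch_set` (the test set is never passed in).
#' @param grid A [pstf_grid()].
#' @param classifier_id Algorithm used to score combinations (and normally
#'   trained later on the winning features).
#' @param n_inner_folds Number of inner CV folds (default 5).
#' @param fs_target Working sampling rate in Hz after downsampling
#'   (default 100).
#' @param seed Integer seed; fold assignment is a pure function of the labels
#'   and this seed.
#' @return An object of class `pstf_model` with fields `filter_spec`,
#'   `eog_model`, `beamformer`, `window`, `cv_score` and the full
#'   `score_table`.
#' @export
fit_pstf <- function(train, grid, classifier_id = "FLDA",
                     n_inner_folds = 5L, fs_target = 100, seed = 1L) {
  stopifnot(inherits(train, "epoch_set"), inherits(grid, "pstf_grid"))
  es <- downsample(train, fs_target)
  nc <- n_channels(es)
  nt <- n_samples_es(es)
  k <- n_epochs(es)
  y <- es$labels
  folds <- stratified_folds(y, n_inner_folds, derive_seed(seed, "pstf-inner"))

  # EOG regression per inner fold on unfiltered downsampled data; filtering
  # commutes with the subtraction, so filtered signals are corrected with the
  # same coefficients (filtered(EEG) - b' filtered(EOG)).
  eog_models <- lapply(seq_len(n_inner_folds), function(f) {
    fit_eog_regression(subset_epochs(es, which(folds != f)))
  })

  combos <- grid_combos(grid)
  scores <- numeric(nrow(combos))
  fpairs <- unique(combos[, c("low_pass", "high_pass")])
  for (fp in seq_len(nrow(fpairs))) {
    lp <- fpairs$low_pass[fp]
    hp <- fpairs$high_pass[fp]
    spec <- filter_spec(lp, if (is.na(hp)) NULL else hp)
    fes <- bandpass_filter(es, spec)
    rows <- which(combos$low_pass == lp &
                    (is.na(hp) & is.na(combos$high_pass) |
                       !is.na(hp) & !is.na(combos$high_pass) &
                       combos$high_pass == hp))
    sub <- combos[rows, ]
    acc <- matrix(0, length(rows), n_inner_folds)
    for (f in seq_len(n_inner_folds)) {
      b <- eog_models[[f]]$coefficients
      xmat <- matrix(fes$data, nrow = nc) -
        crossprod(b, matrix(fes$eog, nrow = dim(fes$eog)[1]))
      tr_idx <- which(folds != f)
      reg_es <- es
      reg_es$data <- array(xmat, dim(es$data))
      sc <- compute_scatter(subset_epochs(reg_es, tr_idx))$scatter
      for (gamma in unique(sub$gamma)) {
        bf <- tryCatch(fit_beamformer(sc, gamma), error = function(e) NULL)
        grows <- which(sub$gamma == gamma)
        if (is.null(bf)) next # score stays 0
        yproj <- t(matrix(crossprod(bf$W, matrix(xmat, nrow = nc)), nrow = nt))
        for (r in grows) {
          w <- sub$window[r]
          if (w > nt) next
          feats <- window_average_rows(yproj, w)
          a <- tryCatch({
            m <- train_classifier(classifier_id,
                                  feats[tr_idx, , drop = FALSE], y[tr_idx],
                                  seed = derive_seed(seed, "grid", f, fp, w))
            mean(predict_label(m, feats[-tr_idx, , drop = FALSE]) == y[-tr_idx])
          }, error = function(e) 0)
          acc[r, f] <- a
        }
      }
    }
    scores[rows] <- rowMeans(acc)
  }

  best <- which.max(scores)
  lp <- combos$low_pass[best]
  hp <- combos$high_pass[best]
  win_spec <- filter_spec(lp, if (is.na(hp)) NULL else hp)

  # refit the frozen chain on all supplied training epochs
  eog_full <- fit_eog_regression(es)
  clean <- apply_eog_regression(es, eog_full)
  filtered <- bandpass_filter(clean, win_spec)
  sc <- compute_scatter(filtered)$scatter
  bf <- fit_beamformer(sc, combos$gamma[best])

  structure(list(
    filter_spec = win_spec, eog_model = eog_full, beamformer = bf,
    window = combos$window[best], gamma = combos$gamma[best],
    cv_score = scores[best], fs_target = fs_target, fs_acquire = train$fs,
    n_channels = nc,
    score_table = cbind(combos, score = scores)
  ), class = "pstf_model")
}

#' @export
print.pstf_model <- function(x, ...) {
  cat("<pstf_model> LPB=", x$filter_spec$low_pass_hz, "Hz, HPB=",
      x$filter_spec$high_pass_hz %||% "none", ", gamma=", x$gamma,
      ", window=", x$window, " samples, inner-CV accuracy=",
      round(x$cv_score, 4), "\n", sep = "")
  invisible(x)
}

#' Apply a fitted PSTF chain to an epoch set
#'
#' Deterministically applies the frozen chain (downsampling if the input is
#' at the acquisition rate, EOG regression, band filtering, beamformer,
#' window averaging) and returns the feature table.
#'
#' @param model A `pstf_model`.
#' @param es An `epoch_set` at the acquisition or working sampling rate.
#' @return Numeric feature matrix, epochs x `floor(T/window)`.
#' @export
pstf_transform <- function(model, es) {
  stopifnot(inherits(model, "pstf_model"), inherits(es, "epoch_set"))
  if (n_channels(es) != model$n_channels) {
    stop("channel count does not match the fitted model")
  }
  if (es$fs == model$fs_acquire) {
    es <- downsample(es, model$fs_target)
  } else if (es$fs != model$fs_target) {
    stop("sampling rate ", es$fs, " Hz matches neither the fitted ",
         "acquisition (", model$fs_acquire, ") nor working (",
         model$fs_target, ") rate")
  }
  es <- apply_eog_regression(es, model$eog_model)
  es <- bandpass_filter(es, model$filter_spec)
  nc <- n_channels(es)
  nt <- n_samples_es(es)
  yproj <- t(matrix(crossprod(model$beamformer$W, matrix(es$data, nrow = nc)),
                    nrow = nt))
  window_average_rows(yproj, model$window)
}
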