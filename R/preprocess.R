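# Pre-processing stage: zero-phase Butterworth band filtering, anti-aliased
# downsampling and EOG artifact regression.

#' Band filter specification
#'
#' Cascaded low-pass (`low_pass_hz`) and optional high-pass (`high_pass_hz`)
#' Butterworth filters, each applied forward-backward (zero phase).
#'
#' @param low_pass_hz Low-pass cut-off in Hz.
#' @param high_pass_hz High-pass cut-off in Hz, or `NULL` for low-pass only.
#' @param order Butterworth order per pass (default 4).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_pass_hz, high_pass_hz = NULL, order = 4L) {
  stopifnot(low_pass_hz > 0, order >= 1)
  if (!is.null(high_pass_hz)) {
    stopifnot(high_pass_hz > 0, high_pass_hz < low_pass_hz)
  }
  structure(list(low_pass_hz = low_pass_hz, high_pass_hz = high_pass_hz,
                 order = as.integer(order)),
            class = "filter_spec")
}

# One pass of a direct-form-II-transposed IIR filter over every column of X
# (rows = time, columns = independent signals). The time recursion is
# sequential but fully vectorized across signals, which is what makes the
# hyperparameter grid search affordable.
iir_pass <- function(b, a, X) {
  b <- b / a[1]
  a <- a / a[1]
  n <- max(length(b), length(a))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  s <- ncol(X)
  Y <- X * 0
  z <- matrix(0, n - 1L, s)
  for (t in seq_len(nrow(X))) {
    x <- X[t, ]
    y <- b[1] * x + z[1, ]
    if (n > 2L) {
      for (j in seq_len(n - 2L)) {
        z[j, ] <- b[j + 1L] * x + z[j + 1L, ] - a[j + 1L] * y
      }
    }
    z[n - 1L, ] <- b[n] * x - a[n] * y
    Y[t, ] <- y
  }
  Y
}

# Zero-phase (forward-backward) filtering of columns with odd-reflection
# padding of almost one epoch length at both ends; epochs are short relative
# to the filter transients, so padding is essential.
filtfilt_mat <- function(b, a, X) {
  t_len <- nrow(X)
  p <- t_len - 1L
  pre <- 2 * X[rep(1L, p), , drop = FALSE] - X[(p + 1L):2L, , drop = FALSE]
  post <- 2 * X[rep(t_len, p), , drop = FALSE] -
    X[(t_len - 1L):(t_len - p), , drop = FALSE]
  Xp <- rbind(pre, X, post)
  Y <- iir_pass(b, a, Xp)
  Y <- iir_pass(b, a, Y[nrow(Y):1L, , drop = FALSE])
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y[(p + 1L):(p + t_len), , drop = FALSE]
}

# Apply zero-phase Butterworth passes to a channels x samples x epochs array.
filter_array <- function(arr, spec, fs) {
  d <- dim(arr)
  ny <- fs / 2
  if (spec$low_pass_hz >= ny) {
    stop("low-pass cut-off ", spec$low_pass_hz, " Hz is not below Nyquist (",
         ny, " Hz)")
  }
  # columns = channel x epoch signals, rows = time
  X <- matrix(aperm(arr, c(2, 1, 3)), nrow = d[2])
  lp <- signal::butter(spec$order, spec$low_pass_hz / ny, type = "low")
  X <- filtfilt_mat(lp$b, lp$a, X)
  if (!is.null(spec$high_pass_hz)) {
    if (spec$high_pass_hz >= ny) {
      stop("high-pass cut-off is not below Nyquist")
    }
    hp <- signal::butter(spec$order, spec$high_pass_hz / ny, type = "high")
    X <- filtfilt_mat(hp$b, hp$a, X)
  }
  aperm(array(X, c(d[2], d[1], d[3])), c(2, 1, 3))
}

#' Zero-phase Butterworth band filtering of an epoch set
#'
#' Applies the low-pass and (optionally) high-pass Butterworth filters of a
#' [filter_spec()] forward and backward over each channel of each epoch, so
#' the net phase response is zero — essential for a waveform feature like the
#' readiness potential whose information is its slow time course. Carried EOG
#' segments are filtered identically so that subsequent EOG subtraction
#' operates on commensurate signals. Epoch count, labels and order are
#' unchanged.
#'
#' @param es An `epoch_set`.
#' @param spec A `filter_spec`.
#' @return A filtered `epoch_set`.
#' @export
bandpass_filter <- function(es, spec) {
  stopifnot(inherits(es, "epoch_set"), inherits(spec, "filter_spec"))
  es$data <- filter_array(es$data, spec, es$fs)
  if (!is.null(es$eog)) es$eog <- filter_array(es$eog, spec, es$fs)
  es
}

#' Downsample an epoch set by an integer factor
#'
#' A zero-phase anti-alias Butterworth low-pass at 80% of the target Nyquist
#' is applied before decimation. The acquisition rate must be an integer
#' multiple of the target rate.
#'
#' @param es An `epoch_set`.
#' @param fs_target Target sampling rate in Hz.
#' @return A downsampled `epoch_set` with `fs = fs_target`.
#' @export
downsample <- function(es, fs_target) {
  stopifnot(inherits(es, "epoch_set"), fs_target > 0)
  if (es$fs == fs_target) return(es)
  q <- es$fs / fs_target
  if (abs(q - round(q)) > 1e-9 || q < 1) {
    stop("sampling rate ", es$fs, " Hz is not an integer multiple of ",
         fs_target, " Hz")
  }
  q <- as.integer(round(q))
  aa <- filter_spec(0.8 * fs_target / 2, NULL, order = 8L)
  keep <- seq.int(1L, n_samples_es(es), by = q)
  es$data <- filter_array(es$data, aa, es$fs)[, keep, , drop = FALSE]
  if (!is.null(es$eog)) {
    es$eog <- filter_array(es$eog, aa, es$fs)[, keep, , drop = FALSE]
  }
  es$fs <- fs_target
  es
}

#' Fit the EOG artifact regression model
#'
#' Ordinary least squares of every EEG channel on the EOG channels over all
#' concatenated samples of the supplied (training) epochs:
#' `b = Cov(EOG)^-1 Cov(EOG, EEG)`. Ocular artifacts propagate near-linearly
#' to the scalp, so subtracting the EOG-predicted component suppresses them.
#' A singular EOG covariance (e.g. a constant EOG channel) is stabilized by
#' adding `1e-10 * trace` to its diagonal.
#'
#' @param es An `epoch_set` carrying EOG and at least two epochs.
#' @return An object of class `eog_model` with a `coefficients` matrix
#'   (`n_eog` x `n_channels`).
#' @export
fit_eog_regression <- function(es) {
  stopifnot(inherits(es, "epoch_set"))
  if (is.null(es$eog)) stop("epoch set carries no EOG")
  if (n_epochs(es) < 2L) stop("need at least 2 epochs to fit EOG regression")
  ne <- dim(es$eog)[1]
  G <- matrix(es$eog, nrow = ne)   # n_eog x (T*K), dim 1 is fastest
  X <- matrix(es$data, nrow = n_channels(es))
  Gc <- G - rowMeans(G)
  Xc <- X - rowMeans(X)
  cg <- tcrossprod(Gc)
  cgx <- Gc %*% t(Xc)
  tr <- sum(diag(cg))
  b <- tryCatch(solve(cg, cgx), error = function(e) NULL)
  if (is.null(b)) {
    if (tr == 0) {
      b <- matrix(0, ne, nrow(X))
    } else {
      b <- solve(cg + 1e-10 * tr * diag(ne), cgx)
    }
  }
  structure(list(coefficients = b, n_channels = nrow(X), n_eog = ne),
            class = "eog_model")
}

#' Subtract the EOG-predicted component from EEG
#'
#' Sample-wise `EEG - t(b) %*% EOG` with frozen coefficients, so a model
#' fitted on training epochs can be applied to held-out epochs without
#' leakage.
#'
#' @param es An `epoch_set` carrying EOG.
#' @param model An `eog_model` from [fit_eog_regression()].
#' @return An `epoch_set` with the artifact component removed.
#' @export
apply_eog_regression <- function(es, model) {
  stopifnot(inherits(es, "epoch_set"), inherits(model, "eog_model"))
  if (is.null(es$eog)) stop("epoch set carries no EOG")
  if (n_channels(es) != model$n_channels || dim(es$eog)[1] != model$n_eog) {
    stop("channel counts do not match the fitted EOG model")
  }
  d <- dim(es$data)
  X <- matrix(es$data, nrow = d[1])
  G <- matrix(es$eog, nrow = model$n_eog)
  es$data <- array(X - crossprod(model$coefficients, G), d)
  es
}
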