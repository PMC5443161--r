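# Shared fixtures: small in-code datasets for unit tests.

# Gaussian toy epoch set: class-dependent mean patterns on the first
# channel(s), optional EOG, unique trial index per epoch.
make_toy_epochs <- function(k_per_class = 10, nc = 4, nt = 20, fs = 100,
                            classes = c("R", "I", "L"), sep = 3, sd = 1,
                            seed = 1) {
  set.seed(seed)
  k <- k_per_class * length(classes)
  data <- array(rnorm(nc * nt * k, sd = sd), c(nc, nt, k))
  labels <- rep(classes, each = k_per_class)
  for (i in seq_len(k)) {
    ci <- (match(labels[i], classes) - 1L) %% nc + 1L
    data[ci, , i] <- data[ci, , i] + sep
  }
  epoch_set(data, labels, paste0("ch", seq_len(nc)), fs,
            eog = array(rnorm(2 * nt * k, sd = sd), c(2, nt, k)))
}

# Epoch set with prescribed per-class counts (for subsampling arithmetic).
make_counted_epochs <- function(n_l = 90, n_r = 90, n_i = 180, nc = 3,
                                nt = 10, seed = 2) {
  set.seed(seed)
  labels <- c(rep("L", n_l), rep("R", n_r), rep("I", n_i))
  k <- length(labels)
  epoch_set(array(rnorm(nc * nt * k), c(nc, nt, k)), labels,
            paste0("ch", seq_len(nc)), 100)
}

# Small, fast simulator configuration used by pipeline tests.
small_sim_cfg <- function(n_trials_per_side = 15, seed = 1, ...) {
  sim_config(n_trials_per_side = n_trials_per_side, fs_acquire = 200,
             seed = seed, ...)
}

# Minimal grid so pipeline tests stay fast.
tiny_grid <- function() {
  pstf_grid(low_pass = 3, high_pass = NA, gamma = 10, window = 25)
}

small_grid <- function() {
  pstf_grid(low_pass = c(1, 3), high_pass = NA, gamma = c(0, 10),
            window = c(10, 25))
}

# Reduced grid used for full protocol runs (a subset of the default
# candidate sets spanning the same ranges).
reduced_grid <- function() {
  pstf_grid(low_pass = c(1, 3, 5), high_pass = c(NA, 0.3),
            gamma = c(0, 10, 1e4), window = c(5, 10, 25))
}

# Random symmetric PSD scatter pair for beamformer tests.
random_scatter_pair <- function(n, rank_b = 2) {
  a <- matrix(rnorm(n * n), n)
  s_w <- crossprod(a) + 0.1 * diag(n)
  b <- matrix(rnorm(n * rank_b), n)
  s_b <- tcrossprod(b)
  list(S_w = (s_w + t(s_w)) / 2, S_b = (s_b + t(s_b)) / 2)
}

cosine <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# A screened single-press trial with index-valued samples so window
# positions are directly readable from the extracted values.
make_index_trial <- function(fs = 100, cue_time = 5, press_time = 9.76,
                             n_total = 1200, cue_side = "R") {
  eeg <- matrix(seq_len(n_total) - 1, nrow = 1) # value = 0-based sample idx
  eog <- matrix(seq_len(n_total) - 1, nrow = 1)
  trial_record(eeg, eog, fs, cue_time, press_time, cue_side)
}
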