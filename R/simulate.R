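# Synthetic readiness-potential EEG generator with known ground truth,
# emulating a self-initiated key-press protocol: idle baseline, auditory cue,
# self-paced press, slow pre-movement negativity lateralized contralaterally
# over motor channels, pink + alpha background noise and blink artifacts
# mixed in from simulated EOG channels.

# 34-channel motor-centric 10-10 montage (the planted patterns load on the
# hand-area channels C1/C3/CP1/CP3 and their right-hemisphere mirrors).
DEFAULT_MONTAGE <- c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
  "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6",
  "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
  "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
  "P3", "Pz", "P4", "POz"
)

#' Simulation configuration
#'
#' Defaults emulate one participant of a self-initiated key-press protocol:
#' 400 trials (200 per hand), 34 EEG + 4 EOG channels at 1 kHz, press
#' latency 4.76 +/- 1.98 s after the cue (truncated at the 2 s screening
#' bound), and a slow negative pre-movement ramp beginning 1.5 s before the
#' press, larger over the hemisphere contralateral to the moving hand.
#' Amplitudes are in microvolts; the defaults put the single-trial RP
#' clearly above the pink/alpha background (a deliberately favourable,
#' synthetic regime — see the package vignette).
#'
#' @param n_channels,n_eog Channel counts.
#' @param fs_acquire Acquisition sampling rate in Hz.
#' @param n_trials_per_side Trials per hand.
#' @param rp_amplitude Peak negativity of the planted RP source (uV).
#' @param lateralization_ratio Contralateral/ipsilateral amplitude ratio
#'   (> 1; 1 makes left and right indistinguishable in expectation).
#' @param noise_pink Standard deviation of the 1/f background per channel.
#' @param noise_alpha Amplitude of the 8-12 Hz oscillation per channel.
#' @param eog_artifact_rate Expected blinks per trial.
#' @param eog_blink_amplitude Blink deflection on the EOG channels (uV).
#' @param p_reactive Fraction of trials with a reactive (< 2 s) press.
#' @param p_multipress Fraction of trials with a second key press.
#' @param channel_names Channel labels (length `n_channels`).
#' @param seed Integer seed; the dataset is a pure function of the config.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_channels = 34L, n_eog = 4L, fs_acquire = 1000,
                       n_trials_per_side = 200L, rp_amplitude = 12,
                       lateralization_ratio = 2, noise_pink = 2.5,
                       noise_alpha = 1.5, eog_artifact_rate = 0.5,
                       eog_blink_amplitude = 100, p_reactive = 0,
                       p_multipress = 0,
                       channel_names = NULL, seed = 1L) {
  if (is.null(channel_names)) {
    channel_names <- if (n_channels == 34L) DEFAULT_MONTAGE
    else paste0("ch", seq_len(n_channels))
  }
  stopifnot(length(channel_names) == n_channels,
            rp_amplitude >= 0, noise_pink >= 0, noise_alpha >= 0,
            lateralization_ratio > 0,
            p_reactive >= 0, p_reactive <= 1,
            p_multipress >= 0, p_multipress <= 1,
            eog_artifact_rate >= 0)
  structure(list(n_channels = as.integer(n_channels),
                 n_eog = as.integer(n_eog), fs_acquire = fs_acquire,
                 n_trials_per_side = as.integer(n_trials_per_side),
                 rp_amplitude = rp_amplitude,
                 lateralization_ratio = lateralization_ratio,
                 noise_pink = noise_pink, noise_alpha = noise_alpha,
                 eog_artifact_rate = eog_artifact_rate,
                 eog_blink_amplitude = eog_blink_amplitude,
                 p_reactive = p_reactive, p_multipress = p_multipress,
                 channel_names = channel_names, seed = as.integer(seed)),
            class = "sim_config")
}

# Unit-norm spatial loading of the RP source for one hand: contralateral
# hand-area channels weighted by the lateralization ratio, ipsilateral by 1,
# midline in between. Unknown montages fall back to index-based groups.
rp_pattern <- function(cfg, side) {
  nm <- cfg$channel_names
  left_hem <- c("C1", "C3", "CP1", "CP3")
  right_hem <- c("C2", "C4", "CP2", "CP4")
  midline <- c("Cz", "CPz", "FCz")
  w <- numeric(cfg$n_channels)
  if (all(c(left_hem, right_hem) %in% nm)) {
    contra <- if (side == "L") right_hem else left_hem
    ipsi <- if (side == "L") left_hem else right_hem
    w[match(contra, nm)] <- cfg$lateralization_ratio
    w[match(ipsi, nm)] <- 1
    w[stats::na.omit(match(midline, nm))] <- (1 + cfg$lateralization_ratio) / 2
  } else {
    half <- cfg$n_channels %/% 2
    idx_l <- seq_len(min(4L, half))
    idx_r <- half + seq_len(min(4L, half))
    contra <- if (side == "L") idx_r else idx_l
    ipsi <- if (side == "L") idx_l else idx_r
    w[contra] <- cfg$lateralization_ratio
    w[ipsi] <- 1
  }
  w / sqrt(sum(w^2))
}

# 1/f ("pink") noise: white Gaussian spectrum shaped to power ~ 1/f, unit
# standard deviation. FFT length padded to a power of two.
pink_noise <- function(n) {
  nfft <- 2^ceiling(log2(max(n, 2)))
  x <- stats::rnorm(nfft)
  sp <- stats::fft(x)
  f <- seq(0, 1, length.out = nfft / 2 + 1)
  f[1] <- f[2]
  shape <- f^(-0.5)
  full <- c(shape, rev(shape[2:(nfft / 2)]))
  y <- Re(stats::fft(sp * full, inverse = TRUE)) / nfft
  y <- y[seq_len(n)]
  y / stats::sd(y)
}

# Raised-cosine blink deflection of the given duration.
blink_template <- function(fs, duration = 0.3) {
  n <- round(duration * fs)
  0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
}

# RP source time course on a trial's time axis: zero until 1.5 s before the
# press, linear ramp to -1 at the press, recovery over 0.3 s after.
rp_source <- function(t, press) {
  s <- numeric(length(t))
  ramp <- t >= press - 1.5 & t < press
  s[ramp] <- -(t[ramp] - (press - 1.5)) / 1.5
  rec <- t >= press & t < press + 0.3
  s[rec] <- -(1 - (t[rec] - press) / 0.3)
  s
}

draw_press_latency <- function() {
  repeat {
    x <- stats::rnorm(1, 4.76, 1.98)
    if (x >= 2 && x <= 12) return(x)
  }
}

#' Simulate a synthetic readiness-potential dataset
#'
#' Generates `2 * n_trials_per_side` trials (sides interleaved in a seeded
#' random order). Each trial holds continuous EEG and EOG from trial start to
#' shortly after the (last) key press: pink background noise (independent per
#' channel plus a shared common-mode term), an 8-12 Hz oscillation, blink
#' artifacts mixed into the EEG through a known frontal-weighted EOG mixing
#' matrix, and — from 1.5 s before the press — the lateralized negative RP
#' ramp. Configured fractions of trials deliberately violate the screening
#' rules (reactive presses, double presses). The output is bit-reproducible
#' from the config seed.
#'
#' @param cfg A [sim_config()].
#' @return A list with `trials` (list of [trial_record()]) and
#'   `ground_truth` (`pattern_left`, `pattern_right` unit spatial vectors,
#'   `eog_mixing`, `rp_source` function).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  fs <- cfg$fs_acquire
  nc <- cfg$n_channels
  ne <- cfg$n_eog
  pat <- list(L = rp_pattern(cfg, "L"), R = rp_pattern(cfg, "R"))

  # frontal-weighted EOG propagation into the EEG, strongest at Fp, decaying
  # toward posterior rows; deterministic and returned as ground truth
  group_gain <- function(name) {
    if (grepl("^Fp", name)) 0.15
    else if (grepl("^F[^C]", name) || name == "Fz") 0.08
    else if (grepl("^FC", name)) 0.04
    else if (grepl("^C[^P]", name) || name == "Cz") 0.02
    else if (grepl("^CP", name)) 0.01
    else 0.005
  }
  gains <- vapply(cfg$channel_names, group_gain, numeric(1))
  eog_mixing <- outer(c(1, 0.8, -0.6, 0.4)[seq_len(ne)], gains)

  n_trials <- 2L * cfg$n_trials_per_side
  sides <- with_seed(derive_seed(cfg$seed, "sides"),
                     sample(rep(c("L", "R"), cfg$n_trials_per_side)))
  n_react <- round(cfg$p_reactive * n_trials)
  n_multi <- round(cfg$p_multipress * n_trials)
  kind <- with_seed(derive_seed(cfg$seed, "kind"),
                    sample(rep(c("reactive", "multi", "valid"),
                               c(n_react, n_multi,
                                 n_trials - n_react - n_multi))))

  trials <- with_seed(derive_seed(cfg$seed, "trials"), {
    lapply(seq_len(n_trials), function(i) {
      cue <- runif(1, 0.8, 1.2)
      latency <- if (kind[i] == "reactive") runif(1, 0.3, 1.9)
      else draw_press_latency()
      press <- cue + latency
      presses <- press
      if (kind[i] == "multi") presses <- c(press, press + runif(1, 0.5, 1.5))
      dur <- max(presses) + 0.25
      n <- ceiling(dur * fs)
      t <- (seq_len(n) - 1) / fs

      # EOG: blinks + sensor noise
      eog <- matrix(rnorm(ne * n, sd = 1), ne, n)
      n_blinks <- stats::rpois(1, cfg$eog_artifact_rate)
      if (n_blinks > 0) {
        tpl <- blink_template(fs) * cfg$eog_blink_amplitude
        for (b in seq_len(n_blinks)) {
          start <- sample.int(max(1L, n - length(tpl)), 1)
          span <- start:(start + length(tpl) - 1L)
          per_ch <- c(1, 0.9, 0.8, 0.7)[seq_len(ne)]
          eog[, span] <- eog[, span] + outer(per_ch, tpl)
        }
      }

      common <- pink_noise(n)
      eeg <- matrix(0, nc, n)
      for (ch in seq_len(nc)) {
        eeg[ch, ] <- cfg$noise_pink * (pink_noise(n) + 0.5 * common) +
          cfg$noise_alpha * sin(2 * pi * runif(1, 8, 12) * t +
                                  runif(1, 0, 2 * pi))
      }
      s <- rp_source(t, press)
      eeg <- eeg + cfg$rp_amplitude * outer(pat[[sides[i]]], s)
      eeg <- eeg + t(eog_mixing) %*% eog
      rownames(eeg) <- cfg$channel_names
      trial_record(eeg, eog, fs, cue, presses, sides[i])
    })
  })

  list(trials = trials,
       ground_truth = list(pattern_left = pat$L, pattern_right = pat$R,
                           eog_mixing = eog_mixing, rp_source = rp_source))
}

#' Simulate, screen and epoch a dataset in one call
#'
#' Convenience wrapper: [simulate_dataset()], [screen_trials()],
#' [epochs_from_trials()].
#'
#' @param cfg A [sim_config()].
#' @param participant_id Identifier for the epoch set.
#' @return A list with `epochs` (an `epoch_set`), `ground_truth` and the
#'   screening `report`.
#' @export
simulate_epochs <- function(cfg, participant_id = "SIM1") {
  sim <- simulate_dataset(cfg)
  scr <- screen_trials(sim$trials)
  es <- epochs_from_trials(scr$trials, channel_names = cfg$channel_names,
                           participant_id = participant_id)
  list(epochs = es, ground_truth = sim$ground_truth, report = scr$report)
}

#' Build a suite of datasets at graded signal-to-noise levels
#'
#' All levels share the seed, the planted spatial patterns and the protocol
#' timing; only the RP source amplitude is scaled by the level, so level 0
#' contains no class signal at all and classification performance should be
#' non-decreasing across levels.
#'
#' @param levels Numeric vector of SNR multipliers, sorted ascending.
#' @param cfg Base [sim_config()].
#' @return Named list of `simulate_dataset()` results, one per level.
#' @export
make_separability_suite <- function(levels, cfg = sim_config()) {
  stopifnot(!is.unsorted(levels))
  out <- lapply(levels, function(s) {
    c2 <- cfg
    c2$rp_amplitude <- cfg$rp_amplitude * s
    simulate_dataset(c2)
  })
  names(out) <- paste0("snr_", levels)
  out
}
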