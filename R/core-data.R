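# Domain containers: trial records, epoch sets, trial screening, epoch
# extraction and the on-disk epoch container.

#' Construct a trial record
#'
#' A trial record holds the continuous multichannel EEG (and parallel EOG) of
#' one experimental trial, together with the timing of the auditory cue and of
#' any key presses. Trials begin in an idle state; after the cue the
#' participant makes a self-initiated key press with the cued hand.
#'
#' @param eeg Numeric matrix, channels x samples.
#' @param eog Numeric matrix, EOG channels x samples (same sample count).
#' @param fs Sampling rate in Hz.
#' @param cue_time Time of the auditory cue, seconds from trial start.
#' @param press_times Numeric vector of key-press times in seconds (may be
#'   empty or contain several presses).
#' @param cue_side `"L"` or `"R"`, the cued hand.
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(eeg, eog, fs, cue_time, press_times, cue_side) {
  eeg <- as.matrix(eeg)
  eog <- as.matrix(eog)
  stopifnot(is.numeric(fs), fs > 0, cue_time >= 0)
  if (ncol(eog) != ncol(eeg)) {
    stop("EEG and EOG must cover the same samples")
  }
  dur <- ncol(eeg) / fs
  if (length(press_times) && any(press_times < 0 | press_times > dur)) {
    stop("press_times must lie within the trial duration")
  }
  cue_side <- match.arg(cue_side, c("L", "R"))
  structure(
    list(eeg = eeg, eog = eog, fs = fs, cue_time = cue_time,
         press_times = as.numeric(press_times), cue_side = cue_side),
    class = "trial_record"
  )
}

#' Construct an epoch set
#'
#' An epoch set is an ordered collection of fixed-length multichannel epochs
#' with one label per epoch drawn from `{"L", "R", "I"}` (left movement, right
#' movement, idle) — or, for binary subproblems, superclass pseudo-labels such
#' as `"A"` (all-others) or `"M"` (movement). Parallel EOG segments extracted
#' with identical windows may be carried alongside.
#'
#' @param data 3-d numeric array, channels x samples x epochs.
#' @param labels Character vector, one label per epoch.
#' @param channel_names Character vector of channel names.
#' @param fs Sampling rate in Hz.
#' @param eog Optional 3-d array, EOG channels x samples x epochs.
#' @param trial_index Optional integer vector mapping each epoch to the trial
#'   it came from (used for trial-level fold construction).
#' @param participant_id Identifier string.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, channel_names, fs, eog = NULL,
                      trial_index = NULL, participant_id = "P1") {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[3] != length(labels)) {
    stop("one label per epoch required")
  }
  if (dim(data)[1] != length(channel_names)) {
    stop("channel_names length must equal the channel count")
  }
  if (!all(is.finite(data))) stop("epoch data must be finite")
  if (!is.null(eog)) {
    stopifnot(length(dim(eog)) == 3, dim(eog)[2] == dim(data)[2],
              dim(eog)[3] == dim(data)[3])
  }
  if (is.null(trial_index)) trial_index <- seq_along(labels)
  structure(
    list(data = data, labels = as.character(labels),
         channel_names = as.character(channel_names), fs = fs, eog = eog,
         trial_index = as.integer(trial_index),
         participant_id = participant_id),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_set> ", d[3], " epochs, ", d[1], " channels x ", d[2],
      " samples @ ", x$fs, " Hz\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

n_epochs <- function(es) dim(es$data)[3]
n_channels <- function(es) dim(es$data)[1]
n_samples_es <- function(es) dim(es$data)[2]

#' Per-class epoch counts
#'
#' @param es An `epoch_set`.
#' @return Named integer vector of counts in canonical class order.
#' @export
class_counts <- function(es) {
  cls <- canonical_classes(es$labels)
  vapply(cls, function(cl) sum(es$labels == cl), integer(1))
}

#' Subset an epoch set by epoch index
#'
#' @param es An `epoch_set`.
#' @param idx Integer vector of epoch indices (order is preserved as given).
#' @param labels Optional replacement labels of the same length as `idx`
#'   (used to relabel epochs into superclasses for binary subproblems).
#' @return An `epoch_set` with the selected epochs.
#' @export
subset_epochs <- function(es, idx, labels = NULL) {
  idx <- as.integer(idx)
  es2 <- es
  es2$data <- es$data[, , idx, drop = FALSE]
  es2$labels <- if (is.null(labels)) es$labels[idx] else as.character(labels)
  es2$trial_index <- es$trial_index[idx]
  if (!is.null(es$eog)) es2$eog <- es$eog[, , idx, drop = FALSE]
  es2
}

#' Screen trials for valid self-initiated responses
#'
#' Trials are kept only if they contain exactly one key press occurring at
#' least 2 s after the auditory cue. A press within 2 s of the cue is a
#' reactive (cued rather than self-initiated) response; a press before the cue
#' is by definition not a response to that cue and is also counted as
#' reactive. Trials with multiple presses are rejected as multipress.
#'
#' @param trials List of `trial_record` objects.
#' @return A list with elements `trials` (kept records) and `report`, a list
#'   with `n_input`, `n_rejected_reactive`, `n_rejected_multipress` and
#'   `kept_indices`.
#' @export
screen_trials <- function(trials) {
  stopifnot(all(vapply(trials, inherits, logical(1), "trial_record")))
  n_multi <- 0L
  n_react <- 0L
  kept <- integer(0)
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    if (length(tr$press_times) != 1L) {
      n_multi <- n_multi + (length(tr$press_times) > 1L)
      n_react <- n_react + (length(tr$press_times) == 0L)
      next
    }
    if (tr$press_times[1] - tr$cue_time < 2) {
      n_react <- n_react + 1L
      next
    }
    kept <- c(kept, i)
  }
  list(
    trials = trials[kept],
    report = list(n_input = length(trials),
                  n_rejected_reactive = n_react,
                  n_rejected_multipress = n_multi,
                  kept_indices = kept)
  )
}

# Half-open sample window [start, end) for a time interval, 0-based in spec
# terms; returned as 1-based R indices. Length depends only on fs.
epoch_window <- function(t_end, fs, duration = 0.5) {
  n <- as.integer(round_half_up(duration * fs))
  end0 <- as.integer(round_half_up(t_end * fs)) # 0-based exclusive end
  list(idx = seq.int(end0 - n + 1L, end0), n = n)
}

#' Extract idle and movement epochs from a screened trial
#'
#' The 500 ms interval immediately preceding the auditory cue is the idle
#' epoch; the 500 ms interval ending 130 ms before the key press is the
#' movement epoch, labelled `"L"` or `"R"` by the cued side. EOG segments are
#' extracted with identical windows. Windows are half-open in samples with
#' time-to-sample conversion by round-half-away-from-zero, so the epoch length
#' `round(0.5 * fs)` depends only on the sampling rate.
#'
#' @param trial A screened `trial_record` (exactly one press, >= 2 s after
#'   the cue).
#' @param duration Epoch duration in seconds (default 0.5).
#' @return List with elements `idle` and `movement`, each a list holding
#'   `data`, `eog` and `label`.
#' @export
extract_epochs <- function(trial, duration = 0.5) {
  stopifnot(inherits(trial, "trial_record"))
  if (length(trial$press_times) != 1L) {
    stop("trial must be screened: exactly one key press expected")
  }
  fs <- trial$fs
  press <- trial$press_times[1]
  idle_w <- epoch_window(trial$cue_time, fs, duration)
  move_w <- epoch_window(press - 0.130, fs, duration)
  if (idle_w$idx[1] < 1L) {
    stop("insufficient pre-cue samples for the idle epoch (cue at ",
         trial$cue_time, " s)")
  }
  if (move_w$idx[1] < 1L || max(move_w$idx) > ncol(trial$eeg)) {
    stop("insufficient samples for the movement epoch (press at ",
         press, " s)")
  }
  list(
    idle = list(data = trial$eeg[, idle_w$idx, drop = FALSE],
                eog = trial$eog[, idle_w$idx, drop = FALSE],
                label = "I"),
    movement = list(data = trial$eeg[, move_w$idx, drop = FALSE],
                    eog = trial$eog[, move_w$idx, drop = FALSE],
                    label = trial$cue_side)
  )
}

#' Build an epoch set from screened trials
#'
#' Runs [extract_epochs()] on every trial and assembles one `epoch_set` in
#' trial order (idle epoch then movement epoch per trial), sharing the trial
#' index between the two epochs of a trial so fold construction can operate
#' at the trial level.
#'
#' @param trials List of screened `trial_record` objects with a common
#'   sampling rate and channel count.
#' @param channel_names Channel names for the EEG rows.
#' @param participant_id Identifier carried into the epoch set.
#' @return An `epoch_set` with `2 * length(trials)` epochs.
#' @export
epochs_from_trials <- function(trials, channel_names = NULL,
                               participant_id = "P1") {
  stopifnot(length(trials) >= 1)
  fs <- trials[[1]]$fs
  ex <- lapply(trials, extract_epochs)
  n <- vapply(ex, function(e) ncol(e$idle$data), integer(1))
  t_common <- min(n) # uniform T across the set
  nc <- nrow(trials[[1]]$eeg)
  ne <- nrow(trials[[1]]$eog)
  k <- 2L * length(trials)
  data <- array(0, c(nc, t_common, k))
  eog <- array(0, c(ne, t_common, k))
  labels <- character(k)
  tidx <- integer(k)
  for (i in seq_along(ex)) {
    for (j in 1:2) {
      ep <- ex[[i]][[j]]
      pos <- 2L * (i - 1L) + j
      data[, , pos] <- ep$data[, seq_len(t_common)]
      eog[, , pos] <- ep$eog[, seq_len(t_common)]
      labels[pos] <- ep$label
      tidx[pos] <- i
    }
  }
  if (is.null(channel_names)) {
    channel_names <- rownames(trials[[1]]$eeg) %||% paste0("ch", seq_len(nc))
  }
  epoch_set(data, labels, channel_names, fs, eog = eog, trial_index = tidx,
            participant_id = participant_id)
}

#' Write an epoch set to a CSV directory container
#'
#' One CSV per epoch (rows = channels, columns = samples), a `manifest.csv`
#' with filename, label, participant and trial index per epoch (plus the EOG
#' filename when EOG is present), and a `meta.json` with the sampling rate and
#' channel names. Doubles are written in shortest round-trip representation,
#' so write-then-read reproduces the data bit-exactly.
#'
#' @param es An `epoch_set`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_epoch_container <- function(es, path) {
  stopifnot(inherits(es, "epoch_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  k <- n_epochs(es)
  files <- sprintf("epoch_%04d.csv", seq_len(k))
  eog_files <- if (!is.null(es$eog)) sprintf("eog_%04d.csv", seq_len(k)) else rep(NA_character_, k)
  # doubles are serialized as %.17g so the decimal text parses back to the
  # identical IEEE value
  write_mat <- function(m, file) {
    dt <- data.table::as.data.table(matrix(sprintf("%.17g", m), nrow(m)))
    data.table::fwrite(dt, file, quote = FALSE)
  }
  for (i in seq_len(k)) {
    write_mat(es$data[, , i], file.path(path, files[i]))
    if (!is.null(es$eog)) {
      write_mat(es$eog[, , i], file.path(path, eog_files[i]))
    }
  }
  manifest <- data.table::data.table(
    filename = files, label = es$labels,
    participant_id = es$participant_id, trial_index = es$trial_index,
    eog_filename = eog_files
  )
  data.table::fwrite(manifest, file.path(path, "manifest.csv"))
  meta <- list(fs = es$fs, channel_names = es$channel_names,
               n_samples = n_samples_es(es),
               n_eog = if (is.null(es$eog)) 0L else dim(es$eog)[1],
               participant_id = es$participant_id)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an epoch set from a CSV directory container
#'
#' @param path Directory written by [write_epoch_container()].
#' @return An `epoch_set`.
#' @export
read_epoch_container <- function(path) {
  meta_file <- file.path(path, "meta.json")
  man_file <- file.path(path, "manifest.csv")
  if (!file.exists(meta_file) || !file.exists(man_file)) {
    stop("not an epoch container: missing meta.json or manifest.csv in ", path)
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  if (is.null(meta$fs)) stop("format error: meta.json lacks sampling rate 'fs'")
  manifest <- data.table::fread(man_file, colClasses = list(
    character = c("filename", "label", "participant_id")))
  k <- nrow(manifest)
  nc <- length(meta$channel_names)
  nt <- as.integer(meta$n_samples)
  bad <- setdiff(manifest$label, c("L", "R", "I", "A", "M"))
  if (length(bad)) stop("format error: unknown label(s) ", paste(bad, collapse = ", "))
  data <- array(0, c(nc, nt, k))
  eog <- if (meta$n_eog > 0) array(0, c(meta$n_eog, nt, k)) else NULL
  for (i in seq_len(k)) {
    m <- as.matrix(data.table::fread(file.path(path, manifest$filename[i])))
    if (!identical(dim(m), c(nc, nt))) {
      stop("format error: epoch ", manifest$filename[i], " has shape ",
           nrow(m), "x", ncol(m), ", expected ", nc, "x", nt)
    }
    data[, , i] <- m
    if (!is.null(eog)) {
      eog[, , i] <- as.matrix(
        data.table::fread(file.path(path, manifest$eog_filename[i])))
    }
  }
  if (k == 0L) {
    return(epoch_set(array(0, c(nc, nt, 0)), character(0), meta$channel_names,
                     meta$fs, participant_id = meta$participant_id %||% "P1"))
  }
  epoch_set(data, manifest$label, meta$channel_names, meta$fs, eog = eog,
            trial_index = manifest$trial_index,
            participant_id = meta$participant_id %||% manifest$participant_id[1])
}
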