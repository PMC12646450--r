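# Domain data model: session recordings, scored hypnograms, study manifests,
# and segmentation of a recording into scored epochs.

DEFAULT_CHANNELS <- c("F3", "F4", "Fz", "Cz")

#' Construct a session recording
#'
#' One subject-condition polysomnography session: a multichannel EEG signal
#' plus metadata. Channels are referenced implicitly (e.g. to Oz); only the
#' referenced signals are stored.
#'
#' @param signals Numeric matrix, samples x channels, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Unique channel labels, one per column.
#' @param subject_id Subject identifier.
#' @param condition Condition label, `"control"` or `"trazodone"`.
#' @return Object of class `session_recording`.
#' @export
session_recording <- function(signals, fs, channel_labels = colnames(signals),
                              subject_id = "unknown", condition = "control") {
  signals <- as.matrix(signals)
  if (is.null(channel_labels)) stop("channel labels are required")
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  if (length(channel_labels) != ncol(signals)) {
    stop("one label per signal column is required")
  }
  if (!is.numeric(fs) || fs <= 0) stop("sampling rate must be positive")
  condition <- match.arg(condition, c("control", "trazodone"))
  colnames(signals) <- channel_labels
  structure(
    list(subject_id = subject_id, condition = condition,
         channels = channel_labels, fs = fs, signals = signals,
         duration_s = nrow(signals) / fs),
    class = "session_recording"
  )
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> %s / %s: %d ch (%s), %g Hz, %.1f s\n",
              x$subject_id, x$condition, length(x$channels),
              paste(x$channels, collapse = ","), x$fs, x$duration_s))
  invisible(x)
}

#' Load a session recording from an EDF file
#'
#' @param path EDF file path.
#' @param expected_channels Channel labels to extract, in the order they
#'   should appear in the result. Channels present in the file but not
#'   requested are dropped; a requested channel missing from the file is an
#'   error naming it.
#' @param subject_id,condition Metadata attached to the recording.
#' @return A [session_recording()].
#' @export
load_recording <- function(path, expected_channels = DEFAULT_CHANNELS,
                           subject_id = "unknown", condition = "control") {
  edf <- read_edf(path)
  missing <- setdiff(expected_channels, edf$channel_labels)
  if (length(missing) > 0) {
    stop("channel(s) missing from ", path, ": ",
         paste(missing, collapse = ", "))
  }
  sig <- edf$signals[, expected_channels, drop = FALSE]
  session_recording(sig, edf$fs, expected_channels,
                    subject_id = subject_id, condition = condition)
}

#' Construct a hypnogram
#'
#' A scored sleep-state sequence in fixed-length epochs, with one artifact
#' flag per epoch (`TRUE` = epoch contaminated).
#'
#' @param states Integer state codes in `0:3` (see [state_codes()]).
#' @param artifact_flags Logical vector, same length as `states`. Defaults
#'   to all clean.
#' @param epoch_length_s Epoch duration in seconds (default 3).
#' @return Object of class `hypnogram`.
#' @export
hypnogram <- function(states, artifact_flags = rep(FALSE, length(states)),
                      epoch_length_s = 3) {
  states <- as.integer(states)
  if (length(states) > 0 && !all(states %in% 0:3)) {
    stop("state codes must be in 0:3")
  }
  if (length(artifact_flags) != length(states)) {
    stop("artifact_flags must match states in length")
  }
  if (epoch_length_s <= 0) stop("epoch_length_s must be positive")
  structure(
    list(states = states, artifact_flags = as.logical(artifact_flags),
         epoch_length_s = epoch_length_s),
    class = "hypnogram"
  )
}

#' @export
length.hypnogram <- function(x) length(x$states)

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs of %gs (%.1f min), %d flagged\n",
              length(x$states), x$epoch_length_s,
              length(x$states) * x$epoch_length_s / 60,
              sum(x$artifact_flags)))
  invisible(x)
}

#' Load a scored hypnogram from TSV
#'
#' Expects columns `epoch_index` (0-based, contiguous), `state`
#' (human-readable label: wake/W, drowsiness/D, NREM, REM; case
#' insensitive) and `artifact_flag` (logical or 0/1).
#'
#' @param path TSV file path.
#' @param epoch_length_s Epoch duration in seconds.
#' @return A [hypnogram()]. An empty file yields an empty hypnogram.
#' @export
load_hypnogram <- function(path, epoch_length_s = 3) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(hypnogram(integer(0), logical(0), epoch_length_s))
  need <- c("epoch_index", "state", "artifact_flag")
  if (!all(need %in% names(df))) {
    stop("hypnogram TSV must have columns ", paste(need, collapse = ", "))
  }
  if (!identical(as.integer(df$epoch_index), seq_len(nrow(df)) - 1L)) {
    stop("epoch_index must be contiguous and start at 0 in ", path)
  }
  labels <- normalize_state_label(df$state)
  if (anyNA(labels)) {
    bad <- which(is.na(labels))[1]
    stop(sprintf("unknown state label '%s' at row %d of %s",
                 df$state[bad], bad, path))
  }
  hypnogram(STATE_CODES[labels], as.logical(df$artifact_flag), epoch_length_s)
}

#' Write a hypnogram to TSV
#'
#' Inverse of [load_hypnogram()]: stores human-readable state labels.
#'
#' @param hyp A [hypnogram()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  df <- data.frame(
    epoch_index = seq_along(hyp$states) - 1L,
    state = state_name(hyp$states),
    artifact_flag = hyp$artifact_flags
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a study manifest
#'
#' A manifest pairs each subject's sessions with their files. Required
#' columns: `subject_id`, `condition`, `recording_path`, `hypnogram_path`;
#' optional: `weight_kg`, `age_months`. Paths are resolved relative to the
#' manifest's directory when not absolute.
#'
#' @param path Manifest TSV path.
#' @return Data frame with one row per session.
#' @export
load_manifest <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "condition", "recording_path", "hypnogram_path")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df[, c("subject_id", "condition")])) {
    stop("each subject may appear at most once per condition")
  }
  base <- dirname(path)
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  df$recording_path <- resolve(df$recording_path)
  df$hypnogram_path <- resolve(df$hypnogram_path)
  df
}

#' Segment a recording into scored epochs, grouped by state
#'
#' Epoch `i` (0-based) covers samples `[i*fs*epoch_length, (i+1)*fs*epoch_length)`
#' of every channel — half-open, non-overlapping intervals. At most one
#' scored epoch may be only partially covered by the recording tail; it is
#' dropped entirely, never padded. Samples beyond the scored span are
#' dropped.
#'
#' @param rec A [session_recording()].
#' @param hyp The session's [hypnogram()].
#' @return Named list (one entry per state present) of epoch sets: each has
#'   `state` (code), `epochs` (list of samples x channels matrices),
#'   `source_indices` (0-based epoch indices), `artifact_flags`, and
#'   `n_points_per_epoch`.
#' @export
segment_epochs <- function(rec, hyp) {
  spr <- as.integer(round(rec$fs * hyp$epoch_length_s))
  n_full <- nrow(rec$signals) %/% spr
  n_scored <- length(hyp$states)
  if (n_scored == 0) stop("empty hypnogram")
  if (n_full < n_scored - 1) {
    stop(sprintf(
      "hypnogram (%d epochs) exceeds recording (%d full epochs) by more than one epoch",
      n_scored, n_full))
  }
  n_use <- min(n_full, n_scored)
  if (n_use == 0) stop("recording shorter than scoring: no complete epoch")
  out <- list()
  for (nm in STATE_NAMES) {
    code <- STATE_CODES[[nm]]
    idx <- which(hyp$states[seq_len(n_use)] == code) - 1L
    if (length(idx) == 0) next
    epochs <- lapply(idx, function(i) {
      rec$signals[(i * spr + 1):((i + 1) * spr), , drop = FALSE]
    })
    out[[nm]] <- epoch_set(code, epochs, idx, hyp$artifact_flags[idx + 1L])
  }
  out
}

epoch_set <- function(state, epochs, source_indices, artifact_flags,
                      seed = NULL) {
  structure(
    list(state = state, epochs = epochs,
         n_points_per_epoch = if (length(epochs)) nrow(epochs[[1]]) else 0L,
         source_indices = source_indices,
         artifact_flags = artifact_flags, seed = seed),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> state %s: %d epochs x %d samples (%d flagged)\n",
              state_name(x$state), length(x$epochs), x$n_points_per_epoch,
              sum(x$artifact_flags)))
  invisible(x)
}
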