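# Sleep-architecture metrics computed from the scored hypnogram: state
# percentages, latencies with end-of-recording censoring, symbolic
# Lempel-Ziv complexity of the state sequence, and transition-probability
# matrices. Artifact flags are ignored here: architecture is a property of
# the scoring, so every scored epoch counts.

#' Percentage of time spent in each state
#'
#' Number of epochs in each state divided by the total number of scored
#' epochs, times 100. All scored epochs are counted, including
#' artifact-flagged ones.
#'
#' @param hyp A [hypnogram()].
#' @return Named numeric vector (wake, drowsiness, nrem, rem) summing
#'   to 100.
#' @export
percent_time <- function(hyp) {
  if (length(hyp$states) == 0) stop("empty hypnogram")
  counts <- vapply(STATE_CODES, function(code) sum(hyp$states == code),
                   numeric(1))
  100 * counts / length(hyp$states)
}

#' Latency to first entry into a state, with censoring
#'
#' Time from recording start to the first epoch scored as `state`, in
#' minutes. If the state never occurs the latency is censored at
#' `total_min` (the full recording duration).
#'
#' @param hyp A [hypnogram()].
#' @param state State code (0-3) or name.
#' @param total_min Recording duration in minutes used for censoring.
#'   Defaults to the scored span of the hypnogram.
#' @return List with `latency_min` and logical `censored`.
#' @export
state_latency <- function(hyp, state,
                          total_min = length(hyp$states) *
                            hyp$epoch_length_s / 60) {
  if (total_min <= 0) stop("total_min must be positive")
  if (is.character(state)) state <- STATE_CODES[[state]]
  first <- which(hyp$states == state)
  if (length(first) == 0) {
    return(list(latency_min = total_min, censored = TRUE))
  }
  list(latency_min = (first[1] - 1) * hyp$epoch_length_s / 60,
       censored = FALSE)
}

#' Lempel-Ziv complexity of a symbol sequence
#'
#' The Kaspar-Schuster production complexity c(S): the number of phrases in
#' the exhaustive-history parse of the sequence. Applicable to any finite
#' alphabet; used here on the 4-symbol hypnogram sequence and on binarized
#' EEG. The raw count is reported (not a normalized rate); use
#' [lzc_signal()] for the normalized signal variant.
#'
#' @param seq Integer (or coercible) symbol sequence.
#' @return Integer phrase count, >= 1.
#' @export
lzc_sequence <- function(seq) {
  if (length(seq) == 0) stop("empty sequence")
  if (is.character(seq) && length(seq) == 1 && nchar(seq) > 1) {
    seq <- strsplit(seq, "")[[1]]
  }
  lzc_ks_cpp(as.integer(factor(seq)))
}

#' First-order transition matrix of a hypnogram
#'
#' Counts all consecutive epoch pairs and row-normalizes: entry (i, j) is
#' the estimated probability of being in state j at epoch t+1 given state i
#' at epoch t. Self-transitions (the diagonal) measure the probability of
#' remaining in a state. Rows for states never visited before the final
#' epoch are undefined (NaN probabilities, zero counts).
#'
#' @param hyp A [hypnogram()] with at least 2 epochs.
#' @return List with `counts` (4x4 integer) and `probs` (4x4, rows summing
#'   to 1 where defined), both with state-name dimnames.
#' @export
transition_matrix <- function(hyp) {
  s <- hyp$states
  if (length(s) < 2) stop("need at least 2 epochs")
  counts <- matrix(0L, 4, 4, dimnames = list(STATE_NAMES, STATE_NAMES))
  from <- s[-length(s)] + 1L
  to <- s[-1] + 1L
  for (k in seq_along(from)) {
    counts[from[k], to[k]] <- counts[from[k], to[k]] + 1L
  }
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs > 0, rs, NA_real_)
  list(counts = counts, probs = probs)
}

#' Architecture summary for one session
#'
#' Bundles the hypnogram-level metrics for one recording session: per-state
#' time percentages, per-state censored latencies, and the Lempel-Ziv
#' complexity of the full state sequence.
#'
#' @param hyp A [hypnogram()].
#' @param total_min Recording duration in minutes (for latency censoring).
#' @return List with `percent_time`, `latency_min`, `censored`,
#'   `hypnogram_lzc`, and `transitions`.
#' @export
architecture_summary <- function(hyp,
                                 total_min = length(hyp$states) *
                                   hyp$epoch_length_s / 60) {
  lat <- lapply(STATE_NAMES, function(nm) state_latency(hyp, nm, total_min))
  list(
    percent_time = percent_time(hyp),
    latency_min = vapply(lat, `[[`, numeric(1), "latency_min") |>
      stats::setNames(STATE_NAMES),
    censored = vapply(lat, `[[`, logical(1), "censored") |>
      stats::setNames(STATE_NAMES),
    hypnogram_lzc = lzc_sequence(hyp$states),
    transitions = if (length(hyp$states) >= 2) transition_matrix(hyp) else NULL
  )
}

#' Compare sleep architecture between two paired conditions
#'
#' Paired two-sided Wilcoxon signed-rank tests, per state, on time
#' percentages and (censored) latencies, plus the hypnogram Lempel-Ziv
#' complexity, and cell-wise paired tests on transition probabilities.
#' Transition cells undefined (unvisited state) in either member of a pair
#' drop that pair; cells with fewer than 2 usable pairs are reported with
#' NA p.
#'
#' @param summaries_a,summaries_b Named lists of [architecture_summary()]
#'   objects; names are subject ids, and subjects present in both lists
#'   form the pairs.
#' @return List with `metrics` (data.frame: metric, state, p, n_used,
#'   degenerate) and `transitions` (data.frame: from, to, p, n_used).
#' @export
compare_architecture <- function(summaries_a, summaries_b) {
  subjects <- intersect(names(summaries_a), names(summaries_b))
  if (length(subjects) < 2) stop("need at least 2 paired subjects")
  a <- summaries_a[subjects]
  b <- summaries_b[subjects]

  rows <- list()
  pull <- function(lst, field, nm) {
    vapply(lst, function(s) s[[field]][[nm]], numeric(1))
  }
  for (nm in STATE_NAMES) {
    for (field in c("percent_time", "latency_min")) {
      tr <- paired_wilcoxon(pull(a, field, nm), pull(b, field, nm))
      rows[[length(rows) + 1]] <- data.frame(
        metric = if (field == "percent_time") "percent_time" else "latency",
        state = nm, p = tr$p_value, n_used = tr$n_used,
        degenerate = tr$degenerate)
    }
  }
  tr <- paired_wilcoxon(vapply(a, `[[`, numeric(1), "hypnogram_lzc"),
                        vapply(b, `[[`, numeric(1), "hypnogram_lzc"))
  rows[[length(rows) + 1]] <- data.frame(
    metric = "hypnogram_lzc", state = NA_character_, p = tr$p_value,
    n_used = tr$n_used, degenerate = tr$degenerate)
  metrics <- do.call(rbind, rows)

  cells <- expand.grid(from = STATE_NAMES, to = STATE_NAMES,
                       stringsAsFactors = FALSE)
  trans_rows <- lapply(seq_len(nrow(cells)), function(k) {
    fr <- cells$from[k]; to <- cells$to[k]
    va <- vapply(a, function(s) s$transitions$probs[fr, to], numeric(1))
    vb <- vapply(b, function(s) s$transitions$probs[fr, to], numeric(1))
    keep <- !(is.na(va) | is.na(vb))
    if (sum(keep) < 2) {
      return(data.frame(from = fr, to = to, p = NA_real_,
                        n_used = sum(keep)))
    }
    t <- paired_wilcoxon(va[keep], vb[keep])
    data.frame(from = fr, to = to, p = t$p_value, n_used = t$n_used)
  })
  list(metrics = metrics, transitions = do.call(rbind, trans_rows))
}
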