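# Clean-epoch sampling and per-state epoch quality summaries.

#' Sample artifact-free epochs per state
#'
#' Draws `n` artifact-free epochs per state uniformly without replacement,
#' reproducibly from `seed`. States with fewer than `n` clean epochs
#' contribute all they have (the shortfall is reported via a message and in
#' the result); states with zero clean epochs are absent from the result,
#' which downstream comparisons treat as missing data (unpaired tests).
#'
#' @param epoch_sets Named list of epoch sets from [segment_epochs()].
#' @param n Number of epochs to draw per state (default 5).
#' @param seed Integer seed governing the draw.
#' @return Named list of epoch sets restricted to the sampled clean epochs.
#' @export
sample_clean_epochs <- function(epoch_sets, n = 5, seed = NULL) {
  if (!is.numeric(n) || n < 1) stop("n must be a positive integer")
  out <- list()
  for (nm in names(epoch_sets)) {
    es <- epoch_sets[[nm]]
    clean <- which(!es$artifact_flags)
    if (length(clean) == 0) {
      message("state ", nm, ": no clean epochs; state absent from sample")
      next
    }
    take <- if (length(clean) <= n) {
      if (length(clean) < n) {
        message(sprintf("state %s: only %d clean epochs available (wanted %d)",
                        nm, length(clean), n))
      }
      clean
    } else {
      sub_seed <- if (is.null(seed)) NULL else derive_seed(seed, nm)
      sort(with_seed(sub_seed, sample(clean, n)))
    }
    out[[nm]] <- epoch_set(es$state, es$epochs[take],
                           es$source_indices[take],
                           rep(FALSE, length(take)), seed = seed)
  }
  out
}

#' Per-state epoch quality summary
#'
#' Counts clean and artifact-flagged epochs per state and the percentage of
#' clean epochs, mirroring a scorer-facing retention table.
#'
#' @param hyp A [hypnogram()].
#' @return Data frame with columns `state`, `n_clean`, `n_noisy`,
#'   `percent_clean`; states never scored are omitted. Empty hypnogram
#'   yields an empty data frame.
#' @export
epoch_quality_summary <- function(hyp) {
  if (length(hyp$states) == 0) {
    return(data.frame(state = character(0), n_clean = integer(0),
                      n_noisy = integer(0), percent_clean = numeric(0)))
  }
  rows <- lapply(STATE_NAMES, function(nm) {
    sel <- hyp$states == STATE_CODES[[nm]]
    if (!any(sel)) return(NULL)
    noisy <- sum(hyp$artifact_flags[sel])
    clean <- sum(sel) - noisy
    data.frame(state = nm, n_clean = clean, n_noisy = noisy,
               percent_clean = 100 * clean / (clean + noisy))
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
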