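# Nonlinear signal metrics: median-binarized Lempel-Ziv complexity and
# Bandt-Pompe permutation entropy, computed on low- and high-frequency
# components of each epoch and averaged over epochs and channels.

#' Median-binarize a signal
#'
#' 1 where the sample exceeds the signal's median, 0 otherwise (ties map
#' to 0, so a constant signal becomes the all-zero sequence).
#'
#' @param x Numeric sample series.
#' @return Integer 0/1 vector of the same length.
#' @export
binarize_median <- function(x) {
  if (length(x) == 0) stop("empty signal")
  as.integer(x > median(x))
}

#' Lempel-Ziv complexity of a continuous signal
#'
#' Median-binarizes the signal ([binarize_median()]) and applies the
#' Kaspar-Schuster parser ([lzc_sequence()]). With `normalized = TRUE`
#' (default) the count c(n) is scaled to the rate `c(n) * log2(n) / n`,
#' which is comparable across equal-length epochs and tends to 1 for
#' incompressible binary sequences.
#'
#' @param x Numeric sample series, length >= 2.
#' @param normalized Return the normalized rate instead of the raw count.
#' @return Numeric scalar.
#' @export
lzc_signal <- function(x, normalized = TRUE) {
  if (length(x) < 2) stop("need at least 2 samples")
  b <- binarize_median(x)
  cn <- lzc_ks_cpp(b)
  if (normalized) cn * log2(length(b)) / length(b) else as.numeric(cn)
}

# Ordinal pattern codes for windows of length D at lag tau. Ranks use
# stable tie-breaking (ties.method = "first"): equal values keep their
# order of occurrence. Vectorized over windows via pairwise comparisons.
ordinal_pattern_codes <- function(x, D, tau) {
  n <- length(x) - (D - 1) * tau
  if (n < 1) stop("series too short for the embedding (need length >= D*tau)")
  W <- vapply(seq_len(D), function(j) x[(1:n) + (j - 1) * tau],
              numeric(n))
  W <- matrix(W, nrow = n)
  # rank (ties "first") of column i: 1 + #{j<i: w_j <= w_i} + #{j>i: w_j < w_i}
  ranks <- matrix(1L, n, D)
  for (i in seq_len(D)) {
    for (j in seq_len(D)) {
      if (j == i) next
      if (j < i) ranks[, i] <- ranks[, i] + (W[, j] <= W[, i])
      else ranks[, i] <- ranks[, i] + (W[, j] < W[, i])
    }
  }
  # integer code of the rank vector (base D+1 positional encoding)
  code <- rep(0, n)
  for (i in seq_len(D)) code <- code * (D + 1) + ranks[, i]
  code
}

#' Bandt-Pompe permutation entropy
#'
#' Shannon entropy (bits) of the distribution of ordinal patterns of
#' embedding dimension `D` at delay `tau`. Equal values within a window
#' are ranked by order of occurrence (stable tie-breaking). With
#' `normalized = TRUE` the entropy is divided by `log2(D!)`, mapping it
#' to \[0, 1\].
#'
#' @param x Numeric sample series, length >= `(D-1)*tau + 1`.
#' @param D Embedding dimension (>= 2; default 4).
#' @param tau Embedding delay in samples (>= 1; default 1).
#' @param normalized Normalize by `log2(D!)`.
#' @return Numeric scalar; 0 for a strictly monotone series.
#' @export
permutation_entropy <- function(x, D = 4, tau = 1, normalized = TRUE) {
  if (D < 2) stop("D must be >= 2")
  if (tau < 1) stop("tau must be >= 1")
  codes <- ordinal_pattern_codes(x, D, tau)
  p <- tabulate(factor(codes))
  p <- p / sum(p)
  H <- -sum(p * log2(p))
  if (normalized) H / log2(factorial(D)) else H
}

#' Frequency-band presets for the nonlinear metrics
#'
#' Low \[1, 16\] Hz and high \[17, 50\] Hz by default; the alternative
#' high band \[16, 45\] Hz used in some displays is available as
#' `band_split("alt")`.
#'
#' @param preset `"default"` or `"alt"`.
#' @return List with `low` and `high` band edges (Hz).
#' @export
band_split <- function(preset = c("default", "alt")) {
  preset <- match.arg(preset)
  if (preset == "default") list(low = c(1, 16), high = c(17, 50))
  else list(low = c(1, 16), high = c(16, 45))
}

#' Band-resolved complexity and entropy of an epoch set
#'
#' Filters each epoch into the low and high band ([band_split()]),
#' computes normalized Lempel-Ziv complexity and permutation entropy per
#' epoch per channel, and averages over epochs and channels, yielding one
#' value per band x metric for the epoch set (one subject x state).
#'
#' @param es Epoch set or list of samples x channels matrices.
#' @param fs Sampling rate (Hz).
#' @param split Band definition from [band_split()].
#' @param D,tau Permutation-entropy embedding parameters.
#' @param normalized Use normalized LZC and PE (default) or raw values.
#' @return Data frame with columns `band`, `metric`, `value`.
#' @export
band_metrics <- function(es, fs, split = band_split(), D = 4, tau = 1,
                         normalized = TRUE) {
  epochs <- if (inherits(es, "epoch_set")) es$epochs else es
  if (length(epochs) == 0) stop("empty epoch set")
  out <- list()
  for (bnm in c("low", "high")) {
    band <- split[[bnm]]
    lzc_vals <- c(); pe_vals <- c()
    for (ep in epochs) {
      ep <- as.matrix(ep)
      for (ch in seq_len(ncol(ep))) {
        f <- bandpass(ep[, ch], fs, band[1], band[2])
        lzc_vals <- c(lzc_vals, lzc_signal(f, normalized = normalized))
        pe_vals <- c(pe_vals, permutation_entropy(f, D, tau,
                                                  normalized = normalized))
      }
    }
    out[[length(out) + 1]] <- data.frame(
      band = bnm, metric = c("lzc", "pe"),
      value = c(mean(lzc_vals), mean(pe_vals)))
  }
  do.call(rbind, out)
}

#' Pairwise state comparison of a nonlinear metric within one condition
#'
#' Kruskal-Wallis omnibus across sleep states, followed by Dunn's pairwise
#' post-hoc z-tests (Holm-adjusted by default), on per-subject metric
#' values. States absent for a subject are simply missing (no imputation).
#'
#' @param df Data frame with columns `state` and `value` (one row per
#'   subject x state).
#' @param p_adjust Dunn adjustment method, see [kruskal_dunn()].
#' @return The [kruskal_dunn()] result.
#' @export
state_comparison <- function(df, p_adjust = "holm") {
  if (!all(c("state", "value") %in% names(df))) {
    stop("df must have 'state' and 'value' columns")
  }
  kruskal_dunn(df$value, df$state, p_adjust = p_adjust)
}
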