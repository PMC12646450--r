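# Welch spectral estimation: one engine (Hann window, 800 ms segments, 50%
# overlap by default) for both relative PSD and magnitude-squared
# coherence, giving a 1.25 Hz frequency grid on 3-s epochs at 400 Hz.

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

welch_segments <- function(n, nperseg, noverlap) {
  step <- nperseg - noverlap
  if (n < nperseg) stop("signal shorter than the Welch window")
  starts <- seq(1, n - nperseg + 1, by = step)
  starts
}

# Per-segment FFTs of a (possibly multichannel) series; returns a list of
# complex matrices (freq x segment) per channel, plus freq grid and the
# density scaling factor.
welch_fft <- function(x, fs, window_s, overlap) {
  x <- as.matrix(x)
  nperseg <- as.integer(round(window_s * fs))
  noverlap <- as.integer(floor(nperseg * overlap))
  starts <- welch_segments(nrow(x), nperseg, noverlap)
  w <- hann_window(nperseg)
  nfreq <- nperseg %/% 2 + 1
  specs <- lapply(seq_len(ncol(x)), function(ch) {
    seg <- vapply(starts, function(s0) {
      seg <- x[s0:(s0 + nperseg - 1), ch]
      seg <- (seg - mean(seg)) * w
      fft(seg)[seq_len(nfreq)]
    }, complex(nfreq))
    matrix(seg, nrow = nfreq)
  })
  # one-sided density scaling: 2 / (fs * sum(w^2)), no doubling at DC/Nyquist
  scale <- 2 / (fs * sum(w^2))
  list(specs = specs, freq = (seq_len(nfreq) - 1) * fs / nperseg,
       scale = scale, nperseg = nperseg)
}

#' Welch power spectral density
#'
#' One-sided PSD by Welch's method: Hann-windowed, mean-detrended segments
#' (default 800 ms, 50% overlap), periodograms averaged across segments.
#' Density scaling, so the PSD integrates to the signal variance.
#'
#' @param x Numeric sample series.
#' @param fs Sampling rate (Hz).
#' @param window_s Segment length in seconds (default 0.8).
#' @param overlap Fractional segment overlap (default 0.5).
#' @return List with `freq` (Hz) and `psd` (power / Hz).
#' @export
welch_psd <- function(x, fs, window_s = 0.8, overlap = 0.5) {
  wf <- welch_fft(x, fs, window_s, overlap)
  S <- wf$specs[[1]]
  p <- rowMeans(Mod(S)^2) * wf$scale
  p[1] <- p[1] / 2
  if (wf$nperseg %% 2 == 0) p[length(p)] <- p[length(p)] / 2
  list(freq = wf$freq, psd = p)
}

#' Magnitude-squared coherence between two signals
#'
#' Welch cross-spectral estimate with the same windowing as [welch_psd()]:
#' `coh(f) = |<Sxy>|^2 / (<Sxx><Syy>)`, averaged over segments.
#'
#' @param x,y Equal-length sample series.
#' @inheritParams welch_psd
#' @return List with `freq` and `coh` in \[0, 1\].
#' @export
welch_coherence <- function(x, y, fs, window_s = 0.8, overlap = 0.5) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  wf <- welch_fft(cbind(x, y), fs, window_s, overlap)
  Sx <- wf$specs[[1]]; Sy <- wf$specs[[2]]
  pxx <- rowMeans(Mod(Sx)^2)
  pyy <- rowMeans(Mod(Sy)^2)
  pxy <- rowMeans(Sx * Conj(Sy))
  coh <- Mod(pxy)^2 / (pxx * pyy)
  coh[!is.finite(coh)] <- 0
  list(freq = wf$freq, coh = pmin(coh, 1))
}

#' Relative power spectral density of an epoch set
#'
#' Welch PSD per epoch per channel, averaged across the set's epochs, then
#' normalized per channel by the summed power over the normalization band
#' (default \[1, 50\] Hz), so that the reported bins sum to 1. The relative
#' spectrum is invariant under global amplitude scaling, removing
#' inter-individual amplitude differences (skull thickness, electrode
#' contact).
#'
#' @param es An epoch set (see [segment_epochs()]), or a list of
#'   samples x channels matrices.
#' @param fs Sampling rate (Hz).
#' @param norm_band Normalization band `c(low, high)` in Hz.
#' @inheritParams welch_psd
#' @return List with `freq` (bins inside `norm_band`), `rpsd`
#'   (freq x channels, columns summing to 1), and `channel_mean`.
#' @export
rpsd <- function(es, fs, norm_band = c(1, 50), window_s = 0.8,
                 overlap = 0.5) {
  epochs <- if (inherits(es, "epoch_set")) es$epochs else es
  if (length(epochs) == 0) stop("empty epoch set")
  nch <- ncol(as.matrix(epochs[[1]]))
  acc <- NULL
  for (ep in epochs) {
    ep <- as.matrix(ep)
    for (ch in seq_len(nch)) {
      w <- welch_psd(ep[, ch], fs, window_s, overlap)
      if (is.null(acc)) {
        acc <- matrix(0, length(w$freq), nch)
        freq <- w$freq
      }
      acc[, ch] <- acc[, ch] + w$psd
    }
  }
  acc <- acc / length(epochs)
  keep <- freq >= norm_band[1] & freq <= norm_band[2]
  r <- acc[keep, , drop = FALSE]
  r <- sweep(r, 2, colSums(r), "/")
  list(freq = freq[keep], rpsd = r, channel_mean = rowMeans(r))
}

# Shared per-frequency-bin comparison used by rPSD and coherence: `a` and
# `b` are subjects x freq matrices.
compare_spectra <- function(a, b, freq, paired, alpha, p_adjust = "none") {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) stop("frequency grids differ between groups")
  if (nrow(a) < 2 || nrow(b) < 2) {
    stop("need at least 2 subjects per group")
  }
  if (paired && nrow(a) != nrow(b)) {
    stop("paired comparison requires equal group sizes")
  }
  p <- vapply(seq_len(ncol(a)), function(j) {
    if (paired) paired_wilcoxon(a[, j], b[, j])$p_value
    else mann_whitney(a[, j], b[, j])$p_value
  }, numeric(1))
  p_eff <- if (p_adjust == "none") p else p.adjust(p, method = p_adjust)
  sig <- p_eff < alpha
  df <- data.frame(freq = freq, p = p, p_adjusted = p_eff,
                   significant = sig)
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  bands <- data.frame(
    low_hz = freq[starts[runs$values]],
    high_hz = freq[ends[runs$values]]
  )
  list(per_bin = df, significant_bands = bands,
       method = if (paired) "Wilcoxon signed-rank" else "Mann-Whitney U",
       alpha = alpha)
}

#' Compare relative PSD between two groups, per frequency bin
#'
#' Per-bin two-sided tests on (typically channel-averaged) relative power:
#' paired Wilcoxon when `paired = TRUE`, Mann-Whitney otherwise. No
#' multiplicity correction across bins by default, matching the raw
#' shading convention of per-bin displays; set `p_adjust = "BH"` for a
#' false-discovery-rate-corrected mask.
#'
#' @param group_a,group_b Subjects x frequency matrices of relative power
#'   (e.g. the `channel_mean` of [rpsd()] stacked across subjects).
#' @param freq Common frequency grid (Hz).
#' @param paired Use the paired test?
#' @param alpha Significance level for the mask (default 0.01).
#' @param p_adjust Adjustment method across bins (default `"none"`).
#' @return List with `per_bin` (freq, p, significant), and
#'   `significant_bands` (contiguous significant bins as frequency bands).
#' @export
compare_rpsd <- function(group_a, group_b, freq, paired = TRUE,
                         alpha = 0.01, p_adjust = "none") {
  compare_spectra(group_a, group_b, freq, paired, alpha, p_adjust)
}

#' Coherence spectrum of a channel pair over an epoch set
#'
#' Magnitude-squared coherence per epoch via [welch_coherence()], averaged
#' across the set's epochs, reported on the analysis band (default
#' \[1, 50\] Hz).
#'
#' @param es Epoch set or list of samples x channels matrices.
#' @param fs Sampling rate (Hz).
#' @param pair Integer or character vector of length 2 naming the two
#'   channels.
#' @param band Reported frequency range in Hz.
#' @inheritParams welch_psd
#' @return List with `freq` and `coh`.
#' @export
coherence_pair <- function(es, fs, pair, band = c(1, 50), window_s = 0.8,
                           overlap = 0.5) {
  epochs <- if (inherits(es, "epoch_set")) es$epochs else es
  if (length(epochs) == 0) stop("empty epoch set")
  acc <- NULL
  for (ep in epochs) {
    ep <- as.matrix(ep)
    wc <- welch_coherence(ep[, pair[1]], ep[, pair[2]], fs, window_s,
                          overlap)
    if (is.null(acc)) { acc <- wc$coh; freq <- wc$freq }
    else acc <- acc + wc$coh
  }
  acc <- acc / length(epochs)
  keep <- freq >= band[1] & freq <= band[2]
  list(freq = freq[keep], coh = acc[keep])
}

#' Compare coherence spectra between two groups, per frequency bin
#'
#' Same procedure as [compare_rpsd()] but with the connectivity-stage
#' default significance level of 0.05.
#'
#' @inheritParams compare_rpsd
#' @export
compare_coherence <- function(group_a, group_b, freq, paired = TRUE,
                              alpha = 0.05, p_adjust = "none") {
  compare_spectra(group_a, group_b, freq, paired, alpha, p_adjust)
}
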