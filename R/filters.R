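# Zero-phase filtering. Filters are designed with signal::butter and
# applied forward-backward (compiled IIR passes over an odd-reflection
# padded signal), so the effective magnitude response is squared and the
# net phase shift is zero — a prerequisite for the Hilbert-phase
# connectivity stage.

# forward-backward application with odd-reflection padding; pad length
# covers the slowest transient we filter for (1 Hz edge at 400 Hz)
zero_phase <- function(b, a, x, pad = 3000L) {
  as.numeric(filtfilt_cpp(as.numeric(b), as.numeric(a), as.numeric(x),
                          as.integer(pad)))
}

check_edges <- function(fs, ...) {
  edges <- c(...)
  if (any(edges <= 0)) stop("filter edges must be positive")
  if (any(edges >= fs / 2)) {
    stop(sprintf("filter edge (%g Hz) at or above Nyquist (%g Hz)",
                 max(edges), fs / 2))
  }
}

#' Zero-phase Butterworth bandpass
#'
#' 4th-order Butterworth applied forward-backward (8th-order effective,
#' zero net phase shift).
#'
#' @param x Numeric sample series.
#' @param fs Sampling rate (Hz).
#' @param low,high Passband edges (Hz); `0 < low < high < fs/2`.
#' @return Filtered series, same length as `x`.
#' @export
bandpass <- function(x, fs, low = 1, high = 70) {
  check_edges(fs, low, high)
  if (low >= high) stop("low edge must be below high edge")
  bt <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  zero_phase(bt$b, bt$a, x)
}

#' Zero-phase IIR notch filter
#'
#' Biquad notch (quality factor `q`, default 30) applied forward-backward,
#' for power-line removal.
#'
#' @inheritParams bandpass
#' @param freq Notch center frequency (Hz), default 60.
#' @param q Quality factor; bandwidth is `freq / q`.
#' @return Filtered series, same length as `x`.
#' @export
notch_filter <- function(x, fs, freq = 60, q = 30) {
  check_edges(fs, freq)
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  zero_phase(b / a[1], a / a[1], x)
}

#' Narrowband filter presets for phase-based connectivity
#'
#' The five 2-Hz-wide physiological bands used for the phase lag index:
#' delta \[2,4\], theta \[5,7\], alpha \[9,11\], beta \[19,21\], gamma
#' \[34,36\] Hz.
#'
#' @return Named list of `c(low, high)` band edges in Hz.
#' @export
pli_bands <- function() {
  list(delta = c(2, 4), theta = c(5, 7), alpha = c(9, 11),
       beta = c(19, 21), gamma = c(34, 36))
}

#' Zero-phase narrowband filter
#'
#' Same machinery as [bandpass()], intended for the narrow phase-analysis
#' bands of [pli_bands()].
#'
#' @inheritParams bandpass
#' @param band Numeric `c(low, high)` in Hz, or the name of a
#'   [pli_bands()] preset.
#' @return Filtered series, same length as `x`.
#' @export
narrowband <- function(x, fs, band) {
  if (is.character(band)) {
    presets <- pli_bands()
    if (!band %in% names(presets)) {
      stop("unknown band preset '", band, "'")
    }
    band <- presets[[band]]
  }
  bandpass(x, fs, band[1], band[2])
}

# Filter every channel of a samples-x-channels matrix.
filter_channels <- function(mat, fun, ...) {
  out <- mat
  for (j in seq_len(ncol(mat))) out[, j] <- fun(mat[, j], ...)
  out
}

#' Standard continuous-record preprocessing
#'
#' Bandpass (default \[1,70\] Hz) plus notch (default 60 Hz) on every
#' channel of a recording, applied to the continuous signal before
#' epoching.
#'
#' @param rec A [session_recording()].
#' @param band Bandpass edges in Hz.
#' @param notch Notch frequency in Hz, or `NULL` to skip.
#' @return The recording with filtered signals.
#' @export
preprocess_recording <- function(rec, band = c(1, 70), notch = 60) {
  sig <- filter_channels(rec$signals, bandpass, fs = rec$fs,
                         low = band[1], high = band[2])
  if (!is.null(notch)) {
    sig <- filter_channels(sig, notch_filter, fs = rec$fs, freq = notch)
  }
  rec$signals <- sig
  rec
}
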