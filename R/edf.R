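# Minimal EDF (European Data Format) reader/writer: 16-bit samples, standard
# 256-byte header plus one 256-byte block per signal, 1-second data records.
# Only the features needed for multichannel EEG interchange are supported.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

num_field <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7)
  if (nchar(s) > width) s <- substr(s, 1, width)
  pad_field(s, width)
}

#' Write a multichannel recording to an EDF file
#'
#' Writes 16-bit EDF with 1-second data records. Each channel is scaled to
#' its own physical range, so the quantization step per channel is
#' `(max - min) / 65535`. Trailing samples that do not fill a whole
#' 1-second record are dropped with a warning.
#'
#' @param path Output file path.
#' @param signals Numeric matrix, samples x channels (microvolts), or a list
#'   of equal-length numeric vectors.
#' @param fs Sampling rate in Hz (samples per data record).
#' @param channel_labels Character vector of channel labels.
#' @param patient_id,recording_id Free-text header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, signals, fs, channel_labels,
                      patient_id = "X", recording_id = "X") {
  if (is.list(signals) && !is.matrix(signals)) {
    signals <- do.call(cbind, signals)
  }
  signals <- as.matrix(signals)
  ns <- ncol(signals)
  stopifnot(length(channel_labels) == ns, fs > 0)
  spr <- as.integer(round(fs))
  n_rec <- nrow(signals) %/% spr
  if (n_rec * spr != nrow(signals)) {
    warning(sprintf("dropping %d trailing samples (partial EDF record)",
                    nrow(signals) - n_rec * spr))
  }
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  signals <- signals[seq_len(n_rec * spr), , drop = FALSE]

  phys_max <- vapply(seq_len(ns), function(j) {
    m <- max(abs(signals[, j]))
    if (m == 0) 1 else signif(m * 1.0001, 7)
  }, numeric(1))
  phys_min <- -phys_max
  dig_max <- 32767L
  dig_min <- -32768L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(patient_id, 80),
    pad_field(recording_id, 80),
    pad_field("01.01.00", 8),
    pad_field("12.00.00", 8),
    pad_field(256 * (ns + 1), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field("1", 8),
    pad_field(ns, 4)
  )
  sig_hdr <- paste0(
    paste(vapply(channel_labels, pad_field, "", width = 16), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field("uV", 8), ns), collapse = ""),
    paste(vapply(phys_min, num_field, "", width = 8), collapse = ""),
    paste(vapply(phys_max, num_field, "", width = 8), collapse = ""),
    paste(rep(num_field(dig_min, 8), ns), collapse = ""),
    paste(rep(num_field(dig_max, 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(num_field(spr, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = "")
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)

  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  dig <- matrix(0L, nrow(signals), ns)
  for (j in seq_len(ns)) {
    d <- round((signals[, j] - phys_min[j]) * scale[j]) + dig_min
    dig[, j] <- as.integer(pmin(pmax(d, dig_min), dig_max))
  }
  # record-interleaved layout: all samples of channel 1 for record r, then
  # channel 2, ...
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    writeBin(as.vector(dig[idx, ]), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(w) readChar(con, w, useBytes = TRUE)
  h <- list(
    version = trimws(rd(8)), patient = trimws(rd(80)),
    recording = trimws(rd(80)), startdate = rd(8), starttime = rd(8),
    header_bytes = as.integer(rd(8)), reserved = rd(44),
    n_records = as.integer(rd(8)), record_duration = as.numeric(rd(8)),
    ns = as.integer(rd(4))
  )
  ns <- h$ns
  fld <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  h$labels <- fld(16)
  fld(80)                      # transducer
  h$phys_dim <- fld(8)
  h$phys_min <- as.numeric(fld(8))
  h$phys_max <- as.numeric(fld(8))
  h$dig_min <- as.numeric(fld(8))
  h$dig_max <- as.numeric(fld(8))
  fld(80)                      # prefiltering
  h$spr <- as.integer(fld(8))
  fld(32)                      # reserved
  h
}

#' Read an EDF file
#'
#' Reads a 16-bit EDF file in which all signals share the same sampling
#' rate (the layout [write_edf()] produces).
#'
#' @param path Path to the EDF file.
#' @return List with `signals` (samples x channels matrix, physical units),
#'   `fs`, `channel_labels`, and `header`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  if (length(unique(h$spr)) != 1) {
    stop("mixed per-signal sampling rates are not supported")
  }
  spr <- h$spr[1]
  fs <- spr / h$record_duration
  ns <- h$ns
  n <- h$n_records * spr
  raw <- readBin(con, "integer", n = n * ns, size = 2, signed = TRUE,
                 endian = "little")
  if (length(raw) < n * ns) stop("EDF file truncated: ", path)
  sig <- matrix(0, n, ns)
  scale <- (h$phys_max - h$phys_min) / (h$dig_max - h$dig_min)
  for (r in seq_len(h$n_records)) {
    block <- raw[((r - 1) * spr * ns + 1):(r * spr * ns)]
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (j in seq_len(ns)) {
      d <- block[((j - 1) * spr + 1):(j * spr)]
      sig[idx, j] <- (d - h$dig_min[j]) * scale[j] + h$phys_min[j]
    }
  }
  colnames(sig) <- h$labels
  list(signals = sig, fs = fs, channel_labels = h$labels, header = h)
}
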