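#' @useDynLib sleepeeg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft kruskal.test ks.test mad median p.adjust pnorm runif
#'   rnorm sd var wilcox.test
#' @importFrom utils read.delim write.table head tail
NULL

# Canonical sleep-state coding used throughout: wake -> 0, drowsiness -> 1,
# NREM -> 2, REM -> 3.
STATE_CODES <- c(wake = 0L, drowsiness = 1L, nrem = 2L, rem = 3L)
STATE_NAMES <- names(STATE_CODES)

#' Sleep-state codes
#'
#' The fixed mapping between state labels and integer codes used by every
#' function in the package: wake = 0, drowsiness = 1, NREM = 2, REM = 3.
#'
#' @return Named integer vector of the four state codes.
#' @export
state_codes <- function() STATE_CODES

state_name <- function(code) STATE_NAMES[match(code, STATE_CODES)]

# Accepts the label spellings a human scorer is likely to write.
normalize_state_label <- function(x) {
  key <- tolower(trimws(x))
  map <- c(
    w = "wake", wake = "wake", wakefulness = "wake",
    d = "drowsiness", drow = "drowsiness", drowsiness = "drowsiness",
    nrem = "nrem", rem = "rem"
  )
  out <- unname(map[key])
  out
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. A NULL seed leaves the RNG stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Deterministic sub-stream seed derived from a master seed and string keys
# (e.g. subject id, condition). Kept below 2^31 - 1.
derive_seed <- function(seed, ...) {
  keys <- paste(c(...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(keys)) h <- (h * 31 + v) %% 2147483647
  as.integer((seed + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
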