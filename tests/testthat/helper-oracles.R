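# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check: string-search parsing for the
# Lempel-Ziv complexity, explicit window enumeration for permutation
# entropy, an explicit time loop for the PLI, and exhaustive
# permutation/sign-flip enumeration for the rank tests.

# Exhaustive-history Lempel-Ziv parse: each phrase is the shortest prefix
# of the remaining suffix that is not a substring of everything before its
# last character; a trailing reproducible phrase still counts.
lzc_oracle <- function(sym) {
  st <- paste(sym, collapse = "")
  n <- nchar(st)
  pos <- 1
  cnt <- 0
  while (pos <= n) {
    k <- 1
    while (TRUE) {
      if (pos + k - 1 > n) break
      word <- substr(st, pos, pos + k - 1)
      hist <- substr(st, 1, pos + k - 2)
      if (!grepl(word, hist, fixed = TRUE)) break
      k <- k + 1
    }
    cnt <- cnt + 1
    pos <- pos + k
  }
  cnt
}

# Direct enumeration of ordinal patterns and their Shannon entropy.
pe_oracle <- function(x, D, tau, normalized = TRUE) {
  n_win <- length(x) - (D - 1) * tau
  stopifnot(n_win >= 1)
  pats <- vapply(seq_len(n_win), function(i) {
    w <- x[i + (0:(D - 1)) * tau]
    paste(rank(w, ties.method = "first"), collapse = "-")
  }, "")
  p <- as.numeric(table(pats)) / n_win
  H <- -sum(p * log2(p))
  if (normalized) H / log2(factorial(D)) else H
}

# Explicit per-sample loop with explicit angle wrapping to (-pi, pi].
pli_oracle <- function(px, py) {
  s <- 0
  for (t in seq_along(px)) {
    d <- px[t] - py[t]
    while (d <= -pi) d <- d + 2 * pi
    while (d > pi) d <- d - 2 * pi
    s <- s + sign(d)
  }
  abs(s / length(px))
}

# Exact two-sided paired Wilcoxon p by sign-flip enumeration (no ties, no
# zero differences assumed).
wilcoxon_exact_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  p <- min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
  list(statistic = w_obs, p = p)
}

# Exact two-sided Mann-Whitney p by enumeration of all rank assignments.
mann_whitney_exact_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  sets <- utils::combn(n + m, n)
  all_r <- rank(seq_len(n + m))
  us <- apply(sets, 2, function(idx) sum(all_r[idx]) - n * (n + 1) / 2)
  p <- min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  list(statistic = u_obs, p = p)
}

# Random symbol sequences over an alphabet.
random_symbols <- function(n, alphabet) {
  sample(alphabet, n, replace = TRUE)
}

# Small helper: all binary strings of length 1..max_len as integer vectors.
all_binary_strings <- function(max_len) {
  out <- list()
  for (len in seq_len(max_len)) {
    g <- as.matrix(expand.grid(rep(list(0:1), len)))
    for (i in seq_len(nrow(g))) out[[length(out) + 1]] <- unname(g[i, ])
  }
  out
}

# A tiny deterministic multichannel epoch list for spectral/connectivity
# unit tests.
noise_epochs <- function(n_epochs = 5, n = 1200, nch = 4, seed = 1,
                         labels = c("F3", "F4", "Fz", "Cz")) {
  set.seed(seed)
  lapply(seq_len(n_epochs), function(i) {
    m <- matrix(rnorm(n * nch), n, nch)
    colnames(m) <- labels[seq_len(nch)]
    m
  })
}
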