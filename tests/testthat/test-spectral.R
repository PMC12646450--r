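# Welch spectra: relative PSD, coherence, and the per-bin group tests.

test_that("Welch PSD satisfies a Parseval-style power balance", {
  set.seed(2)
  x <- rnorm(48000)
  w <- welch_psd(x, 400)
  total <- sum(w$psd) * (w$freq[2] - w$freq[1])
  expect_lt(abs(total - var(x)) / var(x), 0.10)
})

test_that("rPSD concentrates on a pure tone and normalizes to 1", {
  fs <- 400
  t <- (0:1199) / fs
  eps <- lapply(1:5, function(i) {
    matrix(sin(2 * pi * 10 * t + i), ncol = 1, dimnames = list(NULL, "Fz"))
  })
  r <- rpsd(eps, fs)
  expect_equal(sum(r$rpsd[, 1]), 1)
  # bins sit on a 1.25 Hz grid; count every bin overlapping 10 +/- 1 Hz
  df <- r$freq[2] - r$freq[1]
  in_peak <- abs(r$freq - 10) <= 1 + df / 2
  expect_gt(sum(r$rpsd[in_peak, 1]), 0.80)
})

test_that("rPSD of white noise is flat and scale-invariant", {
  fs <- 400
  eps <- noise_epochs(100, 1200, 1, seed = 12, labels = "Fz")
  r <- rpsd(eps, fs)
  mid <- r$freq >= 5 & r$freq <= 45
  expect_lt(max(r$channel_mean[mid]) / min(r$channel_mean[mid]), 3)
  scaled <- lapply(eps, function(e) 37.5 * e)
  expect_equal(rpsd(scaled, fs)$rpsd, r$rpsd, tolerance = 1e-12)
  expect_error(rpsd(list(), fs), "empty")
})

test_that("per-bin comparison finds nothing when the groups are identical", {
  set.seed(8)
  g <- matrix(runif(6 * 40), 6, 40)
  out <- compare_rpsd(g, g, freq = seq_len(40), paired = TRUE)
  expect_false(any(out$per_bin$significant))
  expect_equal(nrow(out$significant_bands), 0)
  expect_error(compare_rpsd(g[1, , drop = FALSE], g[1, , drop = FALSE],
                            seq_len(40)), "at least 2")
  expect_error(compare_rpsd(g, g[, 1:10], seq_len(40)), "grids differ")
})

test_that("per-bin comparison flags a known high-band power shift", {
  set.seed(99)
  freq <- seq(1.25, 50, by = 1.25)
  hi <- freq > 13
  hits_hi <- 0; hits_lo <- 0
  for (r in 1:10) {
    base <- exp(stats::rnorm(12, 0, 0.15))
    a <- outer(base * exp(rnorm(12, 0, 0.05)), rep(1, length(freq)))
    b <- outer(base * exp(rnorm(12, 0, 0.05)), rep(1, length(freq)))
    b[, hi] <- b[, hi] * 1.5
    a <- a * matrix(exp(rnorm(length(a), 0, 0.05)), nrow = 12)
    b <- b * matrix(exp(rnorm(length(b), 0, 0.05)), nrow = 12)
    out <- compare_rpsd(a, b, freq, paired = FALSE, alpha = 0.01)
    hits_hi <- hits_hi + (mean(out$per_bin$significant[hi]) >= 0.5)
    hits_lo <- hits_lo + any(out$per_bin$significant[freq >= 3 & freq <= 8])
  }
  expect_gte(hits_hi, 8)
  expect_lte(hits_lo, 2)
})

test_that("coherence is 1 for identical signals and low for independent noise", {
  fs <- 400
  eps <- noise_epochs(3, 1200, 2, seed = 4, labels = c("F3", "F4"))
  dup <- lapply(eps, function(e) cbind(F3 = e[, 1], F4 = e[, 1]))
  co <- coherence_pair(dup, fs, c("F3", "F4"))
  expect_equal(co$coh, rep(1, length(co$coh)), tolerance = 1e-9)
  # long independent records -> >100 Welch segments, low mean coherence
  set.seed(41)
  long <- list(matrix(rnorm(40000 * 2), ncol = 2,
                      dimnames = list(NULL, c("F3", "F4"))))
  co2 <- coherence_pair(long, fs, c("F3", "F4"))
  expect_lt(mean(co2$coh), 0.2)
  expect_true(all(co2$coh >= 0 & co2$coh <= 1))
})

test_that("a shared tone raises coherence at its frequency only", {
  fs <- 400
  t <- (0:39999) / fs
  set.seed(10)
  common <- sin(2 * pi * 10 * t)
  m <- cbind(F3 = common + rnorm(length(t)), Fz = common + rnorm(length(t)))
  co <- coherence_pair(list(m), fs, c("F3", "Fz"))
  at10 <- co$coh[which.min(abs(co$freq - 10))]
  away <- mean(co$coh[co$freq >= 20 & co$freq <= 45])
  expect_gt(at10, away)
})

test_that("coherence is symmetric in the pair and respects windowing limits", {
  fs <- 400
  eps <- noise_epochs(2, 1200, 2, seed = 6, labels = c("F3", "F4"))
  a <- coherence_pair(eps, fs, c("F3", "F4"))
  b <- coherence_pair(eps, fs, c("F4", "F3"))
  expect_equal(a$coh, b$coh, tolerance = 1e-12)
  short <- list(matrix(rnorm(100 * 2), ncol = 2,
                       dimnames = list(NULL, c("F3", "F4"))))
  expect_error(coherence_pair(short, fs, c("F3", "F4")), "shorter")
})

test_that("unpaired comparison runs with unequal group sizes", {
  set.seed(13)
  freq <- seq(1.25, 50, by = 1.25)
  a <- matrix(runif(12 * length(freq)), 12)
  b <- matrix(runif(5 * length(freq)), 5)
  out <- compare_coherence(a, b, freq, paired = FALSE)
  expect_equal(out$method, "Mann-Whitney U")
  expect_equal(nrow(out$per_bin), length(freq))
})
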