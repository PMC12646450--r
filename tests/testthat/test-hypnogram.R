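# Sleep-architecture metrics: percentages, censored latencies, symbolic
# Lempel-Ziv complexity, transition matrices, and the paired comparison.

test_that("percent_time counts every scored epoch", {
  hyp <- hypnogram(c(rep(0, 4), rep(2, 6)), c(rep(TRUE, 4), rep(FALSE, 6)))
  p <- percent_time(hyp)
  expect_equal(unname(p), c(40, 0, 60, 0))
  expect_equal(sum(p), 100)
  expect_equal(unname(percent_time(hypnogram(rep(3, 8)))), c(0, 0, 0, 100))
  p3 <- percent_time(hypnogram(c(0, 1, 2)))
  expect_equal(unname(p3), c(100 / 3, 100 / 3, 100 / 3, 0))
  expect_error(percent_time(hypnogram(integer(0), logical(0))), "empty")
})

test_that("latency censors at total duration when the state never occurs", {
  hyp <- hypnogram(rep(2, 40))
  lat <- state_latency(hyp, "rem", total_min = 120)
  expect_equal(lat$latency_min, 120)
  expect_true(lat$censored)
  lat0 <- state_latency(hypnogram(c(3, 3, 0)), "rem", total_min = 120)
  expect_equal(lat0$latency_min, 0)
  expect_false(lat0$censored)
  # first REM at epoch index 40 (3-s epochs) -> 2 minutes
  hyp40 <- hypnogram(c(rep(2, 40), 3))
  expect_equal(state_latency(hyp40, "rem", 120)$latency_min, 2)
})

test_that("lzc_sequence matches the exhaustive-history oracle", {
  expect_equal(lzc_sequence(rep(0, 10)), 2)
  expect_equal(lzc_sequence(0), 1)
  paper_prefix <- strsplit("000011001100112221113333", "")[[1]]
  expect_equal(lzc_sequence(paper_prefix), lzc_oracle(paper_prefix))
  # all binary strings up to length 10
  for (s in all_binary_strings(10)) {
    expect_equal(lzc_sequence(s), lzc_oracle(s))
  }
  # random quaternary strings
  set.seed(404)
  for (i in 1:300) {
    s <- random_symbols(sample(2:12, 1), 0:3)
    expect_equal(lzc_sequence(s), lzc_oracle(s))
  }
})

test_that("lzc_sequence is invariant under alphabet relabeling", {
  set.seed(17)
  for (i in 1:50) {
    s <- random_symbols(sample(5:40, 1), 0:3)
    perm <- sample(0:3)
    expect_equal(lzc_sequence(s), lzc_sequence(perm[s + 1]))
  }
})

test_that("hypnogram LZC grows with the chain's switching rate", {
  set.seed(23)
  med_lzc <- vapply(c(0.99, 0.9, 0.75, 0.5), function(diag) {
    off <- (1 - diag) / 3
    P <- matrix(off, 4, 4); diag(P) <- diag
    stats::median(vapply(1:40, function(r) {
      lzc_sequence(gen_hypnogram(P, 400, seed = 1000 * diag + r)$states)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_lzc) >= 0))
  expect_gt(med_lzc[4], med_lzc[1])
})

test_that("transition_matrix counts consecutive pairs and row-normalizes", {
  tm <- transition_matrix(hypnogram(c(0, 0, 1, 1)))
  expect_equal(tm$probs["wake", "wake"], 0.5)
  expect_equal(tm$probs["wake", "drowsiness"], 0.5)
  expect_equal(tm$probs["drowsiness", "drowsiness"], 1)
  expect_equal(sum(tm$counts), 3)

  const <- transition_matrix(hypnogram(rep(2, 4)))
  expect_equal(const$probs["nrem", "nrem"], 1)
  expect_true(all(is.na(const$probs["wake", ])))
  expect_error(transition_matrix(hypnogram(2)), "at least 2")
})

test_that("transition probabilities are recovered from a long Markov chain", {
  P <- rbind(c(0.90, 0.06, 0.04, 0.00),
             c(0.05, 0.85, 0.10, 0.00),
             c(0.02, 0.03, 0.90, 0.05),
             c(0.05, 0.00, 0.10, 0.85))
  hyp <- gen_hypnogram(P, 10000, seed = 77)
  est <- transition_matrix(hyp)$probs
  expect_lt(max(abs(est - P), na.rm = TRUE), 0.02)
  # row sums of defined rows are exactly 1; counts sum to n - 1
  expect_equal(unname(rowSums(est)[!is.na(est[, 1])]),
               rep(1, sum(!is.na(est[, 1]))))
  expect_equal(sum(transition_matrix(hyp)$counts), 9999)
})

test_that("identical architecture in both arms yields degenerate nulls", {
  set.seed(31)
  summaries <- lapply(1:4, function(i) {
    architecture_summary(gen_hypnogram(default_transitions("control"), 200,
                                       seed = i))
  })
  names(summaries) <- paste0("s", 1:4)
  cmp <- compare_architecture(summaries, summaries)
  expect_true(all(cmp$metrics$p == 1))
  expect_true(all(cmp$transitions$p[!is.na(cmp$transitions$p)] == 1))
})

test_that("REM-suppressed arm is compared through censored latencies", {
  set.seed(57)
  n <- 10
  ctrl <- lapply(1:n, function(i) {
    architecture_summary(
      gen_hypnogram(default_transitions("control"), 2400, seed = i),
      total_min = 120)
  })
  # REM entry set to zero: every latency must censor at 120
  P0 <- default_transitions("control")
  P0["nrem", "rem"] <- 0
  P0["nrem", "nrem"] <- P0["nrem", "nrem"] + 0.02
  traz <- lapply(1:n, function(i) {
    architecture_summary(gen_hypnogram(P0, 2400, seed = 100 + i),
                         total_min = 120)
  })
  names(ctrl) <- names(traz) <- paste0("s", 1:n)
  expect_true(all(vapply(traz, function(s) s$censored[["rem"]], logical(1))))
  expect_true(all(vapply(traz, function(s) s$latency_min[["rem"]],
                         numeric(1)) == 120))
  cmp <- compare_architecture(ctrl, traz)
  p_rem_lat <- cmp$metrics$p[cmp$metrics$metric == "latency" &
                               cmp$metrics$state == "rem"]
  expect_lt(p_rem_lat, 0.05)
})
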