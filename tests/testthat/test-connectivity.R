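# Hilbert phase, PLI, surrogates, and the thresholded condition contrast.

test_that("analytic phase advances at the tone frequency", {
  fs <- 400
  t <- (0:1999) / fs
  ph <- instantaneous_phase(sin(2 * pi * 10 * t))
  mid <- 200:1800
  inc <- diff(ph[mid])
  inc <- ifelse(inc < -pi, inc + 2 * pi, inc)
  expect_lt(abs(stats::median(inc) - 2 * pi * 10 / fs) /
              (2 * pi * 10 / fs), 0.01)
})

test_that("quadrature tones sit a constant quarter cycle apart", {
  fs <- 400
  t <- (0:1999) / fs
  pc <- instantaneous_phase(cos(2 * pi * 10 * t))
  ps <- instantaneous_phase(sin(2 * pi * 10 * t))
  d <- pc[200:1800] - ps[200:1800]
  d <- atan2(sin(d), cos(d))
  expect_lt(abs(stats::median(d) - pi / 2), 0.05)
  expect_error(instantaneous_phase(rep(0, 100)), "tolerance")
})

test_that("PLI limits: constant lag gives 1, zero lag gives 0", {
  ph <- runif(1000, -pi, pi)
  expect_equal(pli_pair(ph + pi / 2, ph), 1)
  expect_equal(pli_pair(ph, ph), 0)
  set.seed(14)
  expect_lt(pli_pair(runif(10000, -pi, pi), runif(10000, -pi, pi)), 0.05)
  expect_error(pli_pair(1:5, 1:4), "equal length")
})

test_that("pli_pair equals the explicit-loop oracle to 1e-12", {
  set.seed(15)
  for (i in 1:150) {
    n <- sample(50:400, 1)
    px <- runif(n, -4 * pi, 4 * pi)
    py <- runif(n, -4 * pi, 4 * pi)
    expect_equal(pli_pair(px, py), pli_oracle(px, py), tolerance = 1e-12)
  }
})

test_that("PLI matrices: zero-lag common drive yields ~0, lagged coupling is localized", {
  fs <- 400
  t <- (0:1199) / fs
  set.seed(16)
  common <- lapply(1:3, function(i) {
    s <- sin(2 * pi * 10 * t + runif(1, 0, 2 * pi))
    m <- cbind(s, s, s, s)     # exact copies: zero lag everywhere
    colnames(m) <- c("F3", "F4", "Fz", "Cz")
    m
  })
  m0 <- pli_matrix(common, fs, bands = list(alpha = c(9, 11)))$alpha
  expect_lt(max(m0), 0.05)
  expect_equal(m0, t(m0))
  expect_equal(unname(diag(m0)), rep(0, 4))

  # 30-s segments: the epoch-averaged |PLI| null bias shrinks with
  # segment length, so uncoupled pairs sit well below the coupled one
  prof <- state_profiles()$wake
  cpl <- list(list(pair = c(1, 2), band = c(9, 11), lag = pi / 4,
                   fraction = 0.95))
  eps <- lapply(1:3, function(i)
    gen_state_eeg(prof, cpl, n_channels = 4, duration_s = 30, fs = fs,
                  seed = 300 + i))
  m1 <- pli_matrix(eps, fs, bands = list(alpha = c(9, 11)))$alpha
  expect_gt(m1[1, 2], 0.8)
  others <- m1[upper.tri(m1)][-1]
  expect_lt(max(others), 0.2)
})

test_that("phase-randomized surrogates preserve the PSD and destroy coupling", {
  fs <- 400
  prof <- state_profiles()$wake
  cpl <- list(list(pair = c(1, 2), band = c(9, 11), lag = pi / 4,
                   fraction = 0.95))
  ep <- gen_state_eeg(prof, cpl, n_channels = 2, duration_s = 3, fs = fs,
                      seed = 21)
  sur <- surrogate_signals(ep, seed = 22)
  expect_identical(sur, surrogate_signals(ep, seed = 22))
  for (ch in 1:2) {
    # construction preserves the amplitude spectrum, hence the PSD
    a_orig <- Mod(fft(ep[, ch]))
    a_sur <- Mod(fft(sur[, ch]))
    expect_equal(a_sur, a_orig, tolerance = 1e-9)
  }
  # coupling gone in the surrogate ensemble
  filt <- lapply(1:2, function(ch) narrowband(ep[, ch], fs, "alpha"))
  real_pli <- pli_pair(instantaneous_phase(filt[[1]])[61:1140],
                       instantaneous_phase(filt[[2]])[61:1140])
  expect_gt(real_pli, 0.8)
  sp <- surrogate_pli(list(ep), fs, bands = list(alpha = c(9, 11)),
                      ns = 100, seed = 23)$alpha
  expect_lt(sp$mean[1, 2], 0.3)
  expect_gt(sp$sd[1, 2], 0)
})

test_that("surrogate ensembles are reproducible from the seed", {
  ep <- noise_epochs(2, 1200, 3, seed = 24, labels = c("F3", "F4", "Fz"))
  a <- surrogate_pli(ep, 400, bands = list(alpha = c(9, 11)), ns = 10,
                     seed = 25)
  b <- surrogate_pli(ep, 400, bands = list(alpha = c(9, 11)), ns = 10,
                     seed = 25)
  expect_identical(a, b)
})

test_that("delta PLI flags an injected coupling and demands ns >= 2", {
  fs <- 400
  prof <- state_profiles()$nrem
  set.seed(26)
  mk_dog <- function(sid, coupled) {
    cpl <- if (coupled) {
      list(list(pair = c(3, 4), band = c(9, 11), lag = pi / 4,
                fraction = 0.85))
    } else list()
    eps <- lapply(1:3, function(i)
      gen_state_eeg(prof, cpl, n_channels = 4, duration_s = 3, fs = fs,
                    channel_labels = c("F3", "F4", "Fz", "Cz")))
    eps
  }
  bands <- list(alpha = c(9, 11))
  dogs <- paste0("d", 1:5)
  pli_a <- list(); pli_b <- list(); sur_a <- list(); sur_b <- list()
  for (s in dogs) {
    ea <- mk_dog(s, coupled = FALSE)   # condition A: uncoupled
    eb <- mk_dog(s, coupled = TRUE)    # condition B: alpha Fz-Cz coupling
    pli_a[[s]] <- pli_matrix(ea, fs, bands)
    pli_b[[s]] <- pli_matrix(eb, fs, bands)
    sur_a[[s]] <- surrogate_pli(ea, fs, bands, ns = 40,
                                seed = 500 + match(s, dogs))
    sur_b[[s]] <- surrogate_pli(eb, fs, bands, ns = 40,
                                seed = 600 + match(s, dogs))
  }
  out <- delta_pli(pli_a, pli_b, sur_a, sur_b)$alpha
  expect_true(out$flagged["Fz", "Cz"])
  edge <- out$edges[out$edges$ch_i == "Fz" & out$edges$ch_j == "Cz", ]
  expect_equal(edge$direction, "b_increase")
  # only the injected edge should exceed the threshold
  expect_lte(nrow(out$edges), 2)

  sur1 <- lapply(sur_a, function(x) lapply(x, function(b) {
    b$ns <- 1; b
  }))
  expect_error(delta_pli(pli_a, pli_b, sur1, sur_b), "ns >= 2")
  expect_error(delta_pli(pli_a[1], pli_b[1], sur_a[1], sur_b[1]),
               "at least 2 subjects")
})
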