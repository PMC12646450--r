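# Phase lag index connectivity. The PLI of two narrowband signals is the
# absolute mean sign of their wrapped instantaneous phase difference:
# 0 for zero-lag (volume-conduction-like) or inconsistent coupling, 1 for
# a perfectly consistent nonzero lag. Condition differences are thresholded
# against a phase-randomized surrogate ensemble.

#' Instantaneous phase via the analytic signal
#'
#' FFT-based Hilbert transform: phase of the analytic signal, in
#' (-pi, pi]. The input must already be narrowband-filtered (see
#' [narrowband()]) for the phase to be physically meaningful; epoch edges
#' should be trimmed downstream (filter and Hilbert edge effects).
#'
#' @param x Narrowband real sample series.
#' @param tol Amplitude tolerance: an error is raised if the mean analytic
#'   amplitude is below `tol` (phase undefined for a null signal).
#' @return Phase series in radians, same length as `x`.
#' @export
instantaneous_phase <- function(x, tol = 1e-12) {
  z <- analytic_signal(x)
  if (mean(Mod(z)) < tol) stop("signal amplitude below tolerance: phase undefined")
  Arg(z)
}

# Analytic signal by the half-spectrum method: zero the negative
# frequencies, double the positive ones, keep DC/Nyquist.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Phase lag index of two phase series
#'
#' `PLI = | mean_t sign( wrap(phi_x - phi_y) ) |`, with the difference
#' wrapped to (-pi, pi] and `sign(0) = 0` (so exactly zero-lag coupling
#' contributes nothing).
#'
#' @param phase_x,phase_y Equal-length phase series in radians.
#' @return Scalar in \[0, 1\].
#' @export
pli_pair <- function(phase_x, phase_y) {
  if (length(phase_x) != length(phase_y)) {
    stop("phase series must have equal length")
  }
  d <- phase_x - phase_y
  wrapped <- atan2(sin(d), cos(d))
  abs(mean(sign(wrapped)))
}

trim_idx <- function(n, trim) {
  t0 <- floor(n * trim)
  (t0 + 1):(n - t0)
}

#' Narrowband PLI matrices for an epoch set
#'
#' For each band: filters every epoch's channels to the band, extracts
#' instantaneous phases, trims `edge_trim` of the samples at each end, and
#' computes the PLI for every channel pair; matrices are averaged across
#' the set's epochs.
#'
#' @param es Epoch set or list of samples x channels matrices.
#' @param fs Sampling rate (Hz).
#' @param bands Named list of band edges (default [pli_bands()]).
#' @param edge_trim Fraction of samples dropped at each epoch edge
#'   (default 0.05).
#' @return Named list (per band) of symmetric channels x channels PLI
#'   matrices with zero diagonal.
#' @export
pli_matrix <- function(es, fs, bands = pli_bands(), edge_trim = 0.05) {
  epochs <- if (inherits(es, "epoch_set")) es$epochs else es
  if (length(epochs) == 0) stop("empty epoch set")
  nch <- ncol(as.matrix(epochs[[1]]))
  out <- lapply(bands, function(band) {
    acc <- matrix(0, nch, nch)
    for (ep in epochs) {
      ep <- as.matrix(ep)
      ph <- vapply(seq_len(nch), function(ch) {
        instantaneous_phase(narrowband(ep[, ch], fs, band))
      }, numeric(nrow(ep)))
      keep <- trim_idx(nrow(ep), edge_trim)
      for (a in seq_len(nch - 1)) {
        for (b in (a + 1):nch) {
          v <- pli_pair(ph[keep, a], ph[keep, b])
          acc[a, b] <- acc[a, b] + v
          acc[b, a] <- acc[b, a] + v
        }
      }
    }
    m <- acc / length(epochs)
    dimnames(m) <- dimnames_for(epochs[[1]], nch)
    m
  })
  out
}

dimnames_for <- function(ep, nch) {
  nms <- colnames(as.matrix(ep))
  if (is.null(nms)) nms <- paste0("ch", seq_len(nch))
  list(nms, nms)
}

#' Phase-randomized surrogate of a multichannel segment
#'
#' Independently per channel, randomizes the Fourier phases while keeping
#' the amplitude spectrum, so each channel's PSD is preserved exactly
#' while all cross-channel phase relations are destroyed. Deterministic
#' given `seed`.
#'
#' @param epoch Samples x channels numeric matrix.
#' @param seed Optional integer seed.
#' @return Surrogate matrix of the same dimensions.
#' @export
surrogate_signals <- function(epoch, seed = NULL) {
  epoch <- as.matrix(epoch)
  with_seed(seed, {
    out <- epoch
    n <- nrow(epoch)
    half <- n %/% 2
    for (ch in seq_len(ncol(epoch))) {
      X <- fft(epoch[, ch])
      if (half >= 2) {
        phi <- runif(half - 1, 0, 2 * pi)
        X[2:half] <- Mod(X[2:half]) * exp(1i * phi)
        idx <- (n - half + 2):n
        X[idx] <- Conj(X[half:2])
      }
      out[, ch] <- Re(fft(X, inverse = TRUE) / n)
    }
    out
  })
}

#' Surrogate PLI ensemble for an epoch set
#'
#' The surrogate ensemble behind the significance threshold: per band,
#' each channel of each (band-filtered) epoch gets `ns` independent
#' phase-randomized surrogates; one surrogate's PLI matrix is the average
#' over the set's epochs, mirroring the real-data estimator. Runs in
#' compiled code; deterministic given `seed`.
#'
#' @inheritParams pli_matrix
#' @param ns Number of surrogates (default 100).
#' @param seed Optional integer seed.
#' @return Named list (per band) of `list(mean, sd, ns)`: the mean and SD
#'   across the `ns` surrogate PLI matrices (channels x channels, zero
#'   diagonal; `sd` is `NA` on the diagonal-free entries when `ns = 1`).
#' @export
surrogate_pli <- function(es, fs, bands = pli_bands(), ns = 100,
                          edge_trim = 0.05, seed = NULL) {
  epochs <- if (inherits(es, "epoch_set")) es$epochs else es
  if (length(epochs) == 0) stop("empty epoch set")
  if (ns < 1) stop("ns must be >= 1")
  nch <- ncol(as.matrix(epochs[[1]]))
  dn <- dimnames_for(epochs[[1]], nch)
  with_seed(seed, {
    lapply(bands, function(band) {
      filt <- lapply(epochs, function(ep) {
        filter_channels(as.matrix(ep), narrowband, fs = fs, band = band)
      })
      ens <- surrogate_pli_ensemble_cpp(filt, as.integer(ns), edge_trim)
      to_mat <- function(v) {
        m <- matrix(0, nch, nch, dimnames = dn)
        m[upper.tri(m)] <- v
        m[lower.tri(m)] <- t(m)[lower.tri(m)]
        m
      }
      list(mean = to_mat(colMeans(ens)),
           sd = to_mat(apply(ens, 2, sd)),
           ns = ns)
    })
  })
}

#' Surrogate-thresholded condition difference in PLI
#'
#' For each band, computes the cohort mean difference
#' `delta = mean_subjects(PLI_a - PLI_b)` from the real matrices, and a
#' surrogate null reference from the per-subject ensembles: the
#' per-surrogate condition difference `PLI_a_s - PLI_b_s` has mean
#' `delta_s` and standard deviation `sigma_s` over the whole ensemble
#' (subjects x surrogates, by the law of total variance). The
#' significance threshold is `Th = delta_s + sigma_s`; an edge is flagged
#' when `|delta| > Th`, with its direction recorded (`"a_increase"` when
#' condition A has the larger PLI, `"b_increase"` otherwise). Subjects
#' must contribute both conditions; subjects missing from either list are
#' dropped (pairwise-complete).
#'
#' @param pli_a,pli_b Named lists (subject id -> per-band PLI matrix list
#'   from [pli_matrix()]) for the two conditions.
#' @param surr_a,surr_b Same structure from [surrogate_pli()]; each
#'   subject's ensemble must have `ns >= 2` (the surrogate SD is
#'   undefined otherwise).
#' @return Named list per band: `delta`, `surrogate_mean`, `surrogate_sd`,
#'   `threshold`, `flagged` (logical matrix), and `edges` (data.frame of
#'   flagged edges with direction).
#' @export
delta_pli <- function(pli_a, pli_b, surr_a, surr_b) {
  subjects <- Reduce(intersect, list(names(pli_a), names(pli_b),
                                     names(surr_a), names(surr_b)))
  if (length(subjects) < 2) {
    stop("need at least 2 subjects with both conditions")
  }
  bands <- names(pli_a[[subjects[1]]])
  lapply(stats::setNames(bands, bands), function(bnm) {
    if (any(vapply(subjects, function(s) {
      surr_a[[s]][[bnm]]$ns < 2 || surr_b[[s]][[bnm]]$ns < 2
    }, logical(1)))) {
      stop("surrogate SD undefined: every ensemble needs ns >= 2 surrogates")
    }
    real_diff <- lapply(subjects, function(s) {
      pli_a[[s]][[bnm]] - pli_b[[s]][[bnm]]
    })
    surr_mean_diff <- lapply(subjects, function(s) {
      surr_a[[s]][[bnm]]$mean - surr_b[[s]][[bnm]]$mean
    })
    delta <- Reduce(`+`, real_diff) / length(subjects)
    ds_mean <- Reduce(`+`, surr_mean_diff) / length(subjects)
    # total variance of the per-surrogate difference over subjects and
    # surrogates: within-subject surrogate variance (independent
    # conditions add) plus between-subject variance of the means
    within <- Reduce(`+`, lapply(subjects, function(s) {
      surr_a[[s]][[bnm]]$sd^2 + surr_b[[s]][[bnm]]$sd^2
    })) / length(subjects)
    between_arr <- simplify2array(surr_mean_diff)
    between <- apply(between_arr, c(1, 2), var)
    ds_sd <- sqrt(within + between)
    th <- ds_mean + ds_sd
    flagged <- abs(delta) > th
    diag(flagged) <- FALSE
    nms <- rownames(delta) %||% paste0("ch", seq_len(nrow(delta)))
    idx <- which(flagged & upper.tri(flagged), arr.ind = TRUE)
    edges <- data.frame(
      ch_i = nms[idx[, 1]], ch_j = nms[idx[, 2]],
      delta = delta[idx], threshold = th[idx],
      direction = ifelse(delta[idx] > 0, "a_increase", "b_increase")
    )
    list(delta = delta, surrogate_mean = ds_mean, surrogate_sd = ds_sd,
         threshold = th, flagged = flagged, edges = edges,
         n_subjects = length(subjects))
  })
}
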