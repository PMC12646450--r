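# Synthetic study generator: first-order Markov hypnograms and
# state-dependent, optionally phase-coupled multichannel EEG for paired
# cohorts. Signals are synthesized in the frequency domain as band-weighted
# colored noise (1/f background plus physiological band bumps), so every
# injected effect (spectral shifts, couplings, transition changes, REM
# suppression) is recoverable by the corresponding analysis stage.

SYNTH_BANDS <- list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
                    beta = c(13, 30), gamma = c(30, 50))

#' Default state spectral profiles
#'
#' Relative power weights over the physiological bands (delta, theta,
#' alpha, beta, gamma), a pink-noise background exponent, and an amplitude
#' scale in microvolts RMS, per behavioral state. NREM is delta-dominant;
#' wake and REM are broadband with stronger fast activity; drowsiness sits
#' in between.
#'
#' @return Named list of per-state profiles.
#' @export
state_profiles <- function() {
  list(
    wake = list(weights = c(delta = 1.0, theta = 0.8, alpha = 0.7,
                            beta = 0.5, gamma = 0.3),
                pink = 1, background = 0.3, amp_uv = 30),
    drowsiness = list(weights = c(delta = 1.5, theta = 1.0, alpha = 0.8,
                                  beta = 0.4, gamma = 0.2),
                      pink = 1, background = 0.3, amp_uv = 40),
    nrem = list(weights = c(delta = 4.0, theta = 1.0, alpha = 0.5,
                            beta = 0.2, gamma = 0.08),
                pink = 1, background = 0.2, amp_uv = 60),
    rem = list(weights = c(delta = 0.8, theta = 1.0, alpha = 0.7,
                           beta = 0.5, gamma = 0.3),
               pink = 1, background = 0.3, amp_uv = 30)
  )
}

#' Default state-transition matrices for the two study arms
#'
#' Row-stochastic first-order transition matrices (3-s epochs) over wake,
#' drowsiness, NREM, REM. The control arm switches states freely and
#' enters REM readily; the sedated ("trazodone") arm is stickier in every
#' state, favors sustained drowsiness, and has REM entry suppressed so
#' that a majority of 2-hour sessions never reach REM.
#'
#' @param condition `"control"` or `"trazodone"`.
#' @return 4x4 row-stochastic matrix with state dimnames.
#' @export
default_transitions <- function(condition = c("control", "trazodone")) {
  condition <- match.arg(condition)
  if (condition == "control") {
    m <- rbind(
      wake       = c(0.930, 0.060, 0.010, 0.000),
      drowsiness = c(0.040, 0.900, 0.060, 0.000),
      nrem       = c(0.005, 0.030, 0.945, 0.020),
      rem        = c(0.020, 0.010, 0.030, 0.940))
  } else {
    # sedated arm: stickier states overall, strongly suppressed REM entry
    m <- rbind(
      wake       = c(0.9500, 0.0450, 0.0050, 0.0000),
      drowsiness = c(0.0200, 0.9600, 0.0200, 0.0000),
      nrem       = c(0.0040, 0.0150, 0.98045, 0.00055),
      rem        = c(0.0150, 0.0050, 0.0300, 0.9500))
  }
  colnames(m) <- STATE_NAMES
  m
}

default_clean_frac <- function(condition = c("control", "trazodone")) {
  condition <- match.arg(condition)
  if (condition == "control") {
    c(wake = 0.077, drowsiness = 0.411, nrem = 1.0, rem = 0.335)
  } else {
    c(wake = 0.177, drowsiness = 0.589, nrem = 1.0, rem = 0.531)
  }
}

#' Cohort generator configuration
#'
#' Assembles the parameters of a paired synthetic study. The
#' `"trazodone-like"` preset injects the sedation signature: stickier
#' hypnograms with strongly suppressed REM entry, a x1.5 power increase
#' above 13 Hz (wake, drowsiness, NREM), a power decrease below 13 Hz in
#' wake/drowsiness, and an added alpha-band Cz-Fz phase coupling in NREM.
#' The `"null"` preset generates both arms from identical parameters
#' (for type-I-error checks).
#'
#' @param preset `"trazodone-like"` or `"null"`.
#' @param n_subjects Number of subjects (default 12; each has both arms).
#' @param duration_min Session length in minutes (default 120).
#' @param fs Sampling rate in Hz (default 400).
#' @param epoch_s Scored epoch length in seconds (default 3).
#' @param channels Channel labels (default F3, F4, Fz, Cz).
#' @param seed Master seed; all per-session streams derive from it.
#' @param subject_sdlog Log-SD of the per-subject spectral-shape jitter
#'   applied to the band weights (shared across the subject's two arms).
#' @param session_sdlog Log-SD of the additional per-session jitter.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(preset = c("trazodone-like", "null"),
                          n_subjects = 12, duration_min = 120, fs = 400,
                          epoch_s = 3, channels = DEFAULT_CHANNELS,
                          seed = 1, subject_sdlog = 0.15,
                          session_sdlog = 0.05) {
  preset <- match.arg(preset)
  effects <- if (preset == "trazodone-like") {
    list(
      high_mult = 1.5, high_cut_hz = 13,
      high_states = c("wake", "drowsiness", "nrem"),
      low_mult = 0.85, low_states = c("wake", "drowsiness"),
      coupling = list(list(pair = c("Cz", "Fz"), band = c(9, 11),
                           lag = pi / 4, fraction = 0.8, state = "nrem"))
    )
  } else {
    list(high_mult = 1, high_cut_hz = 13, high_states = character(0),
         low_mult = 1, low_states = character(0), coupling = list())
  }
  transitions <- list(
    control = default_transitions("control"),
    trazodone = if (preset == "trazodone-like") {
      default_transitions("trazodone")
    } else {
      default_transitions("control")
    }
  )
  clean_frac <- list(
    control = default_clean_frac("control"),
    trazodone = if (preset == "trazodone-like") {
      default_clean_frac("trazodone")
    } else {
      default_clean_frac("control")
    }
  )
  structure(
    list(preset = preset, n_subjects = n_subjects,
         duration_min = duration_min, fs = fs, epoch_s = epoch_s,
         channels = channels, seed = seed, transitions = transitions,
         clean_frac = clean_frac, profiles = state_profiles(),
         effects = effects, subject_sdlog = subject_sdlog,
         session_sdlog = session_sdlog),
    class = "cohort_config"
  )
}

#' Simulate a hypnogram from a first-order Markov chain
#'
#' @param transitions Row-stochastic 4x4 matrix, rows/columns ordered
#'   wake, drowsiness, NREM, REM.
#' @param n_epochs Number of epochs to generate.
#' @param initial_state Starting state code (default 0, wake).
#' @param seed Optional integer seed.
#' @param epoch_s Epoch length in seconds.
#' @return A [hypnogram()] (all epochs unflagged).
#' @export
gen_hypnogram <- function(transitions, n_epochs, initial_state = 0,
                          seed = NULL, epoch_s = 3) {
  transitions <- as.matrix(transitions)
  if (any(transitions < 0) ||
      any(abs(rowSums(transitions) - 1) > 1e-8)) {
    stop("transition matrix rows must be nonnegative and sum to 1")
  }
  with_seed(seed, {
    s <- integer(n_epochs)
    s[1] <- as.integer(initial_state)
    cum <- t(apply(transitions, 1, cumsum))
    u <- runif(n_epochs)
    for (t in seq_len(n_epochs - 1)) {
      s[t + 1] <- sum(u[t] > cum[s[t] + 1, ])
    }
    hypnogram(s, epoch_length_s = epoch_s)
  })
}

# Amplitude (sqrt power) spectral template for a state profile on a
# frequency grid; condition multipliers are power multipliers.
profile_amplitude <- function(freq, profile, high_mult = 1,
                              high_cut_hz = 13, low_mult = 1) {
  S <- profile$background / pmax(freq, 1)^profile$pink
  for (bnm in names(SYNTH_BANDS)) {
    b <- SYNTH_BANDS[[bnm]]
    w <- profile$weights[[bnm]]
    if (is.null(w) || w == 0) next
    # unit-power bump with 1 Hz raised-cosine shoulders
    ramp <- function(f, lo, hi) {
      ifelse(f < lo - 1 | f > hi + 1, 0,
             ifelse(f < lo, 0.5 * (1 + cos(pi * (lo - f))),
                    ifelse(f > hi, 0.5 * (1 + cos(pi * (f - hi))), 1)))
    }
    S <- S + w * ramp(freq, b[1], b[2]) / (b[2] - b[1])
  }
  S <- S * ifelse(freq > high_cut_hz, high_mult, low_mult)
  sqrt(S)
}

#' Synthesize one multichannel state-EEG segment
#'
#' Frequency-domain synthesis: per channel, colored noise whose power
#' spectrum follows the state profile (1/f background plus band bumps)
#' with independent uniform phases; coupled channel pairs share a fraction
#' of the band's drive, one copy phase-shifted by the specified lag.
#' Channels are scaled to the profile's RMS amplitude.
#'
#' @param profile A state profile (see [state_profiles()]).
#' @param coupling List of coupling specs, each
#'   `list(pair, band, lag, fraction)`; `pair` indexes or names channels,
#'   `fraction` in \[0,1\] is the amplitude share of the band's drive that
#'   the two channels have in common (one copy lagged by `lag` radians).
#' @param n_channels Number of channels.
#' @param duration_s Segment duration (s).
#' @param fs Sampling rate (Hz).
#' @param seed Optional integer seed.
#' @param channel_labels Optional channel names for the columns.
#' @return Samples x channels matrix (microvolts).
#' @export
gen_state_eeg <- function(profile, coupling = list(), n_channels = 4,
                          duration_s = 3, fs = 400, seed = NULL,
                          channel_labels = NULL) {
  n <- as.integer(round(duration_s * fs))
  mat <- with_seed(seed, {
    gen_epoch_batch(profile, coupling, n_channels, n, fs, n_epochs = 1)[[1]]
  })
  if (!is.null(channel_labels)) colnames(mat) <- channel_labels
  mat
}

# Batched synthesis of n_epochs independent segments of one state (shared
# spectral template, fresh phases) — one inverse FFT per channel via mvfft.
# Uses the current RNG stream.
gen_epoch_batch <- function(profile, coupling, n_channels, n, fs,
                            n_epochs, high_mult = 1, high_cut_hz = 13,
                            low_mult = 1, channel_labels = NULL) {
  half <- n %/% 2
  freq <- (1:(half - 1)) * fs / n
  w <- profile_amplitude(freq, profile, high_mult, high_cut_hz, low_mult)
  specs <- lapply(seq_len(n_channels), function(ch) {
    phi <- matrix(runif((half - 1) * n_epochs, 0, 2 * pi), half - 1)
    w * exp(1i * phi)
  })
  for (cp in coupling) {
    idx <- cp$pair
    if (is.character(idx)) {
      if (is.null(channel_labels)) stop("named coupling pair needs channel labels")
      idx <- match(idx, channel_labels)
    }
    if (anyNA(idx) || any(idx < 1 | idx > n_channels) || idx[1] == idx[2]) {
      stop("invalid coupling pair")
    }
    rows <- which(freq >= cp$band[1] & freq <= cp$band[2])
    if (length(rows) == 0) next
    frac <- cp$fraction
    if (frac < 0 || frac > 1) stop("coupling fraction must be in [0,1]")
    common <- matrix(exp(1i * runif(length(rows) * n_epochs, 0, 2 * pi)),
                     length(rows))
    wb <- w[rows]
    # `fraction` is the amplitude share of the shared drive; the mix is
    # renormalized so the band's expected power is unchanged
    norm <- sqrt((1 - frac)^2 + frac^2)
    for (k in 1:2) {
      shift <- if (k == 1) 1 else exp(-1i * cp$lag)
      own <- specs[[idx[k]]][rows, , drop = FALSE] / wb
      specs[[idx[k]]][rows, ] <- wb * ((1 - frac) * own +
                                         frac * common * shift) / norm
    }
  }
  chans <- lapply(seq_len(n_channels), function(ch) {
    full <- matrix(0 + 0i, n, n_epochs)
    full[2:half, ] <- specs[[ch]]
    full[(n - half + 2):n, ] <- Conj(specs[[ch]][(half - 1):1, , drop = FALSE])
    Re(stats::mvfft(full, inverse = TRUE)) / n
  })
  lapply(seq_len(n_epochs), function(e) {
    m <- vapply(chans, function(cm) cm[, e], numeric(n))
    rms <- sqrt(colMeans(m^2))
    m <- sweep(m, 2, profile$amp_uv / pmax(rms, 1e-12), "*")
    if (!is.null(channel_labels)) colnames(m) <- channel_labels
    m
  })
}

# Full session signal for a hypnogram: per-epoch state synthesis with
# raised-cosine crossfades (0.25 s) at epoch junctions to avoid boundary
# spectral splatter.
gen_session_signals <- function(hyp, profiles, fs, channels, effects,
                                condition, jitter) {
  n_ep <- length(hyp$states)
  spr <- as.integer(round(fs * hyp$epoch_length_s))
  nch <- length(channels)
  epochs <- vector("list", n_ep)
  for (code in unique(hyp$states)) {
    nm <- state_name(code)
    idx <- which(hyp$states == code)
    pr <- profiles[[nm]]
    pr$weights <- pr$weights * jitter[[nm]]
    hm <- if (condition == "trazodone" && nm %in% effects$high_states) {
      effects$high_mult
    } else 1
    lm <- if (condition == "trazodone" && nm %in% effects$low_states) {
      effects$low_mult
    } else 1
    cps <- Filter(function(cp) {
      condition == "trazodone" && (cp$state %||% nm) == nm
    }, effects$coupling)
    batch <- gen_epoch_batch(pr, cps, nch, spr, fs, length(idx),
                             high_mult = hm,
                             high_cut_hz = effects$high_cut_hz,
                             low_mult = lm, channel_labels = channels)
    epochs[idx] <- batch
  }
  sig <- do.call(rbind, epochs)
  # raised-cosine crossfade over 0.25 s centered on each epoch boundary;
  # each side is mirror-extended across the junction so both contents are
  # defined over the whole blend window
  cf <- min(as.integer(0.125 * fs), spr %/% 4)
  if (n_ep > 1 && cf > 1) {
    r <- 0.5 * (1 - cos(pi * seq_len(2 * cf) / (2 * cf + 1)))
    for (e in seq_len(n_ep - 1)) {
      j <- e * spr
      a <- sig[(j - cf + 1):j, , drop = FALSE]      # end of epoch e
      b <- sig[(j + 1):(j + cf), , drop = FALSE]    # start of epoch e+1
      a_ext <- a[cf:1, , drop = FALSE]              # mirrored beyond edge
      b_ext <- b[cf:1, , drop = FALSE]
      sig[(j - cf + 1):j, ] <- (1 - r[1:cf]) * a + r[1:cf] * b_ext
      sig[(j + 1):(j + cf), ] <- (1 - r[(cf + 1):(2 * cf)]) * a_ext +
        r[(cf + 1):(2 * cf)] * b
    }
  }
  sig
}

#' Generate a paired synthetic cohort
#'
#' One session per subject per condition: a Markov hypnogram from the
#' condition's transition matrix and an EEG whose per-epoch state follows
#' the hypnogram with the condition's spectral profiles and couplings.
#' Artifact flags are drawn per state at the configured clean-epoch rates
#' (signals are not corrupted). Fully reproducible from the master seed.
#'
#' @param cfg A [cohort_config()].
#' @return A `synthetic_study`: list with `sessions` (each has
#'   `recording`, `hypnogram`, `subject_id`, `condition`) and `config`.
#' @export
gen_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  n_epochs <- as.integer(round(cfg$duration_min * 60 / cfg$epoch_s))
  sessions <- list()
  for (i in seq_len(cfg$n_subjects)) {
    sid <- sprintf("dog%02d", i)
    jit_seed <- derive_seed(cfg$seed, sid, "jitter")
    jitter <- with_seed(jit_seed, {
      js <- lapply(STATE_NAMES, function(nm) {
        exp(rnorm(5, 0, cfg$subject_sdlog))
      })
      names(js) <- STATE_NAMES
      js
    })
    for (cond in c("control", "trazodone")) {
      s_seed <- derive_seed(cfg$seed, sid, cond)
      sess <- with_seed(s_seed, {
        hyp <- gen_hypnogram(cfg$transitions[[cond]], n_epochs,
                             initial_state = 0, epoch_s = cfg$epoch_s)
        cf <- cfg$clean_frac[[cond]]
        flags <- runif(n_epochs) > cf[state_name(hyp$states)]
        hyp$artifact_flags <- unname(flags)
        sess_jit <- lapply(jitter, function(j) {
          j * exp(rnorm(5, 0, cfg$session_sdlog))
        })
        sig <- gen_session_signals(hyp, cfg$profiles, cfg$fs,
                                   cfg$channels, cfg$effects, cond,
                                   sess_jit)
        list(recording = session_recording(sig, cfg$fs, cfg$channels,
                                           subject_id = sid,
                                           condition = cond),
             hypnogram = hyp, subject_id = sid, condition = cond)
      })
      sessions[[paste(sid, cond, sep = "_")]] <- sess
    }
  }
  structure(list(sessions = sessions, config = cfg),
            class = "synthetic_study")
}

#' Write a synthetic study to disk
#'
#' Writes one EDF recording and one hypnogram TSV per session, plus a
#' study manifest, in the exact formats [load_manifest()],
#' [load_recording()] and [load_hypnogram()] read.
#'
#' @param study A `synthetic_study` from [gen_cohort()].
#' @param dir Output directory (created if needed).
#' @return Path to the manifest file, invisibly.
#' @export
write_cohort <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(study$sessions, function(s) {
    base <- paste(s$subject_id, s$condition, sep = "_")
    rec_path <- file.path(dir, paste0(base, ".edf"))
    hyp_path <- file.path(dir, paste0(base, "_hypnogram.tsv"))
    write_edf(rec_path, s$recording$signals, s$recording$fs,
              s$recording$channels, patient_id = s$subject_id)
    write_hypnogram(s$hypnogram, hyp_path)
    data.frame(subject_id = s$subject_id, condition = s$condition,
               recording_path = basename(rec_path),
               hypnogram_path = basename(hyp_path))
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.tsv")
  write.table(manifest, mpath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(mpath)
}

#' Load a study from a manifest into the in-memory session format
#'
#' @param manifest_path Path to a manifest TSV (see [load_manifest()]).
#' @param channels Channel labels to extract from each recording.
#' @return A study list in the [gen_cohort()] session layout.
#' @export
load_study <- function(manifest_path, channels = DEFAULT_CHANNELS) {
  man <- load_manifest(manifest_path)
  sessions <- list()
  for (k in seq_len(nrow(man))) {
    rec <- load_recording(man$recording_path[k], channels,
                          subject_id = man$subject_id[k],
                          condition = man$condition[k])
    hyp <- load_hypnogram(man$hypnogram_path[k])
    sessions[[paste(man$subject_id[k], man$condition[k], sep = "_")]] <-
      list(recording = rec, hypnogram = hyp,
           subject_id = man$subject_id[k], condition = man$condition[k])
  }
  structure(list(sessions = sessions, config = NULL),
            class = "synthetic_study")
}
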