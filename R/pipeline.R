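# End-to-end study orchestration: preprocess -> epoching/quality ->
# architecture -> spectra -> nonlinear metrics -> connectivity, with the
# pairing policy per state and plain-TSV outputs. Everything is
# deterministic given (inputs, config, seed).

#' Pipeline configuration
#'
#' @param seed Master seed for epoch sampling and surrogates.
#' @param bandpass_hz Continuous-record bandpass edges (Hz).
#' @param notch_hz Notch frequency (Hz), or `NULL` to skip.
#' @param epochs_per_state Clean epochs sampled per state (default 5).
#' @param pe_dim,pe_tau Permutation-entropy embedding parameters.
#' @param n_surrogates Surrogate count for the PLI threshold (default 100).
#' @param alpha_rpsd,alpha_coherence Per-bin significance levels.
#' @param paired_states States compared with the paired test; the rest use
#'   the unpaired Mann-Whitney (the standard fallback when one arm may
#'   lack the state).
#' @param connectivity_states States to run the (costly) surrogate PLI
#'   analysis on; default all four.
#' @param coherence_pairs `"all"` or a list of channel-label pairs.
#' @param bands Narrowband presets for PLI (default [pli_bands()]).
#' @param edge_trim PLI epoch-edge trim fraction.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, bandpass_hz = c(1, 70),
                            notch_hz = 60, epochs_per_state = 5,
                            pe_dim = 4, pe_tau = 1, n_surrogates = 100,
                            alpha_rpsd = 0.01, alpha_coherence = 0.05,
                            paired_states = c("wake", "drowsiness"),
                            connectivity_states = STATE_NAMES,
                            coherence_pairs = "all",
                            bands = pli_bands(), edge_trim = 0.05) {
  structure(as.list(environment()), class = "pipeline_config")
}

all_pairs <- function(channels) {
  idx <- utils::combn(length(channels), 2)
  lapply(seq_len(ncol(idx)), function(k) channels[idx[, k]])
}

#' Run the full study analysis
#'
#' Executes the stages in order on every session of a study:
#' preprocessing (bandpass + notch on the continuous record), epoch
#' segmentation with quality summary and seeded clean-epoch sampling,
#' hypnogram architecture with paired condition comparison, relative PSD
#' and coherence with per-bin condition comparison, band-resolved
#' complexity/entropy with condition and state comparisons, and
#' surrogate-thresholded PLI condition differences. States absent from a
#' session are skipped and the affected comparisons degrade to unpaired
#' tests or report the reduced n.
#'
#' @param study A study list ([gen_cohort()] output or [load_study()]),
#'   or a path to a manifest TSV.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: result tables are written as TSV.
#' @param stages Subset of
#'   `c("architecture", "spectral", "complexity", "connectivity")` to run;
#'   coherence runs with `"spectral"`.
#' @return Named list of result tables and objects; see the vignette for
#'   the full layout.
#' @export
run_study <- function(study, config = pipeline_config(), out_dir = NULL,
                      stages = c("architecture", "spectral", "complexity",
                                 "connectivity")) {
  if (is.character(study)) study <- load_study(study)
  sessions <- study$sessions
  res <- list(config = config)

  # ---- preprocess + epoch every session once --------------------------
  prepped <- lapply(sessions, function(s) {
    rec <- preprocess_recording(s$recording, band = config$bandpass_hz,
                                notch = config$notch_hz)
    sets <- segment_epochs(rec, s$hypnogram)
    clean <- suppressMessages(sample_clean_epochs(
      sets, n = config$epochs_per_state,
      seed = derive_seed(config$seed, s$subject_id, s$condition)))
    list(subject_id = s$subject_id, condition = s$condition,
         fs = rec$fs, channels = rec$channels, hypnogram = s$hypnogram,
         clean = clean)
  })
  subjects <- unique(vapply(prepped, `[[`, "", "subject_id"))
  by_cond <- function(cond) {
    keep <- Filter(function(p) p$condition == cond, prepped)
    stats::setNames(keep, vapply(keep, `[[`, "", "subject_id"))
  }
  ctrl <- by_cond("control"); traz <- by_cond("trazodone")
  fs <- prepped[[1]]$fs

  res$quality <- do.call(rbind, lapply(prepped, function(p) {
    q <- epoch_quality_summary(p$hypnogram)
    if (nrow(q)) cbind(subject_id = p$subject_id, condition = p$condition, q)
  }))

  # ---- architecture ---------------------------------------------------
  if ("architecture" %in% stages) {
    summ <- lapply(prepped, function(p) architecture_summary(p$hypnogram))
    names(summ) <- names(prepped)
    res$architecture <- do.call(rbind, lapply(seq_along(prepped), function(k) {
      p <- prepped[[k]]; s <- summ[[k]]
      data.frame(subject_id = p$subject_id, condition = p$condition,
                 state = STATE_NAMES,
                 percent_time = unname(s$percent_time[STATE_NAMES]),
                 latency_min = unname(s$latency_min[STATE_NAMES]),
                 censored = unname(s$censored[STATE_NAMES]),
                 hypnogram_lzc = s$hypnogram_lzc)
    }))
    summ_c <- summ[paste(names(ctrl), "control", sep = "_")]
    names(summ_c) <- names(ctrl)
    summ_t <- summ[paste(names(traz), "trazodone", sep = "_")]
    names(summ_t) <- names(traz)
    res$architecture_tests <- compare_architecture(summ_c, summ_t)
    res$transitions <- do.call(rbind, lapply(seq_along(prepped), function(k) {
      p <- prepped[[k]]; tm <- summ[[k]]$transitions
      df <- expand.grid(from = STATE_NAMES, to = STATE_NAMES,
                        stringsAsFactors = FALSE)
      df$count <- tm$counts[cbind(df$from, df$to)]
      df$prob <- tm$probs[cbind(df$from, df$to)]
      cbind(subject_id = p$subject_id, condition = p$condition, df)
    }))
  }

  state_values <- function(cond_list, fun) {
    lapply(cond_list, function(p) {
      lapply(p$clean, function(es) fun(es))
    })
  }
  compare_by_state <- function(va, vb, freq, alpha) {
    out <- list()
    for (nm in STATE_NAMES) {
      sa <- names(va)[vapply(va, function(x) !is.null(x[[nm]]), logical(1))]
      sb <- names(vb)[vapply(vb, function(x) !is.null(x[[nm]]), logical(1))]
      if (length(sa) < 2 || length(sb) < 2) next
      paired <- nm %in% config$paired_states && setequal(sa, sb)
      if (paired) sb <- sa   # align subject order for pairing
      a <- do.call(rbind, lapply(va[sa], function(x) x[[nm]]))
      b <- do.call(rbind, lapply(vb[sb], function(x) x[[nm]]))
      out[[nm]] <- compare_spectra(a, b, freq, paired, alpha)
    }
    out
  }

  # ---- spectral -------------------------------------------------------
  if ("spectral" %in% stages) {
    r_ctrl <- state_values(ctrl, function(es) rpsd(es, fs)$channel_mean)
    r_traz <- state_values(traz, function(es) rpsd(es, fs)$channel_mean)
    freq <- rpsd(ctrl[[1]]$clean[[1]], fs)$freq
    res$rpsd <- rbind(
      rpsd_long(r_ctrl, "control", freq),
      rpsd_long(r_traz, "trazodone", freq))
    res$rpsd_tests <- compare_by_state(r_ctrl, r_traz, freq,
                                       config$alpha_rpsd)

    pairs <- if (identical(config$coherence_pairs, "all")) {
      all_pairs(prepped[[1]]$channels)
    } else config$coherence_pairs
    res$coherence_tests <- list()
    res$coherence <- list()
    for (pr in pairs) {
      key <- paste(pr, collapse = "-")
      c_ctrl <- state_values(ctrl, function(es)
        coherence_pair(es, fs, pr)$coh)
      c_traz <- state_values(traz, function(es)
        coherence_pair(es, fs, pr)$coh)
      cfreq <- coherence_pair(ctrl[[1]]$clean[[1]], fs, pr)$freq
      res$coherence[[key]] <- list(control = c_ctrl, trazodone = c_traz,
                                   freq = cfreq)
      res$coherence_tests[[key]] <-
        compare_by_state(c_ctrl, c_traz, cfreq, config$alpha_coherence)
    }
  }

  # ---- complexity / entropy -------------------------------------------
  if ("complexity" %in% stages) {
    nl <- do.call(rbind, lapply(prepped, function(p) {
      do.call(rbind, lapply(names(p$clean), function(nm) {
        bm <- band_metrics(p$clean[[nm]], fs, D = config$pe_dim,
                           tau = config$pe_tau)
        cbind(subject_id = p$subject_id, condition = p$condition,
              state = nm, bm)
      }))
    }))
    rownames(nl) <- NULL
    res$nonlinear <- nl
    res$nonlinear_tests <- nonlinear_condition_tests(nl, config)
    res$state_comparisons <- nonlinear_state_tests(nl)
  }

  # ---- connectivity ---------------------------------------------------
  if ("connectivity" %in% stages) {
    conn_states <- intersect(config$connectivity_states, STATE_NAMES)
    res$delta_pli <- list()
    res$pli <- list()
    for (nm in conn_states) {
      have <- function(lst) Filter(function(p) !is.null(p$clean[[nm]]), lst)
      hc <- have(ctrl); ht <- have(traz)
      both <- intersect(names(hc), names(ht))
      if (length(both) < 2) next
      pli_c <- lapply(hc[both], function(p)
        pli_matrix(p$clean[[nm]], fs, config$bands, config$edge_trim))
      pli_t <- lapply(ht[both], function(p)
        pli_matrix(p$clean[[nm]], fs, config$bands, config$edge_trim))
      sur_c <- lapply(both, function(s)
        surrogate_pli(hc[[s]]$clean[[nm]], fs, config$bands,
                      ns = config$n_surrogates, config$edge_trim,
                      seed = derive_seed(config$seed, s, "control", nm)))
      names(sur_c) <- both
      sur_t <- lapply(both, function(s)
        surrogate_pli(ht[[s]]$clean[[nm]], fs, config$bands,
                      ns = config$n_surrogates, config$edge_trim,
                      seed = derive_seed(config$seed, s, "trazodone", nm)))
      names(sur_t) <- both
      res$pli[[nm]] <- list(control = pli_c, trazodone = pli_t)
      res$delta_pli[[nm]] <- delta_pli(pli_c, pli_t, sur_c, sur_t)
    }
  }

  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

rpsd_long <- function(values, cond, freq) {
  do.call(rbind, lapply(names(values), function(sid) {
    do.call(rbind, lapply(names(values[[sid]]), function(nm) {
      data.frame(subject_id = sid, condition = cond, state = nm,
                 freq = freq, rpsd = values[[sid]][[nm]])
    }))
  }))
}

nonlinear_condition_tests <- function(nl, config) {
  combos <- unique(nl[, c("state", "band", "metric")])
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    sel <- nl$state == combos$state[k] & nl$band == combos$band[k] &
      nl$metric == combos$metric[k]
    a <- nl[sel & nl$condition == "control", ]
    b <- nl[sel & nl$condition == "trazodone", ]
    if (nrow(a) < 2 || nrow(b) < 2) return(NULL)
    paired <- combos$state[k] %in% config$paired_states &&
      nrow(a) == nrow(b) &&
      setequal(a$subject_id, b$subject_id)
    t <- if (paired) {
      b <- b[match(a$subject_id, b$subject_id), ]
      paired_wilcoxon(a$value, b$value)
    } else {
      mann_whitney(a$value, b$value)
    }
    data.frame(state = combos$state[k], band = combos$band[k],
               metric = combos$metric[k], method = t$method,
               p = t$p_value, n_used = t$n_used, paired = t$paired)
  })
  do.call(rbind, rows)
}

nonlinear_state_tests <- function(nl) {
  out <- list()
  for (cond in unique(nl$condition)) {
    for (bnd in unique(nl$band)) {
      for (met in unique(nl$metric)) {
        sel <- nl$condition == cond & nl$band == bnd & nl$metric == met
        df <- nl[sel, c("state", "value")]
        tab <- table(df$state)
        if (length(tab) < 2 || any(tab < 2)) next
        key <- paste(cond, bnd, met, sep = "_")
        out[[key]] <- state_comparison(df)
      }
    }
  }
  out
}

#' Write pipeline results as TSV tables
#'
#' Flat, diffable outputs: one TSV per result family plus a `run_info.tsv`
#' with the seed and the main configuration values.
#'
#' @param res Result list from [run_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    if (!is.null(df) && nrow(df) > 0) {
      write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
  }
  cfg <- res$config
  info <- data.frame(
    key = c("seed", "epochs_per_state", "n_surrogates", "alpha_rpsd",
            "alpha_coherence", "package_version"),
    value = c(cfg$seed, cfg$epochs_per_state, cfg$n_surrogates,
              cfg$alpha_rpsd, cfg$alpha_coherence,
              as.character(utils::packageVersion("sleepeeg"))))
  w(info, "run_info.tsv")
  w(res$quality, "quality_summary.tsv")
  w(res$architecture, "architecture_summary.tsv")
  w(res$transitions, "transition_matrices.tsv")
  if (!is.null(res$architecture_tests)) {
    w(res$architecture_tests$metrics, "architecture_tests.tsv")
    w(res$architecture_tests$transitions, "transition_tests.tsv")
  }
  w(res$rpsd, "rpsd.tsv")
  if (!is.null(res$rpsd_tests)) {
    w(do.call(rbind, lapply(names(res$rpsd_tests), function(nm)
      cbind(state = nm, res$rpsd_tests[[nm]]$per_bin))),
      "spectral_tests.tsv")
  }
  w(res$nonlinear, "nonlinear_metrics.tsv")
  w(res$nonlinear_tests, "nonlinear_tests.tsv")
  if (!is.null(res$delta_pli)) {
    rows <- list()
    for (nm in names(res$delta_pli)) {
      for (bnd in names(res$delta_pli[[nm]])) {
        d <- res$delta_pli[[nm]][[bnd]]
        nms <- rownames(d$delta)
        ut <- which(upper.tri(d$delta), arr.ind = TRUE)
        rows[[paste(nm, bnd)]] <- data.frame(
          state = nm, band = bnd, ch_i = nms[ut[, 1]], ch_j = nms[ut[, 2]],
          delta = d$delta[ut], threshold = d$threshold[ut],
          flagged = d$flagged[ut],
          direction = ifelse(d$delta[ut] > 0, "control_increase",
                             "trazodone_increase"))
      }
    }
    w(do.call(rbind, rows), "delta_pli.tsv")
  }
  invisible(dir)
}
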