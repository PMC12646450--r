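---
title: "Quantifying sleep EEG: architecture, spectra, complexity, and connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sleep EEG: architecture, spectra, complexity, and connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepeeg)
```

## The analysis problem

`sleepeeg` implements a complete quantitative analysis of polysomnographic
sleep studies with a paired (within-subject) design: each subject is
recorded once under a control condition and once under a treatment (the
motivating use case is a sedative given to dogs napping in a lab, recorded
from four scalp electrodes — F3, F4, Fz, Cz referenced to Oz — at 400 Hz
for about two hours). Sleep is scored by experts into four behavioral
states — wakefulness (0), drowsiness (1), NREM (2), REM (3) — in 3-second
epochs, short because unsedated animals move often and switch vigilance
states faster than humans. The package answers four questions about the
treatment:

1. **Architecture** — does it change how much time is spent in each state,
   how quickly states are reached, and how the wake–sleep cycle moves
   between states?
2. **Spectrum** — does it shift the distribution of EEG power across
   frequencies within each state?
3. **Complexity** — does it change the irregularity of the signal, as
   captured by Lempel-Ziv complexity and permutation entropy?
4. **Connectivity** — does it change phase coupling and coherence between
   electrode pairs?

## Preprocessing

The continuous record is bandpassed to [1, 70] Hz and notched at 60 Hz
before epoching. Filters are 4th-order Butterworth (notch: biquad with
quality factor 30) applied forward-backward, so the effective order is
doubled and the net phase shift is zero — phase integrity matters because
the connectivity stage works on instantaneous Hilbert phases. The filter
family and order are not dictated by the scientific question; they are the
standard EEG choice and are applied zero-phase for the stated reason. The
forward-backward passes run over an odd-reflection-padded signal (3000
samples, covering the ~1 s transient of the 1 Hz edge) in compiled code.

Epoch `i` covers samples `[i*fs*3, (i+1)*fs*3)` — 0-based, half-open, 1200
samples per channel at 400 Hz — so epochs concatenate exactly. At most one
scored epoch may be only partially covered by the recording tail; it is
dropped whole, never padded, and a larger shortfall is an error.

Artifact flags come with the scoring; the package performs no automatic
artifact detection. Architecture metrics use *every* scored epoch (the
hypnogram is a property of the scoring); all signal metrics use a seeded
random sample of 5 artifact-free epochs per state, which equalizes the
data volume across states with very different retention rates. If a state
has fewer than 5 clean epochs, all of them are used and the shortfall is
reported; a state with none is treated as missing, and downstream
condition contrasts degrade from paired to unpaired tests.

## Architecture metrics

*Percent time* is the share of scored epochs per state. *Latency* is the
time to the first epoch of a state; a state never reached is censored at
the full recording duration (applied uniformly to every state, not only
REM, for a consistent contract). *Transition matrices* count consecutive
epoch pairs and row-normalize, so entry (i, j) estimates P(state j next |
state i now); the diagonal is the probability of remaining. Rows of states
never visited are undefined and are excluded from comparisons rather than
imputed.

The *Lempel-Ziv complexity of the hypnogram* treats the state sequence as
a 4-symbol string and counts the phrases of its exhaustive-history parse
(the Kaspar–Schuster production complexity). A sleeper that cycles richly
produces many novel phrases; a sedated, "sticky" hypnogram produces few.
The raw count is compared across conditions because sessions have
near-equal length; a normalized rate `c(n) log2(n)/n` is available for the
signal variant.

## Spectral metrics

One Welch engine (800-ms Hann windows, 50% overlap, mean-detrended
segments) serves both power and coherence, giving a 1.25 Hz grid — six
windows per 3-s epoch. The relative PSD divides the epoch-averaged
spectrum by its summed power in [1, 50] Hz, so reported bins sum to 1 per
channel; this removes amplitude-scale differences between subjects (skull
thickness, electrode contact) and is exactly invariant under signal
scaling. Magnitude-squared coherence uses the same windows per epoch and
averages coherence across a state's epochs.

Condition contrasts run per frequency bin: paired Wilcoxon for states
where both arms are complete (wake, drowsiness by default), Mann-Whitney
otherwise (NREM/REM, where a treated arm may lack the state). Masks use
raw p-values at alpha = 0.01 (power) and 0.05 (coherence) — reproducing
the shading convention of per-bin displays — with an optional
Benjamini-Hochberg adjustment for users who prefer FDR control across
bins.

## Complexity and entropy

Signals are split into a low [1, 16] Hz and a high [17, 50] Hz component
(an alternative [16, 45] Hz high preset ships as `band_split("alt")`; the
methods-text split is the default where the two conventions disagree).
Per epoch and channel:

- **LZC**: the signal is binarized at its median (strictly-greater → 1,
  ties → 0, so a constant signal maps to the all-zero, minimal-complexity
  sequence) and parsed by the same Kaspar–Schuster counter; reported
  normalized (`c log2 n / n`) by default so equal-length epochs compare on
  a dimensionless scale, with the raw count retained.
- **Permutation entropy**: Bandt-Pompe ordinal patterns with embedding
  dimension D = 4 and delay tau = 1 by default; series must be longer
  than D·tau. Equal values are ranked by order of occurrence (stable
  tie-break, deterministic). Entropy is Shannon entropy in bits,
  normalized by log2(D!) to [0, 1].

Values are averaged over the 5 epochs and 4 channels, one number per
subject x state x band x metric. Between-condition tests follow the same
pairing policy as the spectra; between-state contrasts within a condition
use Kruskal-Wallis followed by Dunn's pairwise z-tests. The Dunn
adjustment is Holm by default (uniformly more powerful than Bonferroni at
the same family-wise error control); Bonferroni and unadjusted variants
are available.

## Phase-lag-index connectivity

PLI is computed in five narrow bands — delta [2,4], theta [5,7], alpha
[9,11], beta [19,21], gamma [34,36] Hz — because instantaneous phase is
only meaningful for narrowband signals. Per epoch: filter, Hilbert
transform (FFT half-spectrum method), drop 5% of samples at each edge
(filter and Hilbert transients), then

PLI = | mean over t of sign( wrap(phi_x − phi_y) ) |,   sign(0) = 0,

which is 0 for inconsistent or exactly zero-lag coupling (hence
insensitive to volume-conduction-like instantaneous mixing) and 1 for a
consistently one-sided lag. Epoch matrices are averaged per state.

The condition contrast is `delta = mean over subjects of (PLI_control −
PLI_treated)`. Its significance threshold comes from a surrogate
ensemble: per subject, condition, and band, each channel's spectrum keeps
its amplitudes but receives fresh uniform phases (preserving each
channel's PSD exactly while destroying all cross-channel phase
structure), `Ns = 100` times; each surrogate yields an epoch-averaged PLI
matrix. The per-surrogate condition difference has ensemble mean
`delta_s` and standard deviation `sigma_s`, the latter pooled over
subjects and surrogates by the law of total variance. The threshold is
`Th = delta_s + sigma_s`, and an edge is reported when `|delta| > Th`,
with the direction (control- vs treatment-increase) stated explicitly.
Two points were genuinely open and are resolved as follows: the sign of
the difference is thresholded in absolute value with the direction
reported, because a one-sided rule cannot represent treatment-side
increases; and `sigma_s` is the spread of *individual* surrogate
differences, not of per-subject surrogate means — means of 100 surrogates
concentrate so sharply that their spread would flag a large fraction of
null edges, while the ensemble spread matches the scale of a real
between-condition difference under the null (the package's null-cohort
simulations confirm a false-edge rate of a few percent per band x edge
cell). An ensemble of at least 2 surrogates per subject is required, as
the SD is undefined otherwise.

The surrogate engine synthesizes analytic signals directly from the
positive half-spectrum in compiled code; spectral bins below 1e-10 of the
channel maximum are zeroed first (they carry no phase information for a
narrowband signal, and subnormal magnitudes would dominate the runtime).

## Group statistics

All condition and state comparisons are nonparametric and two-sided.
Paired Wilcoxon signed-rank tests drop zero differences (Wilcoxon's rule)
and use the exact null distribution for n <= 25 — computed by the shift
algorithm, so exactness survives tied ranks — and a tie-corrected normal
approximation above. Mann-Whitney tests are exact for small tie-free
samples. The Kolmogorov-Smirnov normality check (against a normal with
the sample's moments) is reported as a diagnostic only and never switches
the rank tests off. Statistical significance is 0.05 except for the
per-bin power masks (0.01).

## The synthetic cohort generator

No clinical recordings ship with the package; the generator produces
study-shaped data so that every stage is testable, and its defaults *are*
the study conditions: 12 subjects, both arms each, 400 Hz, four channels,
3-s epochs, 120-minute sessions.

- **Hypnograms** are first-order Markov chains (the architecture analysis
  is itself first-order; no semi-Markov bout structure in this version).
  The control matrix produces free cycling with ready REM entry; the
  treated matrix is stickier in every state, favors sustained drowsiness,
  and suppresses NREM→REM entry to 0.0004 per epoch so that roughly 60%
  of 120-minute treated sessions never reach REM — the suppression level
  is pinned by that observed absence rate.
- **EEG** is synthesized per epoch in the frequency domain: a 1/f
  background plus raised-cosine band bumps (delta-dominant NREM,
  broadband wake/REM, intermediate drowsiness) with uniform random
  phases, inverse-transformed and scaled to the state's RMS amplitude.
  Epoch boundaries are blended with 0.25-s raised-cosine crossfades so
  epochs stay internally stationary without boundary splatter.
- **Condition effects** (the `"trazodone-like"` preset): power above
  13 Hz multiplied by 1.5 in wake, drowsiness, and NREM; power below
  13 Hz reduced by 0.85 in wake and drowsiness; an added alpha-band
  Cz–Fz coupling (amplitude share 0.8, lag pi/4) in NREM. Artifact rates
  per state and arm follow the observed retention percentages (7.7 /
  41.1 / 100 / 33.5 percent clean for wake / drowsiness / NREM / REM in
  control; 17.7 / 58.9 / 100 / 53.1 treated).
- **Couplings** share a fraction of a band's drive between two channels,
  one copy phase-lagged; the fraction is an amplitude share, and the mix
  is renormalized to keep band power unchanged.
- **Between-subject variability**: each subject gets lognormal band-weight
  jitter (sdlog 0.15) shared across both arms, plus smaller per-session
  jitter (sdlog 0.05). The value is a deliberate choice: relative
  normalization already removes the dominant amplitude-scale variability
  between subjects, so what remains is spectral *shape* variability, for
  which ~15% is a realistic magnitude in a young, healthy, homogeneous
  cohort; it also keeps the paired design's power in the regime the study
  design presumes.
- A `"null"` preset generates both arms from identical parameters for
  type-I-error checks.

What the generator does *not* emulate: real artifact waveforms (epochs
are flagged, not corrupted, by default — a transient injector exists for
robustness tests), bout-duration distributions beyond geometric,
non-stationarity within epochs, volume-conduction mixing, and any
physiological coupling between the spectral and architecture effects.
Passing tests therefore demonstrate that the *estimators recover what the
generator injects at realistic effect sizes*, not that the clinical
effects themselves are reproducible.

## Numerical choices and degenerate inputs

- Epochs are 0-based half-open sample intervals; concatenating a
  session's epochs reproduces the scored span exactly.
- The EDF writer scales each channel to its own physical range; 16-bit
  quantization error is bounded by `(max − min)/65535` per channel.
- Median binarization maps ties to 0; a constant signal gives the
  all-zero sequence and the minimal phrase count of 2 (1 for a
  single-symbol sequence).
- `sign(0) = 0` in the PLI, so exactly zero-lag coupling contributes
  nothing rather than randomly.
- The analytic signal of an all-zero epoch has no phase; this raises an
  error instead of returning noise.
- Undefined transition rows, states absent from a session, and subjects
  missing an arm are all represented as missing and excluded from the
  affected contrast — never imputed as zeros.
- All randomness (epoch sampling, surrogates, generators) flows from
  explicit seeds; per-subject streams are derived deterministically from
  the master seed and the subject/condition keys, so runs are
  reproducible end to end and stages can be re-run idempotently.

## Problem sizes used by the test suite

The packaged simulations run at reduced scale, chosen once: cohort
end-to-end checks use 12 subjects x 2 arms at 10-minute sessions (200
epochs) with 20 replicates for the treatment signature and for type-I
control, 5 matched null cohorts for the false-edge rate, and the full
`Ns = 100` surrogate ensemble restricted to the NREM state where the
connectivity effect is injected. Architecture-only analyses (hypnograms
are cheap) additionally run at the full 120-minute length in the
reproduction script. Oracle-equivalence suites enumerate all 8190 binary
strings up to length 12 for the LZ parser and large random batches for
the entropy, PLI, and rank-test oracles.

## Known limitations

- The pipeline consumes expert scorings; it does not stage sleep.
- Five narrow 2-Hz PLI bands are presets, not adaptive; band edges
  between the spectral annotations and the nonlinear split follow the
  methods conventions they mirror.
- The epoch-averaged |PLI| estimator is biased upward for short epochs
  (about 0.27 for a 3-s alpha-band epoch under independence); the
  surrogate threshold shares the bias, so contrasts remain calibrated,
  but absolute PLI values should not be compared across epoch lengths.
- The per-bin spectral masks deliberately forgo multiplicity correction
  to mirror the shading convention; the BH option is the safer default
  for confirmatory use.
- EDF support covers the single-rate 16-bit layout the package writes;
  exotic EDF variants are out of scope.
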