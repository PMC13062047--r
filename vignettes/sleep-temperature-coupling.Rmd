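---
title: "Sleep–temperature coupling analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep–temperature coupling analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In rodents, the transition from wakefulness into NREM sleep is normally
coupled to two physiological signatures: a surge of cortical delta
(0.5–4 Hz) power and a small drop in core body temperature. Mouse models
of Dravet syndrome (SCN1A haploinsufficiency) show both signatures
attenuated: the delta contribution at NREM onset barely changes relative
to wake, far fewer NREM onsets coincide with a temperature reduction,
and a warm environment fails to promote NREM sleep the way it does in
wild-type animals. `somnotherm` packages the complete analysis chain
needed to quantify these phenotypes from multichannel
electrophysiology — rule-based vigilance scoring, transition-locked
spectral statistics, event-locked temperature-change classification, and
the group-level exact and ANOVA statistics — together with a synthetic
polysomnography generator whose genotype presets encode the phenotypes,
so every stage is testable end to end without animal recordings.

All empirical statements in this vignette are properties the package's
test suite or `scripts/acceptance.R` actually computes.

## The synthetic generator

The generator is first-class, tested code, not a fixture. A
`genotype_preset` bundles everything that differs between groups.

### Vigilance-state bout model

States follow an alternating-renewal (semi-Markov) process on the 5-s
epoch grid: bout lengths are exponential with per-state means
(wake 150 s, NREM 120 s, REM 60 s by default), truncated at one epoch,
and the next state is drawn from an embedded entry chain. REM is entered
only from NREM and rarely (probability 0.02): the short daytime
recordings this models essentially never reach REM, so the REM fraction
defaults near zero. The chain starts from its stationary occupancy
rather than a fixed state, so the first ambient block is not biased
toward wake.

The long-run fraction of time in state $i$ has the closed form
$\pi_i = \nu_i m_i / \sum_j \nu_j m_j$, with $\nu$ the stationary
distribution of the entry chain and $m_i$ the mean bout length. The
Monte-Carlo occupancy tests compare simulated fractions to this formula.

Warmth-induced somnogenesis is encoded in the entry chain, not in the
bout lengths: inside a WARM block a NREM self-re-entry probability $q$
is introduced (at bout end a fresh NREM bout starts with probability
$q$), and $q$ is solved numerically so that stationary NREM occupancy
rises by exactly `warm_nrem_boost` (0.15 for the WT and rescued presets,
0 for the Dravet preset, matching its absent warmth response). Among the
several entry-probability encodings, self-re-entry was chosen because it
keeps the occupancy analytic and perturbs nothing else.

### Signals

The ECoG/LFP channel is pink-noise background (25 µV RMS, 1/f spectrum
flattened below 0.5 Hz) plus state-gated narrowband components, built by
FFT-domain shaping so synthesis is exactly reproducible from the seed:

* **NREM delta**: 0.5–4 Hz noise whose power is chosen so NREM delta
  band power equals `nrem_delta_gain`² times the background (wake) delta
  power. The WT preset uses gain 3; the Dravet preset uses gain 1 — no
  surge at all, mirroring its flat wake/NREM delta ratio; the rescued
  preset uses 2.5.
* **REM theta**: 4–8 Hz noise at 6× the background delta power, which
  puts the per-epoch theta/delta ratio comfortably above the 2.5 REM
  criterion.

The EMG channel is 20–100 Hz noise with per-state RMS (wake 30 µV,
NREM 8 µV, REM 5 µV). State gates cross-fade over 1 s (triangular
kernel) so amplitudes are continuous at boundaries. Default sampling is
250 Hz — above twice the 99 Hz analysis ceiling — and configurable up to
the acquisition-matched 1 kHz.

### Temperature

A 1 Hz trace: baseline (37.0 °C for WT; 36.2 °C for the Dravet presets —
the reduced-baseline magnitude is a free modeling choice, never asserted
against any reference) plus a slow sinusoidal drift (0.05 °C amplitude,
30 min period, random phase) and Gaussian measurement noise
(0.02 °C SD). Independently at each NREM onset, with probability
`temp_drop_prob` (0.65 WT, 0.21 DS), the bout carries a drop: a first-order
relaxation toward `temp_drop_magnitude_c` (0.4 °C; the printed sources for
this quantity are graphical only, so 0.3–0.5 °C is a modeling range)
with time constant 60 s while the bout lasts, relaxing back afterwards.
The generator records which onsets received drops, giving downstream
classification an exact oracle.

### Interictal spikes

Biphasic Gaussian-derivative transients (60 ms support, width parameter
8 ms) at homogeneous-Poisson times, peak amplitude 6× the robust SD of
the clean channel. The WT preset injects none; the Dravet presets use
2/min.

## Spectral analysis

`compute_psd` is a Welch estimator: Hann-windowed, 50%-overlapped
segments, each mean-removed before windowing (the detrend prevents DC
leakage into delta), one-sided density scaled so that
$\int S(f)\,df$ equals the mean square of the detrended input (the
Parseval contract, tested at 2% on tones and noise). The segment length
is 5 s — matching the scoring epoch, 0.2 Hz resolution; a 30-s analysis
window yields 11 overlapped segments. Band powers use a bin-center
convention: a bin belongs to a band iff its center lies in the closed
interval, so the 0.9–3.9 Hz ratio band effectively spans bins 1.0
through 3.8 Hz.

Two delta bands coexist deliberately and are never conflated:

* **0.5–4 Hz** — the display/classification band (epoch features, the
  virtual delta channel);
* **0.9–3.9 Hz over a 0.9–99 Hz total** — the reported `delta_ratio`.
  For flat spectra this ratio is analytically 15/491 ≈ 0.0306 on the
  0.2 Hz grid, one of the test anchors.

Which band the original visual scorers' delta feature corresponds to is
unknowable; the classifier uses the display band and the reported
statistic uses the ratio band.

## Vigilance scoring

Per 5-s epoch the features are delta/theta/total band powers of the
signal channel and the RMS of the 20–100 Hz band-passed EMG. Thresholds
are fit automatically (the original dual-human visual scoring is not
reproducible):

* **EMG wake threshold**: exact Otsu split of log EMG RMS.
* **NREM delta threshold**: Otsu split of log delta power restricted to
  low-EMG epochs, *guarded by a bimodality check*. The optimal Otsu
  split of a unimodal Gaussian still explains ≈ 64% of the variance, so
  a blind split would bisect the NREM mode whenever the low-EMG epochs
  are spectrally homogeneous — exactly the situation in recordings
  without a delta surge, where EMG must carry the classification. If the
  separation score falls below 0.75 (two modes ≥ 3.5 SD apart exceed
  this), the delta gate is disabled by placing the threshold below the
  observed range, and scoring becomes EMG-led.

Both splits act on logs, so thresholds are equivariant under rescaling.

The decision cascade is deterministic and total — artifact flag → WAKE
if EMG exceeds the wake threshold (muscle tone is the primary wake
discriminator) → REM if theta/delta > 2.5 (EMG is already low at this
point in the cascade) → NREM if delta exceeds its threshold → quiet
wake. Artifacts are epochs whose peak amplitude exceeds 8 robust SDs of
the channel or whose total power exceeds the 99.9th percentile.

**The 20-s alternation rule.** Runs of wake or NREM no longer than 20 s
(4 epochs, inclusive) are *short*. Within a maximal block of consecutive
short runs, the states genuinely alternate when the block holds at least
three runs — some state then recurs within 20 s — and all its epochs are
relabeled TRANSITION. A single clean switch (two runs) is not
alternation; stable runs and other labels bound the blocks and are never
touched. This reading keeps a clean wake→NREM switch intact while
relabeling any W/N/W or N/W/N flicker, and it is idempotent. The test
suite checks it against an independently coded oracle on every wake/NREM
label string up to length 8.

`score_agreement` exists so two scorer parameterizations can emulate the
two-investigator consensus (percent agreement, mutually agreed mask);
artifact epochs leave the denominator.

## Transition-locked analysis

Eligibility is forced by the PSD window geometry: an NREM onset
qualifies when ≥ 120 s of contiguous wake precede it (TRANSITION epochs
tolerated in the final 20 s) and ≥ 90 s of contiguous NREM follow, and
retained onsets have non-overlapping analysis windows. The wake PSD
comes from the 30 s starting 2 min before the onset, the NREM PSD from
the 30 s starting 1 min into NREM; if the wake window overlaps an
artifact epoch it slides earlier in 5-s steps up to 30 s, else the event
is dropped with a logged reason. Per-subject averaging precedes group
averaging, so each animal contributes one value.

**Temperature classification.** Baseline is the mean over the 60 s
before onset, post the mean over 60–180 s after; the change is
`negative` below −ε, `positive` above +ε, else `unchanged`, with
ε = 0.1 °C. The windows and ε are this module's own definition of
"unchanged" — no published definition exists — and are configurable.
With generator noise off and ε = 0.05 the class equals the injected drop
indicator for every event (tested); with default noise the end-to-end
misclassification rate is about 1%, so cohort-level percentages are
dominated by the binomial sampling of drop injection, as they should be.

## Statistics

* `fisher_exact_rxc` implements the Freeman–Halton extension from the
  definition: full enumeration of tables with the observed margins,
  two-sided p = total probability of tables no more probable than the
  observed one. It matches `stats::fisher.test` (the independent
  cross-check, never the implementation) to 10⁻⁷ on hundreds of random
  small tables, and a seeded Monte-Carlo mode (Patefield sampling via
  `r2dtable`) covers tables beyond the enumeration budget. Empty rows or
  columns are rejected; pipeline code drops temperature classes observed
  in neither group before testing.
* `holm_sidak` applies the step-down formula
  $\tilde p_{(i)} = \max_{j \le i}\,[1-(1-p_{(j)})^{m-j+1}]$, clipped at
  1, returned in input order.
* `two_way_anova` is the one deliberately delegated computation
  (`stats::aov`; Type II sums of squares via `car::Anova` for unbalanced
  between-subjects designs; an `Error(subject)` stratum for the
  within-subject ambient-block factor). Both repeated and non-repeated
  modes are exposed because the original analyses do not state the
  treatment uniformly.
* The spike detector thresholds the 20–80 Hz-emphasized signal at 5
  robust SDs with 200 ms refractory merging.
* A generic `exclude_start_s` argument on the warmth analysis covers
  protocol exclusions at block start (e.g. drug-absorption windows),
  rather than drug-specific logic.

## Problem sizes and reproduction

The replication experiments run on desk-scale cohorts chosen to mirror
the reference group sizes: a 6-subject WT cohort (2.17 h sessions) and
an 8-subject DS cohort (2.5 h sessions) at room temperature, tuned so
the eligibility rule yields on the order of 34 and 37 transitions, and
7 subjects per preset with 1 h RT + 1 h warm blocks for the
warmth-somnogenesis analysis — all at 250 Hz. With ~35 eligible
transitions per cohort the negative-class percentage carries a binomial
standard error of ~8 percentage points, which is the tolerance scale at
which single-cohort recovery of the 65%/21% coupling parameters is
assessed (±2 SE).

## What the synthetic data does and does not show

Passing tests demonstrate that the pipeline recovers known generator
parameters through the full scoring → detection → classification chain,
that the spectral and exact-test machinery matches analytic and
enumerative oracles, and that the decision rules implement their stated
semantics. They do not demonstrate performance on real recordings: the
generator has stationary Gaussian backgrounds, sharply separated EMG
modes, no movement artifacts beyond amplitude outliers, no arousals, no
ictal events, no electrode drift, and no circadian structure. Automatic
Otsu thresholds stand in for dual-human consensus scoring; on real data
the agreement machinery exists precisely because thresholds are not
trustworthy a priori. The REM criterion is implemented but essentially
unexercised at cohort level, since the emulated recordings rarely reach
REM.
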