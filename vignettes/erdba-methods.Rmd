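---
title: "Methods: ER-DBA, omission ERPs and signal detection in missing-oddball tapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ER-DBA, omission ERPs and signal detection in missing-oddball tapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures the package implements,
the parameters that matter and their defaults, the design choices made
where the methodology was genuinely open, and what the synthetic-data
tests do and do not establish about real recordings.

## The paradigm and its data model

Two cued-tapping tasks are modeled. Task 1 presents a regular sequence of
120 pulses at a 1000-ms inter-stimulus interval (ISI); Task 2 presents 300
slots of which 45 are randomly omitted (missing-oddball). A
`pulse_sequence` stores, per slot, the onset (ms), kind (real/missing),
and three derived annotations: `lag_post` (count of slots since the
nearest preceding omission; 0 at an omission), `lag_pre` (negative count
to the nearest following omission), and `segment_M` (number of real pulses
in the inter-omission segment a slot belongs to). A slot between two
omissions carries both lag labels, and lag-indexed summaries count it
under both — mirroring how lag-locked profiles are tabulated per omission.

Omission placement: omissions are drawn uniformly over all feasible sets
with a minimum slot separation (default 2, i.e. no adjacent omissions;
configurable to 1) and with the first and last slots forced real, so every
omission has flanking real pulses and the lag/M annotation is total. The
uniform draw uses the standard combinatorial reduction (sample from the
shrunk index space, then re-expand), so no rejection loop is needed.

## Behavior: matching, classification, dual-lobe decomposition

Taps are assigned to the unique slot whose half-open window
`[onset − 500, onset + 500)` ms contains them; with a 1000-ms ISI the
windows partition time. The first tap per slot counts; extras and
out-of-window taps are tallied but not assigned.

The pooled real-pulse RT distribution is bimodal: a proactive lobe near
−50 ms and a reactive lobe near +200 ms. `kde_density()` evaluates a
Gaussian-kernel density (Silverman's rule bandwidth unless given) on a
1-ms grid over [−500, 500]. `decompose_dual_lobe()` ranks local maxima by
height and declares bimodality when the valley between the two tallest
peaks dips at least 5% below the lower peak — a guard against calling
sampling wiggles a second mode. The antimode (density minimum between the
peaks) is the proactive/reactive boundary; when the density is unimodal
the boundary falls back to +100 ms, the critical RT above which proactive
(false-hit) responses are essentially absent. "Population heights" are
taken literally as the density heights at the two peaks, giving
CHR = P_C/(P_C + P_F); lobe masses are also reported (`weight_pro`,
computed as density mass left of the antimode) for diagnostics.

## Signal detection

The modified indices are implemented exactly as defined:
`d' = Z(CHR) − Z(CRR)` and `c = −½(Z(CHR) + Z(CRR))`, with CRR = 1 − FAR
from the missing slots. This differs from classical equal-variance SDT,
which would put the false-alarm rate in the second term; the classical
form is available via `sdt_indices(..., classical = TRUE)` for
comparison. Degenerate rates are clipped by the 1/(2n) rule (0 → 1/(2n),
1 → 1 − 1/(2n)) before the quantile transform; clipping never moves a
rate across 0.5. `rates_from_indices()` is the exact algebraic inverse
(chr = Φ(d′/2 − c), crr = Φ(−d′/2 − c)) and exists so that simulations
can round-trip the formulas to numerical precision.

For lag profiles, the lag-specific CHR uses the CH/(CH+FH) count ratio at
that lag (the same quantity the lag-locked CH-ratio histograms show);
KDE heights are impractical at per-lag trial counts. The global CRR of
the participant pairs with each lag's CHR.

## The ER-DBA chain

The DBA index series is computed exactly as the recipe prescribes:

1. O1 and O2 referenced recordings at 256 samples/s are band-passed
   10–13 Hz with a third-order Butterworth filter. The filter is applied
   forward–backward (`signal::filtfilt`), i.e. zero-phase, so dip and
   component latencies are not biased by group delay; the effective
   magnitude order doubles. The ERP branch uses the same design at
   0.01–45 Hz — the 0.01-Hz edge is implemented as stated even though a
   9-s epoch limits its practical effect.
2. The band signal is rectified and averaged over non-overlapping blocks
   of 8 samples, which realizes the 8-point moving average and the
   256 → 32 samples/s decimation in one step (the block mean is the
   moving average sampled on the decimation grid). Rectification leaves a
   residual ripple at twice the carrier frequency; oracles and tolerances
   account for it rather than pretending an analytic envelope was used.
3. Per-channel amplitude streams are squared to power (μV²) and averaged
   across O1 and O2 ("mean actual power"). Averaging power rather than
   amplitude keeps phase-independent channel differences visible; a gain
   g on the raw EEG scales the index by g², which the tests assert.

Epochs span [−1000, 8000) ms around each slot-onset marker (288 samples at
32 SPS); markers whose window exceeds the recording are dropped and
counted. Artifact rejection is a deterministic single pass: the per-epoch
statistic is the maximum absolute deviation from the epoch's own mean, and
epochs whose statistic exceeds mean + 3·SD across epochs are flagged. The
underlying study left the exact statistic unspecified (and additionally
used visual inspection, which this package deliberately replaces with the
automated rule alone); max-deviation was chosen because it is sensitive to
burst artifacts and fully reproducible. Grand averages subtract each
epoch's own baseline mean ([−500, 0] ms for DBA, [−200, 0] ms for ERP)
and report pointwise SEM.

Envelope normalization builds upper and lower envelopes by natural cubic
interpolation through interior local extrema, keeping only extrema whose
prominence reaches 25% of the trace range so that the envelopes track the
slow event-locked excursion and not sample-level ripple; edges are
extended with the nearest extremum value. The normalization constant is
the median over time of the midline (upper + lower)/2 — the midline
reading of "median of the upper and lower envelopes"; the alternative
(median of the pooled envelope traces) is recoverable from the returned
envelopes. The excursion amplitude Δ is the median of (upper − lower).

ERD/ERS classification uses the mean power in a test window minus the
epoch's baseline-window mean. Against baseline alone this statistic is
contaminated by modulation leaking from neighboring pulses (the epoch
windows overlap at a 1000-ms ISI), so condition contrasts — negative- vs
positive-RT taps, avoid vs erroneous tap — are tested with a Welch t-test
between the two conditions' per-epoch statistics, which cancels the
shared leakage. The pipeline's test window is [−200, 400] ms, covering
the proactive pre-tap dip and the reactive/avoid post-onset rise.

## ERP stage

Cz is filtered 0.01–45 Hz, epoched, cleaned and averaged per category as
above. Components are read as signed extrema in configurable windows
(defaults: P1 40–80, N1 80–150, P2 150–250, N2 250–480, LPC 480–800 ms);
a component is "present" when its amplitude exceeds 2×SEM at its latency
and has the correct sign — an explicit, automated stand-in for visual
inspection. CNV is the mean amplitude over the 200 ms preceding the next
expected onset. The omission components oN1 and oP2 are sought at the
latencies of the real-pulse P2 and N2 (windows 150–250 and 300–480 ms):
the omission response is approximately a polarity reversal of the
real-pulse trace, so its negative and positive deflections align with the
real trace's positive and negative ones. The reversal itself is scored as
the Pearson correlation between the missing- and real-pulse traces over a
common window (default 100–500 ms in the pipeline): −1 is a perfect
reversal.

## Statistics

One-way ANOVA (F, p, η² = SSB/(SSB+SSW)), the Holm–Šidák step-down
procedure (i-th sorted p tested against 1 − (1−α)^{1/(m−i+1)}, stopping at
the first failure), Pearson correlation with regression-style indices
(F = r²(n−2)/(1−r²), η² = r²), and a Welch t-test with post-hoc power from
the noncentral t distribution at the observed effect. The t-test defaults
to the unequal-variance form because the sources are unbalanced trial
groups; the power method (noncentral t at the observed noncentrality) is
the package's choice where none was specified. Planning formulas use
ceilings throughout: N = ⌈(z·SD/(Δ·fraction))²⌉ and participant counts
⌈⌈N/epochs-per-participant⌉/(1 − exclusion)⌉, which reproduces the
279 → 21 → 30 chain from Δ = 1.95 μV², SD = 5.53 μV², 13.5 expected false
alarms per participant and a 0.3 exclusion rate. (The intermediate
divisor is taken as 13.5 = 45 × 0.3; the published shorthand "279/19"
does not reproduce its own quoted results, 21 and 30, which the ceiling
chain does.)

## The synthetic cohort: what it emulates

The generator exists so that every stage has a testable input with known
ground truth. Per participant it draws a profile and produces:

* **Behavior.** Real slots tap with probability 1 − miss_rate
  (miss_rate 0.03), in proactive or reactive mode; the proactive weight
  follows a lag-dependent curve whose default mirrors the observed
  CH-ratio trajectory around omissions (strongly reactive at lag 1,
  drifting back toward proactive dominance). RTs are Gaussian,
  N(−50, 40²) ms proactive and N(+200, 40²) ms reactive — the peak
  locations are the reported ones, the common σ = 40 ms is a package
  choice made once so the lobes are separable by the KDE antimode.
  Missing slots tap (false alarm) with per-participant probability
  far ~ U(0.1, 0.6) (the study reports only the 0.3 planning value; the
  range is a package choice that spans it), with RTs centered at the
  event onset (0 ms), matching the single-lobe missing-pulse RT
  distribution. RT draws are truncated to (−480, 480) ms so every
  generated tap falls in its slot's matching window and ground-truth
  recovery is exact.
* **Occipital EEG.** A sinusoidal alpha-2 carrier (frequency per
  participant ~ U(10, 13) Hz) with multiplicative event-locked amplitude
  modulation: Gaussian dips (σ = 150 ms) at proactive tap times, Gaussian
  gains at reactive tap times and at avoided-omission onsets. The carrier
  phase diffuses at 2 rad/√s: real alpha has a finite coherence time, and
  without dephasing the rectification ripple of a carrier commensurate
  with the 1000-ms grid would be phase-locked across epochs — an artifact
  no real recording shows. Two-stage amplitude calibration, done once
  from the generator's own recipe: (i) the end-to-end gain of the DBA
  chain for a unit dephased carrier, averaged over the alpha band, was
  measured as g = 0.296, setting the base amplitude A = √(4.993/g) =
  4.11 μV so the baseline index sits near 5 μV²; (ii) the 3-Hz-wide
  bandpass transmits only ≈ 0.6 of a σ = 150 ms modulation's depth, so
  the default depth 0.33 yields an effective ≈ 0.20 and a grand-average
  excursion Δ ≈ 1.95 μV², the planning value.
* **Cz EEG.** Late-auditory component templates (Gaussians; P1 +2 μV at
  60 ms, N1 −5 at 100, P2 +4 at 200, N2 −3 at 350, LPC +3 at 600) on
  every presented real pulse; omission templates oN1 −3 μV at 200 ms and
  oP2 +3 at 400 ms on false alarms, oP2 only on correct rejections — the
  placement that makes the false-alarm trace an approximate reversal of
  the real-pulse trace.
* **Noise and artifacts.** 1/f background with a white floor (broadband
  SD 4 μV, configurable) and Hann-windowed broadband bursts (200 ms,
  200 μV scale, 0.5/min) that the 3-SD rule flags by construction. The
  pooled trial SD is configurable through `noise_sd`; the default
  prioritizes calibrated excursion recovery over matching the planning
  SD of 5.53 μV², which depends on physiological variance sources the
  generator does not model.

Event times are stored as real-valued ms; the 512-Hz event-channel
quantization is applied only when exporting tap logs.

What passing tests do **not** show: the generator's alpha is a single
dephased sinusoid, not a broadband rhythm with amplitude dynamics; its
artifacts are one burst family, not the taxonomy of blinks and EMG; ERP
templates are fixed Gaussians. Tests therefore validate the *pipeline* —
that it recovers what was injected at the stated tolerances — not any
claim about human physiology.

## Numerical choices and degenerate inputs

* Epoch windows are half-open `[t_min, t_max)`; 0 ms is the marker sample.
* Fewer than 3 epochs: rejection is skipped with a warning, never an error.
* Zero-SD rejection statistics flag nothing (identical epochs pass).
* All-rejected categories raise an explicit error at averaging.
* A flat trace normalizes to 1 with Δ = 0; zero-variance traces make the
  reversal score an explicit error rather than NaN.
* `required_participants()` subtracts 1e-9 before the ceiling so exact
  ratios (21/0.7 = 30) are not promoted by floating-point fuzz.
* EEG is serialized as plain CSV (time column plus one column per
  channel); the package's container is format-agnostic and a different
  on-disk format only needs a reader producing an `eeg_recording`.

## Problem sizes used by the tests and acceptance script

Unit tests run on short sequences (20–120 slots) and small cohorts (2–6
participants); the acceptance checks use the design's own sizes — a
33-participant cohort for the full pipeline patterns and for excursion
recovery (per-participant alpha-frequency draws make the DBA gain vary,
and 33 participants average it out), n = 2000 taps for KDE peak recovery,
and 500-point grids for the SDT round trip. The complete suite and the
acceptance script each finish in about half a minute on one CPU.

## Known limitations

* The d′/c formulas are reproduced as defined, including CRR inside d′;
  comparisons with classical SDT literature need the `classical` flag.
* Ordinary (between-group) one-way ANOVA is used for lag comparisons,
  matching the source methodology, although lags are within-participant.
* The dip "dissolution time" is approximated by the post-dip midline
  re-crossing; it is a heuristic and labeled as such in the feature set.
* The 0.01-Hz high-pass edge is nominal over 9-s epochs.
* Envelope normalization assumes at least one full modulation cycle in
  the trace; shorter traces return the flat-trace fallback.
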