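# erdba

Analysis pipeline for **missing-oddball cued finger-tapping** experiments
with EEG: the event-related deep-brain activity (ER-DBA) method on
occipital alpha-2 power, an omission-response ERP pipeline at Cz,
kernel-density decomposition of bimodal reaction-time distributions, and
modified signal-detection indices — together with a synthetic-cohort
generator so the whole chain can be exercised and validated without any
recorded data.

## The scientific problem

In sensorimotor synchronization, people tap along with an isochronous pulse
train in two distinguishable modes: **proactive** taps anticipate the pulse
(negative mean asynchrony, reaction times clustering near −50 ms) and
**reactive** taps follow it (near +200 ms). When pulses are occasionally and
silently omitted (a missing-oddball design, e.g. 45 omissions among 300
slots at a 1000-ms inter-stimulus interval), proactive control produces
erroneous taps at omissions (false alarms) while reactive control avoids
them. The balance between the two modes shifts pulse by pulse around each
omission, and that shift is visible in three measurements this package
implements:

1. **Behavior.** Taps are matched to pulse slots in a ±500 ms window and
   classified as correct hit (CH, reactive tap to a real pulse), false hit
   (FH, proactive tap), miss, false alarm (FA, tap at an omission), or
   correct rejection (CR). The pooled RT distribution is decomposed by
   Gaussian-kernel density estimation into the two lobes; the antimode
   between the lobe peaks separates modes, and the lobe heights
   P<sub>F</sub>, P<sub>C</sub> define the correct-hit ratio
   CHR = P<sub>C</sub> / (P<sub>C</sub> + P<sub>F</sub>).

2. **Signal detection.** With CRR = 1 − FAR over the missing slots, the
   package computes the modified indices

   d′ = Z(CHR) − Z(CRR)   c = −½ (Z(CHR) + Z(CRR))

   where Z is the standard-normal quantile (rates clipped by the 1/(2n)
   rule). Note these use CRR, not the false-alarm rate, inside d′ — the
   classical form is available behind a flag. Both indices are profiled by
   lag number N, the position of a slot relative to its nearest omission
   (N = 0 at the omission).

3. **EEG.** The **DBA index** is the mean power (μV²) of the occipital
   alpha-2 (10–13 Hz) amplitude streams: O1 and O2 are band-passed with a
   third-order zero-phase Butterworth filter, rectified, smoothed with an
   8-point moving average and decimated to 32 samples/s, squared, and
   averaged across channels. Stimulus-locked epochs (−1000…8000 ms) are
   cleaned by a 3-SD artifact rule and grand-averaged per behavioral
   category with SEM bands; dips mark deactivation (ERD, proactive trials)
   and rises activation (ERS, reactive/avoid trials). A parallel ERP
   pipeline (Cz, 0.01–45 Hz) extracts late auditory components (P1, N1,
   P2, N2, LPC) and scores omission responses — the missing-pulse trace is
   approximately a polarity reversal of the real-pulse trace.

The power-analysis chain used to size such a study is also implemented:
with excursion amplitude Δ = 1.95 μV², pooled SD = 5.53 μV², z = 1.96 and a
Δ/3 resolvable difference, the required epoch count is
N = ⌈(1.96 · 5.53/(1.95/3))²⌉ = 279; at 13.5 expected false alarms per
participant that yields ⌈279/13.5⌉ = 21 participants, inflated to 30 at a
0.3 exclusion rate.

Since no public dataset exists for this paradigm, the package includes a
first-class **synthetic cohort generator** (`generate_cohort()`): shared
stimulus sequences, per-participant RT mixtures, false-alarm rates,
alpha-2 carriers with event-locked amplitude modulation and phase
diffusion, ERP/omission templates, 1/f background and artifact bursts —
every piece configurable, with trial-level ground truth recorded.

## Worked example

```r
library(erdba)
cfg <- default_config()
cfg$n_participants <- 8          # 33 in the full design
coh <- generate_cohort(cfg, seed = 42)
res <- run_analyze(coh)

res$behavior$decomposition[c("peak_rt_pro", "peak_rt_rea", "antimode")]
#> proactive peak -52 ms | reactive peak 197 ms | antimode 65 ms

subset(res$behavior$lag_profile, lag %in% -1:2)[, c("lag","n","mean_rt","ch_ratio")]
#>   lag   n mean_rt ch_ratio
#>    -1 360 138.385    0.765
#>     0 360   2.662       NA
#>     1 360 177.019    0.903
#>     2 296 100.602    0.622

subset(res$sdt$per_lag, lag %in% c(-1, 1, 2))[, c("lag","d_prime","criterion_c")]
#>   lag d_prime criterion_c
#>    -1   0.405      -0.537
#>     1   0.993      -0.831
#>     2  -0.019      -0.325

res$dba$erd_ers$hit_neg   # ERD, p = 8.4e-59 (proactive taps deactivate)
res$dba$erd_ers$CR        # ERS, p = 3.3e-10 (avoidance activates)
res$erp$reversal_score    # -0.704 (omission trace reverses the real-pulse ERP)
```

Reading the output: the pooled RT density is bimodal with lobes at −52 and
+197 ms; tapping right after an omission (lag 1) is strongly reactive
(CH ratio 0.90, mean RT 177 ms), which maximizes d′ and minimizes the
criterion c there; occipital alpha-2 power drops before proactive taps
(ERD) and rises on avoided omissions (ERS); and the false-alarm ERP trace
anticorrelates with the real-pulse trace (omission response).

`run_simulate(cfg, seed, outdir)` writes the cohort to plain CSV (events,
taps, ground truth, EEG) with a hash manifest, and `run_analyze(...,
outdir =)` serializes metrics JSON and trace CSVs.

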