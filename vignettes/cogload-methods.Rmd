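---
title: "Methods: event-locked workload analysis and its synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-locked workload analysis and its synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogload)
```

# The experimental model

`cogload` analyses a within-subject workload experiment: each participant
completes a 1-back (low workload) and a 2-back (high workload) letter block
on the same session timeline — a 10 s eyes-open rest, the first block, a
5 s rest, the second block — while a four-channel EEG headband (TP9, AF7,
AF8, TP10), an eye tracker, and the task server record in parallel. Block
order is counterbalanced by participant-ID parity (odd IDs: low block
first). All three streams share a Unix-seconds clock; the task log's letter
onsets and response times anchor every event-locked window. Intervals are
half-open `[start, end)` throughout.

The two experiment letter sequences are fixed (`nback_sequences()`) and are
constructed so that, scored at their respective N levels, they produce the
*identical* 20-entry match/non-match response key. `derive_response_key()`
re-derives that key from the letters; the package treats the letters as the
authoritative definition of correctness, because the two blocks derive the
same key independently, which is exactly the design intent of the paired
sequences. Each stimulus stays on screen at most 3,000 ms; a trial with no
response inside the timeout is scored incorrect and contributes no reaction
time. Accuracy rate is correct inputs over *scoreable* inputs — the first
N stimuli of a block have no N-back reference and are excluded from the
denominator.

# ERD/ERS quantification

For each trial, channel and band, the pipeline computes

$$\mathrm{ERD/ERS} = \frac{R - A}{R},$$

with $A$ the mean squared band-filtered amplitude from letter onset to the
response (the activation window, at most 3 s) and $R$ the same quantity in
a reference window. Both the fraction and the percentage (×100) are
reported. Negative values mean band power rose above baseline — the
direction Alpha and Beta move under increasing load — and positive values
mean it fell. The package evaluates the formula literally and carries that
sign reading as metadata rather than renaming either direction, because
the workload literature attaches the ERD/ERS labels inconsistently.

Two reference strategies are implemented:

* **near** — the 200 ms immediately preceding each letter onset (the
  default, one baseline per trial);
* **away** — a single 3 s segment at the start of the eyes-open rest,
  shared by all trials (the strategy available when per-stimulus baselines
  are impossible, e.g. free interaction with an application).

Quantification follows the classical four steps: band-pass filtering,
squaring to instantaneous power, then averaging within each event-locked
window (the per-trial fractions are averaged per condition). Filtering is
a zero-phase 4th-order Butterworth band-pass applied forward–backward
(`signal::filtfilt`), with default edges Theta 4–8 Hz, Alpha 8–13 Hz,
Beta 13–30 Hz — conventional boundaries, all configurable — and an optional
50/60 Hz Butterworth notch for mains interference. Trials whose windows
contain no samples, or whose reference power is non-positive, are excluded
and counted per (channel, band); the exclusion report is a first-class
output because per-measure Ns legitimately differ.

## Numerical behaviour at window edges

A zero-phase band-limited filter cannot follow an instantaneous amplitude
change; power crossfades over roughly the reciprocal bandwidth (~0.1 s for
an 8–13 Hz band). Two consequences are worth knowing:

* estimates of an injected fractional power change $d$ are biased toward
  zero by a few percent of $d$ on 1–3 s activation windows, and somewhat
  more in near-baseline mode because the 200 ms reference window abuts the
  onset transition (measured: ~0.26 recovered for an injected 0.3 on Alpha
  with realistic reaction times);
* a window placed on the very first samples of a recording additionally
  sees the filter's startup transient. The synthetic recorder therefore
  starts 2 s before the rest marker — as a physical device does — so the
  away baseline never sits on startup samples.

Degenerate inputs error loudly rather than propagate: a non-positive
reference power is an `undefined-baseline` error (never a silent infinity),
an empty window an `insufficient-data` error, and a response before onset a
`data-integrity` error.

# Eye movement and pupillometry

Per-stimulus interval metrics (onset to response) comprise mean and maximum
baseline-subtracted pupil dilation per eye (mm), mean and maximum fixation
and saccade durations (ms), and fixation/saccade counts per second. The
pupil baseline is the per-eye mean diameter over the valid samples of the
10 s eyes-open rest (a per-trial pre-stimulus baseline is available as an
option); both dilation and raw diameter are emitted so either convention
can be tabulated. Events are assigned to the interval containing their
*start* time — the tie-break is arbitrary for events straddling an edge and
is therefore documented; metrics with no contributing events or samples are
`NA`, never zero.

When vendor fixation/saccade events are absent, `ivt_detect()` classifies
inter-sample velocities against a 30 deg/s threshold with a 60 ms minimum
fixation (vendor-typical defaults); invalid samples and timestamp gaps
break events, and screen geometry (`px_per_deg`) is required because the
threshold is angular.

Capture rate is the valid-sample fraction; the default validity policy
requires both eyes (per-eye policies available). Participant screening
keeps capture rates at or above 0.6 — the threshold is configurable and
always restated in the screening report, since the modelled study kept 18
of 30 participants without publishing its cutoff. The astigmatism
covariate is the two-eye mean degree.

# The statistical layer

A Shapiro–Wilk gate (`p < 0.05`) routes measures to the nonparametric
path; reaction times and most psychophysiological measures fail normality,
so the workhorse is the Mann–Whitney–Wilcoxon test with the reporting
convention `W = sum of the pooled-sample ranks of the first sample`
(equivalently `U + n1(n1+1)/2`). Ties receive midranks. The two-sided
p-value is exact — from the enumerated null rank-sum distribution — when
`n1 + n2 ≤ 16` and the pooled sample is tie-free, and otherwise uses the
normal approximation with tie-corrected variance and a 0.5 continuity
correction. Spearman's rho is the Pearson correlation of midranks, with an
exact permutation p for `n ≤ 8` and the `t`-approximation on `n − 2`
degrees of freedom above that.

`comparison_table()` assembles the `Measure / N back / N / Mean / SD /
Median / W / p` schema, two rows per measure, with significance flags at
0.05 / 0.01 / 0.001. Tests are two-sided throughout and *no*
multiple-testing adjustment is applied by default, mirroring the reporting
style this package models; Holm and Benjamini–Hochberg columns are one
argument away. One caveat is carried in the table metadata rather than
hidden: trial-level observations pooled across participants are treated as
independent by the rank test. That replicates the modelled analysis; a
mixed-effects treatment of the within-participant dependence is explicitly
out of scope.

# What the synthetic generator emulates

The generator exists so that every pipeline stage has a testable ground
truth. Its defaults are calibrated to the population-level summaries the
modelled study reports; they are synthetic stand-ins, not re-measurements.

* **Behaviour.** Reaction times are lognormal per condition with
  parameters matched to the reported medians/means (1-back: median 1.06 s,
  mean 1.11 s; 2-back: 1.43/1.58 s); draws beyond the 3 s timeout become
  unanswered trials (~5% in the 2-back). Answered scoreable trials are
  correct with probability 0.94 (1-back) / 0.85 (2-back). Inter-stimulus
  intervals are uniform on 1–2 s.
* **EEG.** Each channel is a sum of stationary band oscillations (defaults:
  Theta 10 µV at 6 Hz, Alpha 20 µV at 10 Hz, Beta 5 µV at 20 Hz) over 1/f
  Gaussian noise (default SD 2 µV), with optional mains contamination.
  Inside each activation interval the oscillation amplitude is multiplied
  by $\sqrt{1-d}$, so mean band power changes by exactly the fraction $d$;
  the default $d$ table is the set of condition-wise median fractions the
  modelled study reports per band and channel (Alpha/Beta negative, i.e.
  power increases, Theta positive). The study publishes no SNR, so the
  noise scale is a documented synthetic choice.
* **Pupil.** The trace is participant baseline (3.5 ± 0.3 mm across a
  cohort) + a per-trial interval-level workload component + fast sample
  noise (0.05 mm). The interval component is drawn from a three-parameter
  shifted (possibly mirrored) lognormal matched per condition to the
  reported median/mean/SD of averaged pupil dilation (medians 0.113 vs
  0.197 mm, SDs 0.369/0.389 mm) — a family chosen because it reproduces all
  three summaries including the opposite skews, while staying near-normal
  at these parameter values.
* **Gaze events.** Fixations and saccades alternate with lognormal
  durations matched to the reported medians/means (~167 ms fixations,
  ~25 ms saccades); fixations jitter by ~1 px, saccades jump linearly.
* **Missingness and astigmatism.** Samples drop i.i.d. (both eyes jointly)
  at a per-participant probability linked to a lognormal astigmatism degree
  through a Gaussian copula with Pearson $r = 2\sin(\pi\rho_s/6)$, making
  the population Spearman correlation between astigmatism and capture rate
  exactly the target (default −0.55). The link's base rate (0.3) and
  spread (1.5 on the logit scale) put roughly 60% of a cohort above the 0.6
  screening threshold, matching the 18-of-30 retention the modelled study
  reports.
* **Cohort structure.** Default 30 participants, IDs 101–130, odd/even
  counterbalancing, and ID 126 dropped with no streams recorded — so the
  standard cohort yields 29 analyzable sessions.

What the generator does *not* emulate — and what passing recovery tests
therefore cannot certify about real data: blink/motion artifacts (an
option exists but is off by default and has no empirical model),
non-stationary background EEG, saccade kinematics (no main-sequence
velocity profile), luminance-driven pupil responses, bursty rather than
i.i.d. tracker dropout (a config option), and any display-timing jitter.

# Problem sizes and tolerances in the validation suite

The suite's simulation scales were chosen to keep estimator noise an order
of magnitude below each tolerance: noiseless oracle-equivalence runs use
single sessions with full 3 s activation windows and assert recovery of
$d \in \{-0.5, 0, 0.3, 0.6\}$ within 0.02 (away baseline, where edge
transients are smallest); the injected-effect recovery uses a 6-person
high-SNR cohort (~126 trials) against a ±0.05 band; type-I calibration
uses 2,000 null replicates at n = 50 per group against 5% ± 2%; the
pupil-effect power check uses 200 replicates at the generator's reported
scale (n ≈ 245 per group); and the correlation recovery uses 500 cohorts
of n = 18 against a ±0.10 band on the mean estimate. All randomness is
seeded, so the suite is reproducible run to run.

# Known limitations

The pipeline deliberately performs no artifact rejection or ICA, no ERP
component analysis, no gaze-to-AOI mapping, and no mixed-effects modelling;
the near-baseline edge-transient bias discussed above shrinks large
injected effects by a few percent; and the exact rank-sum path switches to
the normal approximation in the presence of any tie, which is conservative
for heavily discretised measures.
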