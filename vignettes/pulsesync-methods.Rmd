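---
title: "Methods: signal models, detection and study analysis in pulsesync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal models, detection and study analysis in pulsesync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsesync)
```

This vignette documents the models, numerical choices and open design
decisions behind `pulsesync`, in the spirit of a methods section: what is
assumed, what is tunable, and what passing tests do and do not demonstrate.

## 1. Synthetic cardiac signals

### Beat-train model

`simulate_beat_times()` draws inter-beat intervals i.i.d. from a normal
distribution with mean $60/\mathrm{HR}$ and standard deviation
`hrv_sd_s`, truncated to $[0.3, 2.0]$ s, and accumulates them from $t=0$.
This is deliberately the simplest controllable-variance model: it gives an
SDNN-style variability knob with an exactly known mean rate, which is what
the round-trip and parameter-recovery tests need. It does **not** model
autocorrelated heart-rate dynamics (respiratory sinus arrhythmia, Mayer
waves) or ectopic beats; detector performance on such structure is not
claimed. The default `hrv_sd_s = 0.05` s is a typical resting short-term
variability for healthy young adults.

### Waveform templates

Each PPG beat contributes a sum of two Gaussians: a unit-amplitude
systolic peak (SD 55 ms) and a dicrotic bump (amplitude 0.35, SD 90 ms,
250 ms later). The template's only role is to provide a realistic *timing*
problem — a dominant peak, a secondary bump that a naive detector would
double-count, and in-band spectral content; it makes no claim to optical
fidelity. The systolic peak occurs at `beat_time + ptt_s`; the default
pulse-transit time of 0.25 s emulates a wrist-worn sensor (≈ 0.20 s is
appropriate for an upper-arm placement). The ECG template is a narrow
R spike (Gaussian SD 12 ms, well under 0.1 s wide) with a small S dip, so
the R peak is the unambiguous argmax near each beat; P and T waves are out
of scope since the reference annotator operates on QRS energy alone.

### Noise model

`noise_spec()` adds three components: a baseline-wander sinusoid
(respiratory band, random phase), white sample noise, and motion-artifact
bursts — a 3 Hz oscillation under a Gaussian envelope (SD 0.15 s) at
listed times. The burst frequency sits *inside* the pulse passband on
purpose: artifacts that the band-pass would remove are no test of
robustness. The named profiles fix, once, what the validation simulations
mean by clean and noisy recordings: `"mild"` (white SD 0.02, wander 0.1)
and `"moderate"` (white SD 0.05 — 5 % of the pulse amplitude —, wander
0.25, one unit-amplitude artifact burst per ≈ 2.5 minutes). Real wearable
recordings report only qualitative "minor motion, breathing, or sweating
artifacts", so these magnitudes are the package's own definition of a
realistic moderately disturbed recording, not a calibration to any
dataset.

## 2. Causal PPG detection

The detector is a single-pass state machine over samples, suitable for
on-device streaming:

1. **Causal band-pass**: second-order Butterworth, 0.5–8 Hz, applied
   forward-only (direct form II transposed). The band keeps the pulse
   upstroke sharp while removing wander and most sample noise; its group
   delay at pulse frequencies is ≈ 19 ms at 134 Hz, which is what makes
   the overall latency budget attainable.
2. **Adaptive threshold**: an exponentially weighted running mean square
   of the filtered signal with half-life 3 s (default) tracks slow
   amplitude drift from sweating or contact changes. The arming threshold
   is 1.5 × the running RMS: low enough to fire on the systolic upstroke,
   high enough that the dicrotic bump (≈ 0.35 of the systolic amplitude)
   stays below it.
3. **Hysteresis**: after a beat, the filtered signal must fall below half
   the threshold before the detector can re-arm. This, together with the
   0.3 s refractory period (a 200 bpm ceiling), eliminates dicrotic
   double-triggering without any backtracking.
4. **Peak confirmation**: while armed, the running maximum of the filtered
   signal is tracked; the peak is confirmed as soon as the maximum has not
   improved for 2 samples (≈ 15 ms at 134 Hz). Plateaus resolve to their
   earliest sample, minimizing latency.

The emitted *decision latency* per beat is the gap between the confirmed
peak sample and the emission sample. The end-to-end latency relative to
the true waveform peak adds the filter delay; on clean synthetic data it
measures ≈ 30–40 ms, inside the 50 ms budget (`max_decision_latency_s`)
that a synchronous display pipeline must respect. The tests verify both:
the stored latencies against the configured budget, and the true-peak
latency against 50 ms using ground truth.

Degenerate inputs are contracts, not crashes: a flat-line trace yields
zero beats with a warning; cutoffs at or above Nyquist, wrong channels and
sub-5 s traces are invalid-argument errors.

The offline ECG annotator (`detect_ecg_rpeaks()`) is the reference, so it
may use the whole record: zero-phase 5–40 Hz filtering, smoothed squared
signal, global quantile threshold, 0.25 s minimum separation, and argmax
refinement of each candidate. On noise-free renders it recovers every
simulated beat to within one sample.

## 3. Validation metrics

Matching removes the median measured-minus-reference offset first, because
the peripheral pulse lags cardiac activation by a roughly constant
pulse-transit plus processing delay; a validator that did not remove it
would score a perfectly synchronous detector as uniformly late. Matching
is one-to-one with a 0.4 s tolerance (below half the minimum plausible
interval, so assignments are essentially unambiguous; a brute-force
assignment oracle backs this in the tests).

The interval error metric is reported **relative**: for consecutively
matched beats (adjacent in the reference, so no gap intrudes),
$\mathrm{RMSE}\% = 100\sqrt{\tfrac1n\sum_i\big((m_i-r_i)/r_i\big)^2}$.
A published percentage without a stated denominator can also be read as an
error *rate*; the per-interval relative reading is adopted here because it
is the only one that makes an RMSE unit-free, and the ambiguity is noted
rather than hidden. Missed beats are unmatched reference beats interior to
the matched span (equivalently: a measured interval spanning $k$ reference
intervals contributes $k-1$ misses); beats outside the matched span are
edge effects and excluded, so matched + missed + edge-excluded always
equals the reference count.

Pooling across recordings reports the mean and sample SD of per-recording
RMSE plus summed beat and miss totals; a single recording has no sample SD
and is flagged (`sd_defined = FALSE`) rather than reported as `NA`.

On twenty clean simulated 5-minute recordings the pipeline achieves
≈ 0.4 % mean interval RMSE with zero missed beats, and ≈ 1.5 % with zero
misses under the moderate profile (`scripts/acceptance.R` recomputes
these). Real recordings from the hardware this emulates report
2–3.4 % RMSE — synthetic templates are cleaner than physiology, so the
synthetic numbers bound what the *algorithm* loses, not what a wearable
achieves on skin.

## 4. Stimulation scheduling

`schedule_sync()` maps each detected beat to a flash at
`beat + lag_s`; the 0.05 s default models the constant peak-detection plus
wireless transmission delay of a watch-to-headset pipeline. Being
constant, it preserves synchrony; being causal, it never uses a future
beat.

`schedule_async()` implements the shuffled-rate control: inter-onset
interval $60/(f \cdot \mathrm{HR}(t))$ with $f$ drawn uniformly from
{0.8, 0.9, 1.1, 1.2}. A factor of exactly 1 is rejected — it would
reproduce the synchronous condition. Two details are underdetermined by
the protocol description and fixed here as package choices:

* **Factor epochs.** Whether the original application held one factor per
  5-minute block or shuffled within a block is not stated. The factor is
  re-drawn at every 60 s boundary: per-minute re-draws keep the rate
  non-trackable for the participant while remaining statistically
  testable (per-epoch factor usage is uniform by χ²).
* **Heart-rate estimate.** "Actual heart rate" is implemented as the
  running mean of the last 8 detected inter-beat intervals
  (`hr_estimate_from_beats()`), held constant between beats — a causal,
  smooth estimate with a few-beats response time.

The brightness envelope jumps to 1 at onset and decays as
$e^{-t/\tau}$; $\tau = 0.4$ s quantifies an unquantified "slow fade" and
is exposed in `envelope_params()`. Overlapping flashes combine by the
maximum — a fresh flash resets the silhouette to full brightness and an
old flash never darkens a newer one.

`plan_session()` randomizes {sync, sync, async, async} uniformly over the
six distinguishable orders, with 300 s blocks and 180 s rests.

## 5. Study analysis

Questionnaire composites are unweighted item means (usability: 3 items on
1–5; simulator sickness: 7 items on 1–4; ownership: 7 items on 0–6), and
the group composite is the mean of item means — identical to the mean of
participant composites for complete data, and computable directly from a
published item-mean table.

Pain deltas follow the instruments' sign conventions, chosen so that
*positive always means increased pain sensitivity*: per block, the
bilateral (left/right) mean is taken per phase; the Algopeg block delta is
post − pre (higher rating = more pain reported at the same clamping
force) while the Somedic block delta is pre − post (a dropped
pressure-pain threshold = pain at lower pressure); the condition delta is
the mean over the condition's two blocks. Missing sides, phases or blocks
raise errors listing the offending keys rather than silently dropping
cells.

`paired_condition_test()` reproduces the normality-gated recipe: the
Lilliefors variant of the Kolmogorov–Smirnov test on the paired
differences (the plain KS test with fixed parameters would be
anti-conservative when the mean and SD are estimated from the same
sample), then a one-sided paired *t* test if normality is not rejected,
otherwise the Wilcoxon signed-rank test. The default direction tests
sync < async on the sensitivity scale, i.e. synchronous stimulation
lowering pain sensitivity. All-zero differences produce a degenerate
report, not an exception.

The signed-rank test is implemented with explicit, documented
conventions — Pratt handling of zero differences (zeros are ranked, then
discarded, with the null moments corrected accordingly) and average ranks
for ties, with a tie-corrected normal approximation — because the standard
implementation drops zeros before ranking and would silently change the
statistic on the zero-heavy ordinal data ownership ratings produce. On
tie-free data it agrees with `stats::wilcox.test` exactly; for small
samples the tests check the statistic against exhaustive enumeration of
all sign assignments. Ownership is compared two-sided on per-participant
item means (a published "single score per condition" without a stated
definition; the item mean is this package's choice, stated here once).

The synthetic study tables (`simulate_pain_table()`,
`simulate_questionnaires()`) emulate a 20-participant null study —
per-participant baselines, measurement noise, Somedic values averaged over
3 ramp repetitions, floor-skewed ownership — and exist so the analysis
path is exercised end to end; group-level published outcomes depend on the
original per-participant data and are not reproduced, only the
aggregation arithmetic and test logic are verified (by construction and by
oracle).

## 6. Problem sizes and reproducibility

The test suite and acceptance script use 5-minute recordings (twenty per
noise profile, ≈ 7 000 beats total), 300 s parameter-recovery runs,
60 000-seed randomization checks, and exhaustive signed-rank enumeration
up to n = 8 — sizes at which every stochastic check is stable across
seeds while the full suite runs in well under a minute. All randomness
flows through explicit `seed` arguments; seeded calls restore the caller's
RNG state, so package calls never perturb an enclosing simulation, and
`run_demo()` is byte-identical across runs at a fixed seed.

Known limitations, summarized: no autocorrelated HRV or ectopy; stylized
waveforms and additive noise only (no sensor saturation, no multiplicative
perfusion changes); detector parameters tuned for resting heart rates
(30–220 bpm contract, 200 bpm refractory ceiling); validation assumes a
roughly constant PPG lag; published group outcomes are out of reach
without raw data, by design.
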