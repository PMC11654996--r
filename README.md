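# pulsesync

Heartbeat detection, ECG-referenced validation and cardiovisual stimulation
scheduling for cardiac interoception experiments.

## The problem

Cardiovisual full-body-illusion setups display a participant's heartbeat as
a flash on a virtual avatar: a silhouette lights up at each beat
(synchronous condition) or at a shuffled rate (asynchronous control).
Building such a setup raises three engineering questions that this package
answers with testable code:

1. **Detection.** Can pulse peaks be extracted from a wearable PPG signal
   *causally* — sample by sample, with a per-beat decision latency small
   enough (≤ 50 ms) that the flash still feels synchronous?
2. **Validation.** How accurate is the detector against a clinical ECG
   reference? The two field metrics are the relative peak-to-peak interval
   RMSE, `100 · sqrt(mean(((mᵢ − rᵢ)/rᵢ)²))` over consecutively matched
   intervals (measured `mᵢ`, reference `rᵢ`), and the number of missed
   beats, counted as interior reference beats left unmatched after
   constant-lag removal and one-to-one matching.
3. **Stimulation and analysis.** How are flash trains scheduled (sync:
   one flash per beat plus a constant lag; async: 80/90/110/120 % of the
   running heart-rate estimate, factor re-drawn each minute), how are
   four 5-minute blocks randomized, and how are the study outcomes
   (usability/sickness questionnaires, bilateral pre/post pain deltas with
   per-instrument sign conventions, normality-gated paired tests)
   computed?

Because no recordings ship with the package, a synthetic-data module
generates ground-truth beat trains (truncated-normal inter-beat intervals)
and renders PPG (134 Hz, with pulse-transit delay, baseline wander, white
noise and motion-artifact bursts) and ECG (240 Hz, narrow R spikes), so
every downstream claim is tested against known truth.

## Worked example

```r
library(pulsesync)

truth <- simulate_beat_times(mean_hr_bpm = 72, hrv_sd_s = 0.05,
                             duration_s = 300, seed = 1)
ppg <- render_ppg(truth, noise = noise_profile("mild", 300, seed = 2),
                  duration_s = 300)
det <- detect_ppg_beats(ppg)
validate_beats(truth, det$beats)
#> <validation_report>
#>   reference beats : 359
#>   matched         : 359
#>   missed          : 0
#>   extra           : 0
#>   interval RMSE   : 1.461 %
#>   constant lag    : 270.0 ms
```

All 359 simulated beats are recovered, none missed; the inter-beat
intervals are reproduced to 1.46 % RMSE under mild noise; and the
detector's events trail the cardiac beats by a constant ≈ 0.27 s (the
0.25 s pulse-transit delay plus filter delay), which is exactly the
constant lag the validator removes before matching. Scheduling and
analysis follow the same pattern:

```r
sync <- schedule_sync(det$beats, lag_s = 0.05)   # one flash per beat
async <- schedule_async(det$beats, 300, seed = 3) # shuffled-rate control
plan_session(seed = 4)
#> <session_plan: async -> async -> sync -> sync (300 s blocks, 180 s rests)>
```

`run_demo(seed = 42)` chains the full pipeline (simulate → detect →
validate → schedule → analyze) and returns a reproducible report; the
`inst/cli/pulsesync` script exposes the same steps as shell subcommands
(`simulate`, `detect`, `validate`, `schedule`, `analyze`, `demo`).

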