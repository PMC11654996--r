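#' Noise specification for synthetic traces
#'
#' Describes the additive disturbances layered on top of a rendered clean
#' trace: slow baseline wander (a low-frequency sinusoid emulating breathing
#' and sensor drift), white measurement noise, and transient motion-artifact
#' bursts (an in-band oscillation under a Gaussian envelope) at listed times.
#'
#' @param white_sd Standard deviation of i.i.d. Gaussian sample noise, in
#'   units of the unit-amplitude pulse (>= 0).
#' @param wander_amp Amplitude of the baseline-wander sinusoid (>= 0).
#' @param wander_freq_hz Frequency of the baseline wander, Hz. Default
#'   0.25 Hz (respiratory band).
#' @param artifact_times Times (s) of motion-artifact bursts; must lie inside
#'   the rendered trace.
#' @param artifact_amps Peak amplitudes of the bursts; recycled to the length
#'   of `artifact_times`; all >= 0.
#' @param artifact_width_s Gaussian envelope SD of each burst (s).
#' @param artifact_freq_hz Oscillation frequency inside a burst, Hz. The
#'   default 3 Hz sits inside the pulse passband, so bursts genuinely
#'   disturb detection rather than being filtered away.
#' @param seed Integer seed controlling the random phase of the wander and
#'   the white-noise draw; `NULL` uses the ambient RNG stream.
#'
#' @return An object of class `noise_spec`.
#' @seealso [noise_profile()] for named presets.
#' @export
noise_spec <- function(white_sd = 0, wander_amp = 0, wander_freq_hz = 0.25,
                       artifact_times = numeric(), artifact_amps = numeric(),
                       artifact_width_s = 0.15, artifact_freq_hz = 3,
                       seed = NULL) {
  if (white_sd < 0 || wander_amp < 0) {
    stop_invalid("noise amplitudes must be non-negative")
  }
  artifact_times <- as.numeric(artifact_times)
  if (length(artifact_times) > 0) {
    artifact_amps <- rep_len(as.numeric(artifact_amps), length(artifact_times))
    if (any(artifact_amps < 0)) stop_invalid("artifact amplitudes must be >= 0")
  } else {
    artifact_amps <- numeric()
  }
  structure(
    list(
      white_sd = white_sd, wander_amp = wander_amp,
      wander_freq_hz = wander_freq_hz,
      artifact_times = artifact_times, artifact_amps = artifact_amps,
      artifact_width_s = artifact_width_s, artifact_freq_hz = artifact_freq_hz,
      seed = seed
    ),
    class = "noise_spec"
  )
}

#' Named noise presets
#'
#' Convenience presets used throughout the examples and the validation
#' simulations. `"none"` renders a clean trace; `"mild"` adds light wander
#' and sample noise; `"moderate"` adds stronger wander, more sample noise
#' and sparse motion-artifact bursts (about two per 5 minutes), emulating a
#' wearable recording with occasional movement and contact changes.
#'
#' @param profile One of `"none"`, `"mild"`, `"moderate"`.
#' @param duration_s Trace duration, used to place artifact bursts for the
#'   `"moderate"` profile.
#' @param seed Seed forwarded to [noise_spec()].
#' @return A [noise_spec()].
#' @export
noise_profile <- function(profile = c("none", "mild", "moderate"),
                          duration_s = 300, seed = NULL) {
  profile <- match.arg(profile)
  switch(profile,
    none = noise_spec(seed = seed),
    mild = noise_spec(
      white_sd = 0.02, wander_amp = 0.1, wander_freq_hz = 0.25, seed = seed
    ),
    moderate = {
      n_art <- max(1L, round(duration_s / 150))
      at <- seq(duration_s / (n_art + 1), by = duration_s / (n_art + 1),
                length.out = n_art)
      noise_spec(
        white_sd = 0.05, wander_amp = 0.25, wander_freq_hz = 0.3,
        artifact_times = at, artifact_amps = rep(1, n_art), seed = seed
      )
    }
  )
}

# Render the additive noise component for a time grid.
render_noise <- function(noise, t) {
  if (is.null(noise)) return(numeric(length(t)))
  stopifnot(inherits(noise, "noise_spec"))
  dur <- max(t)
  if (length(noise$artifact_times) > 0 &&
      any(noise$artifact_times < 0 | noise$artifact_times > dur)) {
    stop_invalid("artifact times must lie within the trace duration")
  }
  with_seed(noise$seed, {
    out <- numeric(length(t))
    if (noise$wander_amp > 0) {
      phase <- runif(1, 0, 2 * pi)
      out <- out + noise$wander_amp *
        sin(2 * pi * noise$wander_freq_hz * t + phase)
    }
    if (noise$white_sd > 0) {
      out <- out + rnorm(length(t), sd = noise$white_sd)
    }
    if (length(noise$artifact_times) > 0) {
      for (j in seq_along(noise$artifact_times)) {
        tc <- noise$artifact_times[j]
        env <- noise$artifact_amps[j] *
          exp(-(t - tc)^2 / (2 * noise$artifact_width_s^2))
        out <- out + env * sin(2 * pi * noise$artifact_freq_hz * (t - tc))
      }
    }
    out
  })
}

#' Simulate ground-truth heartbeat times
#'
#' Draws inter-beat intervals i.i.d. from a normal distribution with mean
#' `60 / mean_hr_bpm` and standard deviation `hrv_sd_s`, truncated to the
#' physiological range \[0.3, 2.0\] s, and accumulates them starting at
#' time 0. With `hrv_sd_s = 0` the output is a perfectly regular beat train.
#'
#' @param mean_hr_bpm Mean heart rate in beats per minute, in \[30, 220\].
#' @param hrv_sd_s Standard deviation of the inter-beat interval in seconds
#'   (>= 0). This is a direct SDNN-style variability knob, not a full
#'   autoregressive/respiratory HRV model.
#' @param duration_s Duration of the simulated recording (> 0); beats are
#'   generated on \[0, duration_s).
#' @param seed Integer seed for reproducibility; `NULL` uses the ambient
#'   RNG stream.
#' @param interval_range_s Truncation bounds for the interval distribution.
#'
#' @return A [beat_series()] with source `"ground_truth"`.
#' @examples
#' simulate_beat_times(60, 0, 5) # beats at 0, 1, 2, 3, 4
#' @export
simulate_beat_times <- function(mean_hr_bpm, hrv_sd_s = 0.05, duration_s,
                                seed = NULL,
                                interval_range_s = c(0.3, 2.0)) {
  if (!is_scalar_number(mean_hr_bpm) || mean_hr_bpm < 30 || mean_hr_bpm > 220) {
    stop_invalid("mean_hr_bpm must be in [30, 220], got %s", mean_hr_bpm)
  }
  if (!is_scalar_number(hrv_sd_s) || hrv_sd_s < 0) {
    stop_invalid("hrv_sd_s must be >= 0")
  }
  if (!is_scalar_number(duration_s) || duration_s <= 0) {
    stop_invalid("duration_s must be > 0")
  }
  mu <- 60 / mean_hr_bpm
  lo <- interval_range_s[1]
  hi <- interval_range_s[2]
  with_seed(seed, {
    n_guess <- ceiling(duration_s / max(mu - 4 * hrv_sd_s, lo)) + 8L
    intervals <- numeric(0)
    while (sum(intervals) < duration_s) {
      draw <- if (hrv_sd_s == 0) {
        rep(mu, n_guess)
      } else {
        # rejection sampling from the truncated normal; acceptance is high
        # for physiological parameter values
        d <- rnorm(n_guess, mean = mu, sd = hrv_sd_s)
        while (any(bad <- (d < lo | d > hi))) {
          d[bad] <- rnorm(sum(bad), mean = mu, sd = hrv_sd_s)
        }
        d
      }
      intervals <- c(intervals, draw)
    }
    times <- cumsum(c(0, intervals))
    beat_series(times[times < duration_s], source = "ground_truth")
  })
}

# Stereotyped pulse waveform: unit-amplitude systolic Gaussian plus a
# smaller, wider dicrotic bump 0.25 s later. The systolic peak is the
# unique global maximum of the template.
ppg_template <- function(dt) {
  exp(-dt^2 / (2 * 0.055^2)) + 0.35 * exp(-(dt - 0.25)^2 / (2 * 0.09^2))
}

# Narrow R spike plus a small S dip; argmax is at the beat time.
ecg_template <- function(dt) {
  exp(-dt^2 / (2 * 0.012^2)) - 0.15 * exp(-(dt - 0.04)^2 / (2 * 0.018^2))
}

render_trace <- function(beats, sampling_rate_hz, delay_s, noise, duration_s,
                         channel, template, support_s) {
  if (length(beats) == 0L) {
    stop_invalid("cannot render a trace from an empty beat series")
  }
  if (delay_s < 0) stop_invalid("transit delay must be >= 0")
  if (is.null(duration_s)) {
    duration_s <- max(as.numeric(beats)) + delay_s + 1.0
  }
  n <- ceiling(duration_s * sampling_rate_hz)
  t <- (0:(n - 1L)) / sampling_rate_hz
  x <- numeric(n)
  for (b in as.numeric(beats)) {
    centre <- b + delay_s
    i0 <- max(1L, floor((centre - support_s[1]) * sampling_rate_hz) + 1L)
    i1 <- min(n, ceiling((centre + support_s[2]) * sampling_rate_hz) + 1L)
    if (i0 > n || i1 < 1L) next
    idx <- i0:i1
    x[idx] <- x[idx] + template(t[idx] - centre)
  }
  x <- x + render_noise(noise, t)
  signal_trace(x, sampling_rate_hz, channel = channel)
}

#' Render a synthetic PPG trace from beat times
#'
#' Each beat contributes a stereotyped blood-volume pulse (systolic peak plus
#' dicrotic bump) whose systolic maximum occurs `ptt_s` seconds after the
#' cardiac beat, emulating the pulse-transit delay to a peripheral optical
#' sensor. Additive noise follows `noise`.
#'
#' @param beats A [beat_series()] (must be non-empty).
#' @param sampling_rate_hz Sampling rate, Hz; default 134 (smartwatch PPG).
#' @param ptt_s Pulse-transit time in seconds (>= 0). Defaults to 0.25 s, a
#'   typical heart-to-wrist delay; about 0.20 s suits an upper-arm sensor.
#' @param noise A [noise_spec()] or `NULL` for a clean trace.
#' @param duration_s Trace duration (s); default extends 1 s past the last
#'   pulse. The trace has `ceiling(duration_s * sampling_rate_hz)` samples.
#'
#' @return A [signal_trace()] with channel `"ppg"`.
#' @examples
#' b <- simulate_beat_times(60, 0, 10)
#' tr <- render_ppg(b, duration_s = 10)
#' length(tr$samples) # 1340
#' @export
render_ppg <- function(beats, sampling_rate_hz = 134, ptt_s = 0.25,
                       noise = NULL, duration_s = NULL) {
  render_trace(beats, sampling_rate_hz, ptt_s, noise, duration_s,
    channel = "ppg", template = ppg_template, support_s = c(0.4, 0.8)
  )
}

#' Render a synthetic ECG trace from beat times
#'
#' Each beat contributes a narrow R spike (Gaussian SD 12 ms, total width
#' well under 0.1 s) with a small S dip, so the R peak is the unambiguous
#' local maximum at each beat time. There is no transit delay: the ECG
#' measures cardiac electrical activity directly. P/T waves are not
#' modelled.
#'
#' @param beats A [beat_series()] (must be non-empty).
#' @param sampling_rate_hz Sampling rate, Hz; default 240 (clinical ECG).
#' @param noise A [noise_spec()] or `NULL`.
#' @param duration_s Trace duration (s); default extends 1 s past the last
#'   beat.
#'
#' @return A [signal_trace()] with channel `"ecg"`.
#' @export
render_ecg <- function(beats, sampling_rate_hz = 240, noise = NULL,
                       duration_s = NULL) {
  render_trace(beats, sampling_rate_hz, 0, noise, duration_s,
    channel = "ecg", template = ecg_template, support_s = c(0.15, 0.2)
  )
}
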