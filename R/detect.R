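#' Configuration for the online PPG pulse-peak detector
#'
#' Parameters of the causal detection chain: a second-order Butterworth
#' band-pass, an exponentially adapting amplitude threshold, a refractory
#' period, and a hard budget on the per-beat decision latency (the time
#' between the waveform peak sample and the emission of the beat event).
#' The 50 ms default latency budget corresponds to about 7 samples of
#' lookahead at the 134 Hz PPG rate.
#'
#' @param bandpass_low_hz Low cutoff of the band-pass (Hz). Default 0.5,
#'   below the slowest plausible heart rate, removing baseline wander.
#' @param bandpass_high_hz High cutoff (Hz). Default 8, keeping the pulse
#'   upstroke sharp while suppressing sample noise. Must be below the
#'   Nyquist frequency of the trace.
#' @param refractory_s Minimum spacing between emitted beats (s); >= 0.2.
#'   Default 0.3 s, a 200 bpm ceiling.
#' @param threshold_scale Arming threshold as a multiple of the running RMS
#'   of the filtered signal. Default 1.5: low enough to fire on the systolic
#'   upstroke, high enough to ignore the dicrotic bump.
#' @param adaptive_halflife_s Half-life (s) of the exponentially weighted
#'   running amplitude used by the adaptive threshold. Default 3 s, tracking
#'   slow amplitude drift from sweating or contact changes.
#' @param confirm_samples Number of samples the running maximum must stall
#'   before a peak is confirmed. Default 2; this is the structural decision
#'   latency of the detector.
#' @param max_decision_latency_s Per-beat decision latency budget (s);
#'   default 0.05.
#'
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(bandpass_low_hz = 0.5, bandpass_high_hz = 8,
                            refractory_s = 0.3, threshold_scale = 1.5,
                            adaptive_halflife_s = 3, confirm_samples = 2L,
                            max_decision_latency_s = 0.05) {
  if (bandpass_low_hz <= 0 || bandpass_high_hz <= bandpass_low_hz) {
    stop_invalid("need 0 < bandpass_low_hz < bandpass_high_hz")
  }
  if (refractory_s < 0.2) {
    stop_invalid("refractory_s must be >= 0.2 s (physiological floor)")
  }
  if (max_decision_latency_s <= 0) {
    stop_invalid("max_decision_latency_s must be > 0")
  }
  structure(
    list(
      bandpass_low_hz = bandpass_low_hz,
      bandpass_high_hz = bandpass_high_hz,
      refractory_s = refractory_s,
      threshold_scale = threshold_scale,
      adaptive_halflife_s = adaptive_halflife_s,
      confirm_samples = as.integer(confirm_samples),
      max_decision_latency_s = max_decision_latency_s
    ),
    class = "detector_config"
  )
}

butter_coefs <- function(config, fs) {
  nyq <- fs / 2
  if (config$bandpass_high_hz >= nyq) {
    stop_invalid(
      "bandpass_high_hz (%g Hz) must be below the Nyquist frequency (%g Hz)",
      config$bandpass_high_hz, nyq
    )
  }
  bf <- signal::butter(
    2, c(config$bandpass_low_hz, config$bandpass_high_hz) / nyq,
    type = "pass"
  )
  list(b = as.numeric(bf$b), a = as.numeric(bf$a))
}

#' Causal band-pass filter for PPG traces
#'
#' Applies the detector's second-order Butterworth band-pass as a causal
#' (forward-only) IIR filter: the output at each sample depends only on
#' current and past samples, as required for streaming detection. Output has
#' the same length and sampling rate as the input.
#'
#' @param trace A [signal_trace()] with channel `"ppg"`.
#' @param config A [detector_config()].
#' @return A filtered [signal_trace()].
#' @export
causal_bandpass <- function(trace, config = detector_config()) {
  stopifnot(inherits(trace, "signal_trace"))
  if (trace$channel != "ppg") {
    stop_invalid("causal_bandpass expects a PPG trace, got channel '%s'",
                 trace$channel)
  }
  co <- butter_coefs(config, trace$sampling_rate_hz)
  y <- as.numeric(signal::filter(signal::Arma(b = co$b, a = co$a),
                                 trace$samples))
  signal_trace(y, trace$sampling_rate_hz, channel = "ppg", t0 = trace$t0)
}

#' Create a streaming PPG detector
#'
#' Lower-level interface to the online detector: construct a detector, then
#' push samples through it in arbitrary chunks with [feed_samples()]. The
#' emitted beats are identical whatever the chunking, including one sample
#' at a time — the detector is strictly single-pass with bounded lookahead.
#'
#' The chain is: causal band-pass, an exponentially weighted running RMS
#' (half-life `adaptive_halflife_s`) that sets the arming threshold, a
#' rising-edge arming test with hysteresis (after a beat the filtered signal
#' must fall back below half the threshold before re-arming, which rejects
#' the dicrotic bump), and peak confirmation when the running maximum of the
#' filtered signal has not improved for `confirm_samples` samples. Plateau
#' ties resolve to the earliest sample. The beat time is the confirmed peak
#' sample; the decision latency is the gap between that sample and the
#' sample at which the event is emitted.
#'
#' @param config A [detector_config()].
#' @param sampling_rate_hz Sampling rate of the stream (Hz).
#' @return An object of class `ppg_detector` holding the filter and
#'   threshold state.
#' @seealso [detect_ppg_beats()] for the one-shot interface.
#' @export
ppg_detector <- function(config = detector_config(), sampling_rate_hz = 134) {
  co <- butter_coefs(config, sampling_rate_hz)
  fs <- sampling_rate_hz
  if (config$confirm_samples / fs > config$max_decision_latency_s) {
    stop_invalid(
      "confirm_samples (%d) exceeds the decision latency budget of %g s at %g Hz",
      config$confirm_samples, config$max_decision_latency_s, fs
    )
  }
  structure(
    list(
      config = config, fs = fs, b = co$b, a = co$a,
      z = numeric(4), # band-pass state (direct form II transposed)
      q = 0, # running mean square of the filtered signal
      lambda = 2^(-1 / (config$adaptive_halflife_s * fs)),
      n_seen = 0L, # samples consumed so far
      armed = FALSE, need_reset = FALSE,
      run_max = -Inf, run_max_idx = 0L,
      last_peak_idx = -Inf,
      beat_idx = integer(), latency_samples = integer()
    ),
    class = "ppg_detector"
  )
}

#' Push samples through a streaming PPG detector
#'
#' @param det A [ppg_detector()].
#' @param samples Numeric vector of raw PPG samples (any length, including
#'   length one).
#' @return The updated detector; accumulated beats are read off with
#'   [detector_beats()].
#' @export
feed_samples <- function(det, samples) {
  stopifnot(inherits(det, "ppg_detector"))
  cfg <- det$config
  b <- det$b; a <- det$a
  z1 <- det$z[1]; z2 <- det$z[2]; z3 <- det$z[3]; z4 <- det$z[4]
  q <- det$q; lambda <- det$lambda
  n <- det$n_seen
  armed <- det$armed; need_reset <- det$need_reset
  run_max <- det$run_max; run_max_idx <- det$run_max_idx
  last_peak <- det$last_peak_idx
  refr <- round(cfg$refractory_s * det$fs)
  m <- cfg$confirm_samples
  k <- cfg$threshold_scale
  beats <- det$beat_idx; lats <- det$latency_samples

  for (x in as.numeric(samples)) {
    n <- n + 1L
    # causal band-pass, direct form II transposed
    y <- b[1] * x + z1
    z1 <- b[2] * x - a[2] * y + z2
    z2 <- b[3] * x - a[3] * y + z3
    z3 <- b[4] * x - a[4] * y + z4
    z4 <- b[5] * x - a[5] * y
    # adaptive amplitude tracking
    q <- lambda * q + (1 - lambda) * y * y
    thr <- k * sqrt(q)
    if (need_reset && y < 0.5 * thr) need_reset <- FALSE
    if (!armed) {
      if (!need_reset && y > thr && thr > 0 && (n - last_peak) >= refr) {
        armed <- TRUE
        run_max <- y
        run_max_idx <- n
      }
    } else {
      if (y > run_max) { # strict: plateau resolves to earliest sample
        run_max <- y
        run_max_idx <- n
      } else if (n - run_max_idx >= m) {
        beats <- c(beats, run_max_idx)
        lats <- c(lats, n - run_max_idx)
        last_peak <- run_max_idx
        armed <- FALSE
        need_reset <- TRUE
        run_max <- -Inf
      }
    }
  }

  det$z <- c(z1, z2, z3, z4)
  det$q <- q
  det$n_seen <- n
  det$armed <- armed; det$need_reset <- need_reset
  det$run_max <- run_max; det$run_max_idx <- run_max_idx
  det$last_peak_idx <- last_peak
  det$beat_idx <- beats; det$latency_samples <- lats
  det
}

#' Read accumulated beats off a streaming detector
#'
#' @param det A [ppg_detector()] after one or more [feed_samples()] calls.
#' @param t0 Time of the first fed sample (s).
#' @return A `detection_result`: list with `beats` (a [beat_series()],
#'   source `"ppg_detector"`) and `decision_latencies_s` (one per beat).
#' @export
detector_beats <- function(det, t0 = 0) {
  times <- t0 + (det$beat_idx - 1L) / det$fs
  structure(
    list(
      beats = beat_series(times, source = "ppg_detector"),
      decision_latencies_s = det$latency_samples / det$fs,
      config = det$config
    ),
    class = "detection_result"
  )
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf(
    "<detection_result: %d beats, max decision latency %.1f ms>\n",
    length(x$beats),
    if (length(x$decision_latencies_s)) 1000 * max(x$decision_latencies_s) else 0
  ))
  invisible(x)
}

#' Online PPG pulse-peak detection
#'
#' Runs the causal streaming detector over a stored trace in a single pass.
#' Emits one event per detected systolic peak, respects the refractory
#' period, and guarantees every per-beat decision latency is within
#' `config$max_decision_latency_s`. See [ppg_detector()] for the algorithm.
#'
#' @param trace A [signal_trace()] with channel `"ppg"`, at least 5 s long.
#' @param config A [detector_config()].
#' @return A `detection_result` (see [detector_beats()]). A flat-line trace
#'   yields zero beats with a warning, not an error.
#' @examples
#' b <- simulate_beat_times(60, 0.03, 30, seed = 1)
#' tr <- render_ppg(b, duration_s = 30)
#' det <- detect_ppg_beats(tr)
#' length(det$beats)
#' @export
detect_ppg_beats <- function(trace, config = detector_config()) {
  stopifnot(inherits(trace, "signal_trace"))
  if (trace$channel != "ppg") {
    stop_invalid("detect_ppg_beats expects a PPG trace, got channel '%s'",
                 trace$channel)
  }
  if (trace_duration(trace) < 5) {
    stop_invalid("trace must be at least 5 s long for stable detection")
  }
  det <- ppg_detector(config, trace$sampling_rate_hz)
  det <- feed_samples(det, trace$samples)
  res <- detector_beats(det, t0 = trace$t0)
  if (length(res$beats) == 0L) {
    warning("no beats detected (flat or sub-threshold signal)", call. = FALSE)
  }
  res
}

#' Offline ECG R-peak annotation
#'
#' Reference annotator for validation: band-passes the ECG around the QRS
#' band (5-40 Hz, zero-phase), finds local maxima of the smoothed squared
#' signal above an amplitude threshold with a 0.25 s minimum separation, and
#' refines each candidate to the R-peak maximum of the band-passed trace.
#' Being the offline reference, it may use the full record (zero-phase
#' filtering, global threshold).
#'
#' @param trace A [signal_trace()] with channel `"ecg"`.
#' @param qrs_band_hz Band-pass edges for QRS enhancement (Hz).
#' @param threshold_frac Detection threshold as a fraction of the 99.5th
#'   percentile of the smoothed squared signal.
#' @return A [beat_series()] with source `"ecg_reference"`; empty (with a
#'   warning) if no QRS-like activity is found.
#' @export
detect_ecg_rpeaks <- function(trace, qrs_band_hz = c(5, 40),
                              threshold_frac = 0.25) {
  stopifnot(inherits(trace, "signal_trace"))
  if (trace$channel != "ecg") {
    stop_invalid("detect_ecg_rpeaks expects an ECG trace, got channel '%s'",
                 trace$channel)
  }
  fs <- trace$sampling_rate_hz
  nyq <- fs / 2
  if (qrs_band_hz[2] >= nyq) {
    stop_invalid("QRS band upper edge must be below Nyquist (%g Hz)", nyq)
  }
  bf <- signal::butter(2, qrs_band_hz / nyq, type = "pass")
  y <- as.numeric(signal::filtfilt(bf, trace$samples))
  energy <- y^2
  w <- max(1L, round(0.08 * fs))
  smooth <- as.numeric(stats::filter(energy, rep(1 / w, w), sides = 2))
  smooth[is.na(smooth)] <- 0
  peak_floor <- threshold_frac * quantile(smooth, 0.995, names = FALSE)
  if (!is.finite(peak_floor) || peak_floor <= 0) {
    warning("no QRS-like activity found", call. = FALSE)
    return(beat_series(numeric(), source = "ecg_reference"))
  }
  # pad so maxima at the record boundaries are found too
  padded <- c(min(smooth) - 1, smooth, min(smooth) - 1)
  pk <- pracma::findpeaks(padded,
    minpeakheight = peak_floor,
    minpeakdistance = max(1L, round(0.25 * fs))
  )
  if (is.null(pk)) {
    warning("no QRS-like activity found", call. = FALSE)
    return(beat_series(numeric(), source = "ecg_reference"))
  }
  cand <- sort(as.integer(pk[, 2]) - 1L) # undo padding offset
  half <- as.integer(round(0.05 * fs))
  n <- length(y)
  peaks <- vapply(cand, function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    lo + which.max(y[lo:hi]) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))
  # enforce minimum separation after refinement
  if (length(peaks) > 1L) {
    keep <- c(TRUE, diff(peaks) > round(0.25 * fs))
    peaks <- peaks[keep]
  }
  beat_series(trace$t0 + (peaks - 1L) / fs, source = "ecg_reference")
}
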