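#' Beat series: strictly increasing event times
#'
#' A `beat_series` is the unit of truth for all beat-level computation: a
#' strictly increasing vector of event times in seconds, tagged with the
#' source that produced it (simulated ground truth, the online PPG detector,
#' or the offline ECG reference annotator).
#'
#' @param times Numeric vector of event times in seconds, strictly
#'   increasing, all non-negative.
#' @param source Label for provenance: one of `"ground_truth"`,
#'   `"ppg_detector"`, `"ecg_reference"`.
#' @param min_interval_s Physiological floor on consecutive inter-beat
#'   intervals (seconds). Intervals at or below this floor are rejected;
#'   set to `0` to disable the check. Default 0.2 s (300 bpm).
#'
#' @return An object of class `beat_series`: a numeric vector of times with
#'   attributes `source` and `min_interval_s`.
#' @examples
#' b <- beat_series(c(0, 1, 2, 3), source = "ground_truth")
#' beat_intervals(b)
#' @export
beat_series <- function(times,
                        source = c("ground_truth", "ppg_detector", "ecg_reference"),
                        min_interval_s = 0.2) {
  source <- match.arg(source)
  times <- as.numeric(times)
  if (anyNA(times)) stop_invalid("beat times must not contain NA")
  if (any(times < 0)) stop_invalid("beat times must be non-negative")
  if (is.unsorted(times, strictly = TRUE)) {
    stop_invalid("beat times must be strictly increasing")
  }
  if (length(times) >= 2L && min_interval_s > 0 &&
      any(diff(times) <= min_interval_s)) {
    stop_invalid(
      "inter-beat interval at or below the physiological floor of %g s",
      min_interval_s
    )
  }
  structure(times,
    source = source, min_interval_s = min_interval_s,
    class = "beat_series"
  )
}

#' @export
print.beat_series <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<beat_series: %d beats, source = %s>\n", n, attr(x, "source")))
  if (n > 0) {
    cat(sprintf(
      "  span %.3f .. %.3f s", min(x), max(x)
    ))
    if (n > 1) {
      ibi <- diff(unclass(x))
      cat(sprintf(
        ", mean IBI %.3f s (%.1f bpm)", mean(ibi), 60 / mean(ibi)
      ))
    }
    cat("\n")
  }
  invisible(x)
}

#' Inter-beat intervals of a beat series
#'
#' @param beats A [beat_series()].
#' @return Numeric vector of consecutive differences (seconds); length
#'   `length(beats) - 1`.
#' @export
beat_intervals <- function(beats) {
  diff(as.numeric(beats))
}

#' @export
`[.beat_series` <- function(x, i, ...) {
  beat_series(unclass(x)[i],
    source = attr(x, "source"),
    min_interval_s = attr(x, "min_interval_s")
  )
}

#' Uniformly sampled single-channel biosignal
#'
#' Container for a sampled PPG or ECG trace. Default sampling rates follow
#' the hardware this package emulates: 134 Hz for the smartwatch PPG channel
#' and 240 Hz for the clinical ECG reference.
#'
#' @param samples Numeric vector of amplitudes (arbitrary units), at least
#'   one sample.
#' @param sampling_rate_hz Sampling rate in Hz (> 0). If missing, defaults
#'   to 134 for `channel = "ppg"` and 240 for `channel = "ecg"`.
#' @param channel `"ppg"` or `"ecg"`.
#' @param t0 Time of the first sample in seconds (trace time, not
#'   wall-clock). Default 0.
#'
#' @return An object of class `signal_trace`.
#' @examples
#' tr <- signal_trace(sin(2 * pi * 1.2 * (0:999) / 134), channel = "ppg")
#' trace_duration(tr)
#' @export
signal_trace <- function(samples, sampling_rate_hz = NULL,
                         channel = c("ppg", "ecg"), t0 = 0) {
  channel <- match.arg(channel)
  if (is.null(sampling_rate_hz)) {
    sampling_rate_hz <- if (channel == "ppg") 134 else 240
  }
  if (!is_scalar_number(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop_invalid("sampling_rate_hz must be a single positive number")
  }
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop_invalid("a trace needs at least one sample")
  structure(
    list(
      samples = samples,
      sampling_rate_hz = sampling_rate_hz,
      channel = channel,
      t0 = as.numeric(t0)
    ),
    class = "signal_trace"
  )
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf(
    "<signal_trace: %s, %d samples @ %g Hz, %.2f s>\n",
    x$channel, length(x$samples), x$sampling_rate_hz, trace_duration(x)
  ))
  invisible(x)
}

#' Trace duration in seconds
#' @param trace A [signal_trace()].
#' @return Duration `n_samples / sampling_rate` in seconds.
#' @export
trace_duration <- function(trace) {
  length(trace$samples) / trace$sampling_rate_hz
}

#' Sample times of a trace
#' @param trace A [signal_trace()].
#' @return Numeric vector of sample times (seconds), starting at `t0`.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1L) / trace$sampling_rate_hz
}

#' @export
plot.signal_trace <- function(x, ..., beats = NULL) {
  plot(trace_times(x), x$samples,
    type = "l", xlab = "time (s)",
    ylab = "amplitude (a.u.)",
    main = sprintf("%s @ %g Hz", toupper(x$channel), x$sampling_rate_hz), ...
  )
  if (!is.null(beats)) {
    abline(v = as.numeric(beats), col = "firebrick", lty = 3)
  }
  invisible(x)
}
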