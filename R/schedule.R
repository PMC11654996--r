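#' Flash brightness envelope parameters
#'
#' The silhouette flash jumps instantaneously to full brightness at onset
#' and then fades back exponentially: `brightness(t) = exp(-t / tau)`.
#'
#' @param decay_time_constant_s Exponential decay time constant `tau` (s);
#'   default 0.4 s, a "slow fade" that has visibly decayed before the next
#'   beat at resting heart rates.
#' @return An object of class `envelope_params`.
#' @export
envelope_params <- function(decay_time_constant_s = 0.4) {
  if (decay_time_constant_s <= 0) stop_invalid("decay constant must be > 0")
  structure(
    list(peak_brightness = 1.0, decay_time_constant_s = decay_time_constant_s),
    class = "envelope_params"
  )
}

#' Brightness of a single flash
#'
#' @param t_since_onset_s Time since flash onset (s), >= 0; vectorised.
#' @param params An [envelope_params()].
#' @return Brightness in \[0, 1\]: 1 at onset, `exp(-t / tau)` afterwards.
#' @examples
#' envelope_brightness(0.4) # exp(-1) = 0.3679
#' @export
envelope_brightness <- function(t_since_onset_s, params = envelope_params()) {
  if (any(t_since_onset_s < 0)) stop_invalid("t_since_onset_s must be >= 0")
  exp(-t_since_onset_s / params$decay_time_constant_s)
}

#' Combined brightness of a flash schedule at given times
#'
#' Overlapping flashes combine by taking the maximum of their envelopes (a
#' fresh flash resets the silhouette to full brightness; an old flash never
#' darkens a newer one).
#'
#' @param schedule A [flash_schedule][schedule_sync()].
#' @param t Numeric vector of query times (s).
#' @return Brightness values in \[0, 1\]; 0 before the first onset.
#' @export
schedule_brightness <- function(schedule, t) {
  onsets <- schedule$onsets
  vapply(t, function(tt) {
    past <- onsets[onsets <= tt]
    if (length(past) == 0L) return(0)
    max(envelope_brightness(tt - past, schedule$envelope))
  }, numeric(1))
}

new_flash_schedule <- function(onsets, mode, factor, envelope) {
  onsets <- as.numeric(onsets)
  if (is.unsorted(onsets, strictly = TRUE)) {
    stop_invalid("flash onsets must be strictly increasing")
  }
  structure(
    list(onsets = onsets, mode = mode, factor = factor, envelope = envelope),
    class = "flash_schedule"
  )
}

#' @export
print.flash_schedule <- function(x, ...) {
  cat(sprintf(
    "<flash_schedule: %s, %d flashes%s>\n", x$mode, length(x$onsets),
    if (x$mode == "async") {
      sprintf(", factors {%s}", paste(sort(unique(x$factor)), collapse = ", "))
    } else {
      ""
    }
  ))
  invisible(x)
}

#' Synchronous flash schedule from detected beats
#'
#' One flash per beat, `lag_s` seconds after it. The default lag of 0.05 s
#' models the combined peak-detection and wireless transmission delay of a
#' watch-to-headset pipeline; it is constant, so the flash train remains
#' synchronous with the heartbeat. Only past beats are used (causality).
#'
#' @param beats A [beat_series()].
#' @param lag_s Constant display lag (s), >= 0.
#' @param envelope An [envelope_params()].
#' @return A `flash_schedule` with mode `"sync"` and factor 1.
#' @export
schedule_sync <- function(beats, lag_s = 0.05, envelope = envelope_params()) {
  if (lag_s < 0) stop_invalid("lag_s must be >= 0")
  new_flash_schedule(as.numeric(beats) + lag_s,
    mode = "sync",
    factor = rep(1.0, length(beats)), envelope = envelope
  )
}

#' Asynchronous ("shuffling mode") flash schedule
#'
#' Control-condition flashes at a frequency equal to a factor of 80%, 90%,
#' 110% or 120% of the current heart-rate estimate. The active factor is
#' re-drawn uniformly at random at the start of each factor epoch (every
#' `epoch_s` seconds); the inter-onset interval at time `t` is
#' `60 / (factor * hr(t))`. A factor of exactly 1 is rejected — it would
#' reproduce the synchronous condition.
#'
#' @param hr_bpm Heart-rate estimate: a single number (constant HR), a
#'   function of time returning bpm, or a [beat_series()] (converted with
#'   [hr_estimate_from_beats()]). Must be positive throughout.
#' @param duration_s Schedule duration (s).
#' @param factors Candidate rate factors; default `c(0.8, 0.9, 1.1, 1.2)`.
#' @param seed Seed for the factor draws; `NULL` uses the ambient stream.
#' @param epoch_s Length of a factor epoch (s); default 60.
#' @param envelope An [envelope_params()].
#' @return A `flash_schedule` with mode `"async"`; `factor` holds the
#'   active factor at each onset.
#' @examples
#' s <- schedule_async(60, 300, factors = 1.1)
#' diff(s$onsets)[1] # 60 / 66 = 0.9091 s
#' @export
schedule_async <- function(hr_bpm, duration_s,
                           factors = c(0.8, 0.9, 1.1, 1.2), seed = NULL,
                           epoch_s = 60, envelope = envelope_params()) {
  if (any(abs(factors - 1) < 1e-12)) {
    stop_invalid("factor 1.0 is not allowed in the asynchronous condition")
  }
  if (any(factors <= 0)) stop_invalid("factors must be positive")
  if (duration_s <= 0) stop_invalid("duration_s must be > 0")
  hr_fun <- if (inherits(hr_bpm, "beat_series")) {
    hr_estimate_from_beats(hr_bpm)
  } else if (is.function(hr_bpm)) {
    hr_bpm
  } else if (is_scalar_number(hr_bpm)) {
    function(t) rep(hr_bpm, length(t))
  } else {
    stop_invalid("hr_bpm must be a number, function of time, or beat_series")
  }
  n_epochs <- ceiling(duration_s / epoch_s)
  epoch_factor <- with_seed(seed, {
    if (length(factors) == 1L) {
      rep(factors, n_epochs)
    } else {
      sample(factors, n_epochs, replace = TRUE)
    }
  })
  onsets <- numeric(0)
  fac <- numeric(0)
  t <- 0
  repeat {
    f <- epoch_factor[min(floor(t / epoch_s) + 1, n_epochs)]
    hr <- hr_fun(t)
    if (!is.finite(hr) || hr <= 0) {
      stop_invalid("heart-rate estimate must be positive throughout")
    }
    t <- t + 60 / (f * hr)
    if (t >= duration_s) break
    onsets <- c(onsets, t)
    fac <- c(fac, f)
  }
  new_flash_schedule(onsets, mode = "async", factor = fac, envelope = envelope)
}

#' Running heart-rate estimate from detected beats
#'
#' The scheduler's notion of "actual heart rate": the running mean of the
#' last `window` inter-beat intervals, held constant between beats and
#' extrapolated beyond the last beat.
#'
#' @param beats A [beat_series()] with at least 2 beats.
#' @param window Number of most recent intervals averaged; default 8.
#' @return A function of time returning bpm.
#' @export
hr_estimate_from_beats <- function(beats, window = 8) {
  times <- as.numeric(beats)
  if (length(times) < 2L) stop_invalid("need at least 2 beats to estimate HR")
  ibi <- diff(times)
  est <- vapply(seq_along(ibi), function(i) {
    mean(ibi[max(1, i - window + 1):i])
  }, numeric(1))
  hr <- 60 / est
  # piecewise-constant, left-continuous: estimate available from the beat
  # that completes each interval; causal by construction
  f <- approxfun(times[-1], hr,
    method = "constant", rule = 2, f = 0
  )
  function(t) f(t)
}

#' Randomized session plan
#'
#' Plans the four 5-minute stimulation blocks of one experimental session:
#' two synchronous and two asynchronous blocks in uniformly random order,
#' separated by 3-minute rests.
#'
#' @param seed Seed for the block randomization; `NULL` uses the ambient
#'   stream.
#' @param block_s Block duration (s); default 300.
#' @param rest_s Rest between blocks (s); default 180.
#' @return An object of class `session_plan`: a data frame `blocks` with
#'   `block`, `condition`, `start_s`, `duration_s`, plus the seed.
#' @export
plan_session <- function(seed = NULL, block_s = 300, rest_s = 180) {
  conditions <- with_seed(seed, sample(c("sync", "sync", "async", "async")))
  start <- (seq_along(conditions) - 1) * (block_s + rest_s)
  structure(
    list(
      blocks = data.frame(
        block = seq_along(conditions),
        condition = conditions,
        start_s = start,
        duration_s = rep(block_s, length(conditions))
      ),
      rest_s = rest_s,
      seed = seed
    ),
    class = "session_plan"
  )
}

#' @export
print.session_plan <- function(x, ...) {
  cat(sprintf(
    "<session_plan: %s (%g s blocks, %g s rests)>\n",
    paste(x$blocks$condition, collapse = " -> "),
    x$blocks$duration_s[1], x$rest_s
  ))
  invisible(x)
}

#' @export
plot.flash_schedule <- function(x, t_max = NULL, dt = 0.01, ...) {
  if (is.null(t_max)) t_max <- max(x$onsets) + 1
  t <- seq(0, t_max, by = dt)
  plot(t, schedule_brightness(x, t),
    type = "l", ylim = c(0, 1),
    xlab = "time (s)", ylab = "brightness",
    main = sprintf("%s flash schedule", x$mode), ...
  )
  invisible(x)
}
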