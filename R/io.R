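#' Write / read a signal trace as annotated CSV
#'
#' Traces are stored as two-column CSV (`time_s`, `amplitude`) preceded by
#' `#`-comment header lines carrying the metadata needed for a lossless
#' round-trip: `sampling_rate_hz`, `channel` and `t0`.
#'
#' @param trace A [signal_trace()].
#' @param path File path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   [signal_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "signal_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# pulsesync signal trace",
    sprintf("# sampling_rate_hz: %.10g", trace$sampling_rate_hz),
    sprintf("# channel: %s", trace$channel),
    sprintf("# t0: %.10g", trace$t0),
    "time_s,amplitude"
  ), con)
  write.table(
    data.frame(
      time_s = sprintf("%.6f", trace_times(trace)),
      amplitude = sprintf("%.10g", trace$samples)
    ),
    con,
    sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

read_header_field <- function(lines, key, path) {
  pat <- sprintf("^#\\s*%s:\\s*(.+)$", key)
  hit <- grep(pat, lines, value = TRUE)
  if (length(hit) == 0L) {
    stop_invalid("file '%s' is missing required header field '%s'", path, key)
  }
  sub(pat, "\\1", hit[1])
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#")]
  fs <- as.numeric(read_header_field(header, "sampling_rate_hz", path))
  channel <- read_header_field(header, "channel", path)
  t0 <- as.numeric(read_header_field(header, "t0", path))
  body <- lines[!startsWith(lines, "#")]
  df <- read.csv(text = body)
  signal_trace(df$amplitude, fs, channel = channel, t0 = t0)
}

#' Write / read a beat series
#'
#' Beats are stored as one time (seconds) per line under a `time_s` header,
#' with the source label in a `#` comment.
#'
#' @param beats A [beat_series()].
#' @param path File path.
#' @return `write_beats` returns `path` invisibly; `read_beats` a
#'   [beat_series()].
#' @export
write_beats <- function(beats, path) {
  stopifnot(inherits(beats, "beat_series"))
  writeLines(c(
    sprintf("# source: %s", attr(beats, "source")),
    "time_s",
    sprintf("%.6f", as.numeric(beats))
  ), path)
  invisible(path)
}

#' @rdname write_beats
#' @export
read_beats <- function(path) {
  lines <- readLines(path)
  source <- read_header_field(lines[startsWith(lines, "#")], "source", path)
  body <- lines[!startsWith(lines, "#")]
  df <- read.csv(text = body)
  beat_series(df$time_s, source = source)
}

#' Write a flash schedule as CSV
#'
#' @param schedule A [flash_schedule][schedule_sync()].
#' @param path File path.
#' @return `path`, invisibly. Columns: `onset_s`, `factor`, `mode`.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "flash_schedule"))
  write.csv(
    data.frame(
      onset_s = schedule$onsets,
      factor = schedule$factor,
      mode = schedule$mode
    ),
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' Run the full synthetic pipeline end to end
#'
#' Demonstration and integration entry point: simulates ground-truth beats
#' and a PPG/ECG recording pair, runs the online PPG detector and the
#' offline ECG annotator, validates the detector against both ground truth
#' and the ECG reference, builds a synchronous and an asynchronous flash
#' schedule, simulates a 20-participant study table, and runs the outcome
#' analyses. All randomness derives from `seed`, so two runs with the same
#' seed produce identical reports.
#'
#' @param seed Integer seed for the whole pipeline.
#' @param duration_s Duration of the simulated recording (s); default 300.
#' @param mean_hr_bpm,hrv_sd_s Simulated heart-rate parameters.
#' @param noise A [noise_spec()], a [noise_profile()] name, or `NULL`.
#' @param out_dir If non-NULL, the report is also written there as
#'   `demo_report.json` (plus trace/beat/schedule CSVs).
#' @return A nested list report (invisibly if `out_dir` is given).
#' @export
run_demo <- function(seed = 42, duration_s = 300, mean_hr_bpm = 72,
                     hrv_sd_s = 0.05, noise = "mild", out_dir = NULL) {
  if (is.character(noise)) {
    noise <- noise_profile(noise, duration_s = duration_s,
                           seed = derive_seed(seed, 1))
  }
  truth <- simulate_beat_times(mean_hr_bpm, hrv_sd_s, duration_s,
                               seed = derive_seed(seed, 2))
  ppg <- render_ppg(truth, noise = noise, duration_s = duration_s)
  ecg <- render_ecg(truth, duration_s = duration_s)
  det <- detect_ppg_beats(ppg)
  ecg_ref <- detect_ecg_rpeaks(ecg)
  val_truth <- validate_beats(truth, det$beats)
  val_ecg <- validate_beats(ecg_ref, det$beats)

  plan <- plan_session(seed = derive_seed(seed, 3))
  sync_sched <- schedule_sync(det$beats)
  async_sched <- schedule_async(det$beats, duration_s,
                                seed = derive_seed(seed, 4))

  pain <- simulate_pain_table(seed = derive_seed(seed, 5))
  deltas <- compute_pain_deltas(pain)
  q <- simulate_questionnaires(seed = derive_seed(seed, 6))
  sus <- aggregate_sus(q$sus)
  ssq <- aggregate_ssq(q$ssq)
  own <- ownership_contrast(q$ownership_sync, q$ownership_async)

  tests <- lapply(
    split(deltas, list(deltas$instrument, deltas$site), drop = TRUE),
    function(d) {
      wide <- merge(
        d[d$condition == "sync", c("participant", "delta")],
        d[d$condition == "async", c("participant", "delta")],
        by = "participant", suffixes = c("_sync", "_async")
      )
      tr <- paired_condition_test(wide$delta_sync, wide$delta_async)
      list(
        branch = tr$branch, statistic = tr$statistic, p_value = tr$p.value,
        mean_sync = mean(wide$delta_sync), mean_async = mean(wide$delta_async)
      )
    }
  )

  report <- list(
    seed = seed,
    simulation = list(
      mean_hr_bpm = mean_hr_bpm, hrv_sd_s = hrv_sd_s,
      duration_s = duration_s, n_true_beats = length(truth)
    ),
    detection = list(
      n_detected = length(det$beats),
      max_decision_latency_ms = 1000 * max(det$decision_latencies_s),
      mean_hr_estimate_bpm = 60 / mean(beat_intervals(det$beats))
    ),
    validation_vs_truth = list(
      rmse_percent = val_truth$rmse_percent,
      n_missed = val_truth$n_missed, n_extra = val_truth$n_extra
    ),
    validation_vs_ecg = list(
      rmse_percent = val_ecg$rmse_percent,
      n_reference_beats = val_ecg$n_reference_beats,
      n_missed = val_ecg$n_missed, n_extra = val_ecg$n_extra
    ),
    session_plan = plan$blocks$condition,
    schedules = list(
      n_sync_flashes = length(sync_sched$onsets),
      n_async_flashes = length(async_sched$onsets),
      async_factors_used = sort(unique(async_sched$factor))
    ),
    questionnaires = list(
      sus_composite = sus$composite, ssq_composite = ssq$composite,
      ownership = list(
        median_sync = own$median_sync, median_async = own$median_async,
        statistic = own$test$statistic, p_value = own$test$p.value
      )
    ),
    pain_tests = tests
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trace(ppg, file.path(out_dir, "ppg.csv"))
    write_beats(det$beats, file.path(out_dir, "detected_beats.csv"))
    write_beats(ecg_ref, file.path(out_dir, "ecg_beats.csv"))
    write_schedule(sync_sched, file.path(out_dir, "schedule_sync.csv"))
    write_schedule(async_sched, file.path(out_dir, "schedule_async.csv"))
    jsonlite::write_json(report, file.path(out_dir, "demo_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  report
}
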