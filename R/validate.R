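#' Match detected beats to a reference series
#'
#' One-to-one matching of a measured [beat_series()] (e.g. the PPG detector
#' output) against a reference series (e.g. ECG R-peaks). Because the
#' peripheral pulse lags cardiac activation by a roughly constant
#' pulse-transit plus processing delay, the median offset between measured
#' beats and their nearest reference beats is removed before matching; each
#' accepted pair must then agree within `tol_s`. With `tol_s` below half
#' the minimum plausible inter-beat interval, every measured beat has a
#' unique nearest reference beat, and for each reference beat the closest
#' candidate wins.
#'
#' @param ref Reference [beat_series()] (non-empty).
#' @param meas Measured [beat_series()].
#' @param tol_s Matching tolerance after offset removal (s); default 0.4,
#'   which must stay below half the minimum plausible interval.
#' @return A list of class `beat_match`: `pairs` (data frame with
#'   `ref_index`, `ref_time`, `meas_time`), `unmatched_ref` (indices),
#'   `unmatched_meas` (indices), and `offset_s` (the removed median lag).
#' @export
match_beats <- function(ref, meas, tol_s = 0.4) {
  ref <- as.numeric(ref)
  meas <- as.numeric(meas)
  if (length(ref) == 0L) stop_invalid("reference beat series is empty")
  if (tol_s <= 0) stop_invalid("tol_s must be > 0")
  if (length(meas) == 0L) {
    return(structure(
      list(
        pairs = data.frame(
          ref_index = integer(), ref_time = numeric(), meas_time = numeric()
        ),
        unmatched_ref = seq_along(ref), unmatched_meas = integer(),
        offset_s = 0
      ),
      class = "beat_match"
    ))
  }
  nearest_ref <- findInterval(meas, ref)
  nearest_ref <- pmax(nearest_ref, 1L)
  upper <- pmin(nearest_ref + 1L, length(ref))
  pick_upper <- abs(meas - ref[upper]) < abs(meas - ref[nearest_ref])
  nearest_ref[pick_upper] <- upper[pick_upper]
  offset <- median(meas - ref[nearest_ref])
  adj <- meas - offset

  # re-derive nearest reference on the lag-corrected times
  nearest_ref <- findInterval(adj, ref)
  nearest_ref <- pmax(nearest_ref, 1L)
  upper <- pmin(nearest_ref + 1L, length(ref))
  pick_upper <- abs(adj - ref[upper]) < abs(adj - ref[nearest_ref])
  nearest_ref[pick_upper] <- upper[pick_upper]

  err <- abs(adj - ref[nearest_ref])
  match_of_ref <- rep(NA_integer_, length(ref))
  for (j in order(err)) { # closest candidate wins each reference beat
    if (err[j] <= tol_s && is.na(match_of_ref[nearest_ref[j]])) {
      match_of_ref[nearest_ref[j]] <- j
    }
  }
  matched_ref <- which(!is.na(match_of_ref))
  pairs <- data.frame(
    ref_index = matched_ref,
    ref_time = ref[matched_ref],
    meas_time = meas[match_of_ref[matched_ref]]
  )
  structure(
    list(
      pairs = pairs,
      unmatched_ref = setdiff(seq_along(ref), matched_ref),
      unmatched_meas = setdiff(seq_along(meas), match_of_ref[matched_ref]),
      offset_s = offset
    ),
    class = "beat_match"
  )
}

as_pairs <- function(x) {
  if (inherits(x, "beat_match")) return(x$pairs)
  if (is.matrix(x)) {
    x <- as.data.frame(x)
    names(x) <- c("ref_time", "meas_time")
  }
  if (is.data.frame(x) && !"ref_index" %in% names(x)) {
    x$ref_index <- seq_len(nrow(x)) # assume consecutively matched
  }
  x[order(x$ref_index), ]
}

#' Relative peak-to-peak interval RMSE, in percent
#'
#' The detector's interval-accuracy metric: for every pair of consecutively
#' matched beats (adjacent in the reference series, so no missed beat lies
#' between them), the measured interval `m` is compared with the reference
#' interval `r`, and the root mean square of the relative errors
#' `(m - r) / r` is reported as a percentage:
#' `100 * sqrt(mean(((m - r) / r)^2))`.
#'
#' @param matched A `beat_match` from [match_beats()], or a two-column
#'   matrix/data frame of (ref_time, meas_time) pairs assumed consecutive.
#' @return Interval RMSE as a percentage (>= 0).
#' @examples
#' interval_rmse_percent(cbind(0:3, c(0, 1.01, 2.00, 3.00))) # 0.8165
#' @export
interval_rmse_percent <- function(matched) {
  pairs <- as_pairs(matched)
  if (nrow(pairs) < 3L) {
    stop_invalid("need at least 3 matched beats (2 intervals) for interval RMSE")
  }
  adjacent <- diff(pairs$ref_index) == 1L
  if (sum(adjacent) < 2L) {
    stop_invalid("need at least 2 consecutively matched intervals")
  }
  r <- diff(pairs$ref_time)[adjacent]
  m <- diff(pairs$meas_time)[adjacent]
  100 * sqrt(mean(((m - r) / r)^2))
}

#' Count missed beats against a reference
#'
#' Automates the gap count between a measured and a reference beat train: a
#' reference beat is missed when it goes unmatched while lying strictly
#' inside the matched span (equivalently, a measured interval spanning `k`
#' reference intervals contributes `k - 1` misses). Reference beats before
#' the first or after the last matched beat are edge effects and excluded.
#'
#' @inheritParams match_beats
#' @param match Optionally, a precomputed [match_beats()] result.
#' @return Non-negative integer count of missed beats.
#' @export
count_missed_beats <- function(ref, meas, tol_s = 0.4, match = NULL) {
  if (is.null(match)) match <- match_beats(ref, meas, tol_s)
  if (nrow(match$pairs) == 0L) return(0L)
  span <- range(match$pairs$ref_index)
  sum(match$unmatched_ref > span[1] & match$unmatched_ref < span[2])
}

#' Validate a detected beat series against a reference
#'
#' Full validation of one recording: matches the measured series to the
#' reference (constant-lag removal, one-to-one matching), then reports the
#' relative interval RMSE, the missed-beat count, and the extra
#' (unmatched-measured) count.
#'
#' @inheritParams match_beats
#' @return An object of class `validation_report`: `rmse_percent`,
#'   `n_reference_beats`, `n_matched`, `n_missed`, `n_extra`,
#'   `n_edge_excluded`, `offset_s` and the `pairs` table.
#' @examples
#' truth <- simulate_beat_times(70, 0.04, 60, seed = 2)
#' det <- detect_ppg_beats(render_ppg(truth, duration_s = 60))
#' validate_beats(truth, det$beats)
#' @export
validate_beats <- function(ref, meas, tol_s = 0.4) {
  if (inherits(meas, "detection_result")) meas <- meas$beats
  match <- match_beats(ref, meas, tol_s)
  n_ref <- length(as.numeric(ref))
  n_missed <- count_missed_beats(ref, meas, tol_s, match = match)
  rmse <- if (nrow(match$pairs) >= 3L &&
              sum(diff(match$pairs$ref_index) == 1L) >= 2L) {
    interval_rmse_percent(match)
  } else {
    NA_real_
  }
  structure(
    list(
      rmse_percent = rmse,
      n_reference_beats = n_ref,
      n_matched = nrow(match$pairs),
      n_missed = n_missed,
      n_extra = length(match$unmatched_meas),
      n_edge_excluded = n_ref - nrow(match$pairs) - n_missed,
      offset_s = match$offset_s,
      pairs = match$pairs
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  reference beats : %d\n", x$n_reference_beats))
  cat(sprintf("  matched         : %d\n", x$n_matched))
  cat(sprintf("  missed          : %d\n", x$n_missed))
  cat(sprintf("  extra           : %d\n", x$n_extra))
  cat(sprintf("  interval RMSE   : %.3f %%\n", x$rmse_percent))
  cat(sprintf("  constant lag    : %.1f ms\n", 1000 * x$offset_s))
  invisible(x)
}

#' Pool validation reports across recordings
#'
#' Aggregates per-recording validation reports the way a multi-participant
#' validation is summarised: mean and sample SD of the per-recording
#' interval RMSE, plus grand totals of reference beats and missed beats.
#'
#' @param reports A list of [validate_beats()] reports (at least one).
#' @return An object of class `pooled_summary`: `mean_rmse_percent`,
#'   `sd_rmse_percent` (0 with `sd_defined = FALSE` for a single report),
#'   `total_beats`, `total_missed`, `n_recordings`.
#' @export
pool_reports <- function(reports) {
  if (inherits(reports, "validation_report")) reports <- list(reports)
  if (length(reports) < 1L) stop_invalid("need at least one report to pool")
  rmse <- vapply(reports, function(r) r$rmse_percent, numeric(1))
  structure(
    list(
      mean_rmse_percent = mean(rmse, na.rm = TRUE),
      sd_rmse_percent = if (length(rmse) > 1L) sd(rmse, na.rm = TRUE) else 0,
      sd_defined = length(rmse) > 1L,
      total_beats = sum(vapply(reports, function(r) r$n_reference_beats,
                               numeric(1))),
      total_missed = sum(vapply(reports, function(r) r$n_missed, numeric(1))),
      n_recordings = length(reports)
    ),
    class = "pooled_summary"
  )
}

#' @export
print.pooled_summary <- function(x, ...) {
  cat(sprintf(
    "<pooled_summary: %d recordings, RMSE %.2f%% (SD %.2f%%), %d/%d beats missed>\n",
    x$n_recordings, x$mean_rmse_percent, x$sd_rmse_percent,
    x$total_missed, x$total_beats
  ))
  invisible(x)
}
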