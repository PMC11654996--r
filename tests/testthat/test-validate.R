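mk <- function(x, src = "ground_truth") beat_series(x, source = src)

test_that("identical series match completely", {
  b <- mk(0:9)
  m <- match_beats(b, b)
  expect_equal(nrow(m$pairs), 10)
  expect_length(m$unmatched_ref, 0)
  expect_length(m$unmatched_meas, 0)
  expect_equal(m$offset_s, 0)
})

test_that("a constant lag is removed before matching", {
  ref <- mk(0:9)
  meas <- mk(0:9 + 0.25, src = "ppg_detector")
  m <- match_beats(ref, meas)
  expect_equal(nrow(m$pairs), 10)
  expect_equal(m$offset_s, 0.25)
  oracle <- oracle_match(as.numeric(ref), as.numeric(meas), tol = 0.4,
                         offset = 0.25)
  expect_equal(m$pairs$ref_index, oracle$pairs$ref_index)
})

test_that("a dropped beat leaves one unmatched reference", {
  ref <- mk(0:9)
  meas <- mk(setdiff(0:9, 5), src = "ppg_detector")
  m <- match_beats(ref, meas)
  expect_equal(nrow(m$pairs), 9)
  expect_equal(m$unmatched_ref, 6L) # the beat at t = 5 (1-based index 6)
  oracle <- oracle_match(as.numeric(ref), as.numeric(meas), tol = 0.4)
  expect_equal(nrow(m$pairs), oracle$n)
})

test_that("matching agrees with brute-force assignment on jittered series", {
  set.seed(42)
  for (rep in 1:5) {
    ref <- cumsum(runif(8, 0.7, 1.1))
    keep <- runif(8) > 0.15
    meas <- (ref + rnorm(8, 0.2, 0.03))[keep]
    m <- match_beats(mk(ref), mk(sort(meas), src = "ppg_detector"))
    oracle <- oracle_match(ref, sort(meas), tol = 0.4, offset = m$offset_s)
    expect_equal(nrow(m$pairs), oracle$n)
  }
})

test_that("empty reference is an error, empty measurement is not", {
  expect_error(match_beats(mk(numeric()), mk(0:3)), "empty")
  m <- match_beats(mk(0:3), mk(numeric(), src = "ppg_detector"))
  expect_equal(m$unmatched_ref, 1:4)
})

test_that("interval RMSE matches direct arithmetic", {
  # perfect agreement
  expect_equal(interval_rmse_percent(cbind(0:3, 0:3)), 0)
  # ref intervals all 1 s; measured 1.01, 0.99, 1.00
  pairs <- cbind(c(0, 1, 2, 3), c(0, 1.01, 2.00, 3.00))
  expect_equal(interval_rmse_percent(pairs),
               oracle_rmse_percent(c(1, 1, 1), c(1.01, 0.99, 1.00)))
  expect_equal(interval_rmse_percent(pairs), 0.8165, tolerance = 1e-4)
  # ref intervals 0.80, 0.90; measured 0.84, 0.90 (constant 0.1 lag);
  # relative errors 0.04/0.80 = 0.05 and 0
  pairs2 <- cbind(c(0, 0.8, 1.7), c(0.1, 0.94, 1.84))
  expect_equal(interval_rmse_percent(pairs2),
               oracle_rmse_percent(c(0.8, 0.9), c(0.84, 0.9)))
  expect_equal(interval_rmse_percent(pairs2), 3.536, tolerance = 1e-3)
})

test_that("interval RMSE refuses fewer than two intervals", {
  expect_error(interval_rmse_percent(cbind(0:1, 0:1)), "3 matched beats")
})

test_that("intervals spanning a missed beat are excluded from the RMSE", {
  ref <- mk(0:9)
  meas <- mk(setdiff(0:9, 5), src = "ppg_detector")
  m <- match_beats(ref, meas)
  # all used intervals are exact, so RMSE is 0 despite the gap
  expect_equal(interval_rmse_percent(m), 0)
})

test_that("missed-beat counting follows the interior-gap rule", {
  ref <- mk(0:9)
  expect_identical(count_missed_beats(ref, ref), 0L)
  expect_equal(count_missed_beats(ref, mk(setdiff(0:9, 5), "ppg_detector")), 1)
  expect_equal(count_missed_beats(ref, mk(setdiff(0:9, 5:6), "ppg_detector")), 2)
  # beats missing at the edges are excluded, not counted as missed
  expect_equal(count_missed_beats(ref, mk(1:8, "ppg_detector")), 0)
})

test_that("conservation: matched + missed + edge-excluded = reference count", {
  set.seed(7)
  for (rep in 1:10) {
    ref <- cumsum(runif(30, 0.6, 1.2))
    keep <- runif(30) > 0.2
    meas <- sort(ref[keep] + rnorm(sum(keep), 0.2, 0.02))
    r <- validate_beats(mk(ref), mk(meas, "ppg_detector"))
    expect_equal(r$n_matched + r$n_missed + r$n_edge_excluded,
                 r$n_reference_beats)
    expect_gte(r$n_edge_excluded, 0)
  }
})

test_that("injecting one miss adds exactly one missed beat, RMSE unchanged", {
  ref <- mk(cumsum(c(0, rep(1, 19))))
  meas_perfect <- mk(as.numeric(ref) + 0.2, "ppg_detector")
  r0 <- validate_beats(ref, meas_perfect)
  dropped <- mk(as.numeric(meas_perfect)[-10], "ppg_detector")
  r1 <- validate_beats(ref, dropped)
  expect_equal(r1$n_missed, r0$n_missed + 1)
  expect_equal(r1$rmse_percent, r0$rmse_percent)
})

test_that("pooling reports follows sample statistics and conserves totals", {
  mk_report <- function(rmse, n_ref, n_missed) {
    structure(
      list(rmse_percent = rmse, n_reference_beats = n_ref,
           n_missed = n_missed),
      class = "validation_report"
    )
  }
  single <- pool_reports(list(mk_report(2.5, 100, 1)))
  expect_equal(single$mean_rmse_percent, 2.5)
  expect_equal(single$sd_rmse_percent, 0)
  expect_false(single$sd_defined)

  two <- pool_reports(list(mk_report(2, 100, 0), mk_report(4, 120, 2)))
  expect_equal(two$mean_rmse_percent, 3)
  expect_equal(two$sd_rmse_percent, sqrt(2), tolerance = 1e-9)
  expect_equal(two$total_beats, 220)
  expect_equal(two$total_missed, 2)

  many <- lapply(1:20, function(i) mk_report(runif(1, 1, 5), 90 + i, i %% 3))
  pooled <- pool_reports(many)
  expect_equal(pooled$total_beats,
               sum(vapply(many, function(r) r$n_reference_beats, numeric(1))))
  expect_equal(pooled$total_missed,
               sum(vapply(many, function(r) r$n_missed, numeric(1))))
  expect_error(pool_reports(list()), "at least one")
})

test_that("validation report accepts a detection result directly", {
  rec <- make_recording(duration_s = 30, hr = 65, hrv = 0.04, seed = 11)
  det <- detect_ppg_beats(rec$ppg)
  r <- validate_beats(rec$truth, det)
  expect_s3_class(r, "validation_report")
  expect_equal(r$n_missed, 0)
  expect_lt(r$rmse_percent, 2)
})
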