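#' Aggregate System Usability Scale items
#'
#' The usability questionnaire uses three 5-point Likert items (1 = strongly
#' disagree, 5 = strongly agree). The per-participant composite is the
#' unweighted mean of the three items; the group composite is the mean of
#' the item means, which equals the mean of the participant composites when
#' responses are complete.
#'
#' @param responses Either a numeric matrix / data frame with one row per
#'   participant and one column per item (values in 1..5), or a numeric
#'   vector of per-item means (e.g. transcribed from a published table).
#' @return A list of class `questionnaire_summary`: `item_means`,
#'   `composite` (group), `composite_sd`, and `participant_composites`
#'   (NULL when only item means were supplied).
#' @examples
#' aggregate_sus(c(4.54, 4.36, 4.36))$composite # 4.42
#' @export
aggregate_sus <- function(responses) {
  aggregate_items(responses, n_items = 3, range = c(1, 5), scale = "SUS")
}

#' Aggregate Simulator Sickness Questionnaire items
#'
#' Seven symptom items on a 4-point scale (1 = none .. 4 = severe),
#' aggregated exactly as [aggregate_sus()]: unweighted item mean.
#'
#' @inheritParams aggregate_sus
#' @return A `questionnaire_summary` (see [aggregate_sus()]).
#' @examples
#' aggregate_ssq(c(1, 1, 2, 1, 1, 1, 1))$composite # 8/7
#' @export
aggregate_ssq <- function(responses) {
  aggregate_items(responses, n_items = 7, range = c(1, 4), scale = "SSQ")
}

#' Aggregate body-ownership items
#'
#' Seven ownership items on a 7-point Likert scale from 0 (complete
#' disagreement) to 6 (complete agreement), answered once per stimulation
#' condition. The per-participant condition score is the item mean.
#'
#' @inheritParams aggregate_sus
#' @return A `questionnaire_summary` (see [aggregate_sus()]).
#' @export
aggregate_ownership <- function(responses) {
  aggregate_items(responses, n_items = 7, range = c(0, 6), scale = "ownership")
}

aggregate_items <- function(responses, n_items, range, scale) {
  if (is.data.frame(responses)) responses <- as.matrix(responses)
  if (is.matrix(responses)) {
    if (ncol(responses) != n_items) {
      stop_invalid("%s expects %d items, got %d columns", scale, n_items,
                   ncol(responses))
    }
    if (anyNA(responses)) stop_invalid("%s responses contain NA", scale)
    if (any(responses < range[1] | responses > range[2])) {
      stop_invalid("%s item scores must lie in [%g, %g]", scale,
                   range[1], range[2])
    }
    item_means <- colMeans(responses)
    pc <- rowMeans(responses)
    composite_sd <- sd(pc)
  } else if (is.numeric(responses)) {
    if (length(responses) != n_items) {
      stop_invalid("%s expects %d item means, got %d", scale, n_items,
                   length(responses))
    }
    if (any(responses < range[1] | responses > range[2])) {
      stop_invalid("%s item means must lie in [%g, %g]", scale,
                   range[1], range[2])
    }
    item_means <- responses
    pc <- NULL
    composite_sd <- NA_real_
  } else {
    stop_invalid("%s responses must be a matrix, data frame or numeric vector",
                 scale)
  }
  structure(
    list(
      scale = scale,
      item_means = unname(item_means),
      composite = mean(item_means),
      composite_sd = composite_sd,
      participant_composites = unname(pc)
    ),
    class = "questionnaire_summary"
  )
}

#' @export
print.questionnaire_summary <- function(x, ...) {
  cat(sprintf(
    "<%s summary: composite %.3f%s>\n", x$scale, x$composite,
    if (is.na(x$composite_sd)) "" else sprintf(" (SD %.3f)", x$composite_sd)
  ))
  invisible(x)
}

#' Pre/post pain deltas with instrument sign conventions
#'
#' Builds per-participant, per-condition outcome deltas from a long-format
#' table of pain measurements. For each block, the bilateral mean (over
#' left/right) is taken per phase; the block delta follows the instrument's
#' sign convention, chosen so that a positive value always means increased
#' pain sensitivity:
#' \itemize{
#'   \item Algopeg (0-10 numerical rating of pain at a fixed clamping
#'     force): `post - pre` — higher ratings after stimulation mean more
#'     pain reported.
#'   \item Somedic (pressure-pain threshold in kPa, each value the mean of
#'     3 ramp repetitions): `pre - post` — a dropped threshold means pain
#'     arrives at lower pressure.
#' }
#' Each condition is measured in two blocks; the condition delta is the
#' mean of its two block deltas.
#'
#' @param measures Data frame with columns `participant`, `block` (1-4),
#'   `condition` (`"sync"`/`"async"`), `phase` (`"pre"`/`"post"`),
#'   `instrument` (`"algopeg"`/`"somedic"`), `site` (`"finger"`/
#'   `"earlobe"`; earlobe only for algopeg), `side` (`"left"`/`"right"`),
#'   `value` (NRS 0-10 for algopeg, kPa > 0 for somedic).
#' @return Data frame with one row per participant x condition x
#'   instrument x site and a signed `delta` column.
#' @export
compute_pain_deltas <- function(measures) {
  required <- c("participant", "block", "condition", "phase", "instrument",
                "site", "side", "value")
  missing_cols <- setdiff(required, names(measures))
  if (length(missing_cols)) {
    stop_invalid("measures is missing column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  bad <- with(measures, instrument == "somedic" & site == "earlobe")
  if (any(bad)) stop_invalid("somedic is measured at the finger only")
  alg <- measures$value[measures$instrument == "algopeg"]
  if (any(alg < 0 | alg > 10)) {
    stop_invalid("algopeg values must lie on the 0-10 rating scale")
  }
  som <- measures$value[measures$instrument == "somedic"]
  if (any(som <= 0)) stop_invalid("somedic thresholds must be positive (kPa)")

  # bilateral mean per participant/block/instrument/site/phase
  bilat <- stats::aggregate(
    value ~ participant + block + condition + phase + instrument + site,
    data = measures, FUN = mean
  )
  n_sides <- stats::aggregate(
    side ~ participant + block + condition + phase + instrument + site,
    data = measures, FUN = length
  )
  if (any(n_sides$side != 2L)) {
    off <- n_sides[n_sides$side != 2L, , drop = FALSE]
    stop_invalid(
      "missing bilateral data for: %s",
      paste(apply(off[1:6], 1, paste, collapse = "/"), collapse = "; ")
    )
  }

  wide <- stats::reshape(
    bilat,
    idvar = c("participant", "block", "condition", "instrument", "site"),
    timevar = "phase", direction = "wide"
  )
  if (!all(c("value.pre", "value.post") %in% names(wide)) ||
      anyNA(wide$value.pre) || anyNA(wide$value.post)) {
    miss <- wide[is.na(wide$value.pre) | is.na(wide$value.post), , drop = FALSE]
    stop_invalid(
      "missing pre or post phase for: %s",
      paste(apply(miss[1:5], 1, paste, collapse = "/"), collapse = "; ")
    )
  }
  wide$delta_block <- ifelse(
    wide$instrument == "algopeg",
    wide$value.post - wide$value.pre, # more pain reported
    wide$value.pre - wide$value.post # threshold dropped
  )
  out <- stats::aggregate(
    delta_block ~ participant + condition + instrument + site,
    data = wide, FUN = mean
  )
  n_blocks <- stats::aggregate(
    delta_block ~ participant + condition + instrument + site,
    data = wide, FUN = length
  )
  if (any(n_blocks$delta_block != 2L)) {
    off <- n_blocks[n_blocks$delta_block != 2L, , drop = FALSE]
    stop_invalid(
      "expected 2 blocks per condition, violated for: %s",
      paste(apply(off[1:4], 1, paste, collapse = "/"), collapse = "; ")
    )
  }
  names(out)[names(out) == "delta_block"] <- "delta"
  out[order(out$participant, out$condition, out$instrument, out$site), ,
      drop = FALSE]
}

#' Wilcoxon signed-rank test with Pratt zero handling
#'
#' Paired signed-rank test using the normal approximation, with the two
#' conventions documented and fixed: zero differences are ranked together
#' with the non-zero ones and then discarded (Pratt), and tied absolute
#' differences receive average ranks. The statistic is `V`, the sum of the
#' ranks of the positive differences; `Z` standardises `V` by the
#' Pratt-corrected null mean and the tie-corrected null variance.
#'
#' @param x,y Paired numeric vectors (`y` defaults to zeros: one-sample
#'   test against `mu`).
#' @param mu Null shift; default 0.
#' @param alternative `"two.sided"`, `"greater"` (x tends above y) or
#'   `"less"`.
#' @return A list of class `wilcoxon_report`: `statistic` (V), `z`,
#'   `p.value`, `n`, `n_zero`, `alternative`, `degenerate` (TRUE when all
#'   differences are zero — no test is performed).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, mu = 0,
                                 alternative = c("two.sided", "greater",
                                                 "less")) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x - mu else x - y - mu
  if (anyNA(d)) stop_invalid("paired differences contain NA")
  n <- length(d)
  if (all(d == 0)) {
    return(structure(
      list(
        statistic = 0, z = NA_real_, p.value = NA_real_, n = n,
        n_zero = n, alternative = alternative, degenerate = TRUE,
        method = "Wilcoxon signed rank (Pratt zeros, average ranks)"
      ),
      class = "wilcoxon_report"
    ))
  }
  r <- rank(abs(d)) # zeros ranked with everything else (Pratt)
  nonzero <- d != 0
  v <- sum(r[d > 0])
  n_zero <- sum(!nonzero)
  # null moments under Pratt: zeros occupy the lowest ranks
  e_v <- (n * (n + 1) - n_zero * (n_zero + 1)) / 4
  var_v <- (n * (n + 1) * (2 * n + 1) -
              n_zero * (n_zero + 1) * (2 * n_zero + 1)) / 24
  ties <- table(r[nonzero])
  var_v <- var_v - sum(ties^3 - ties) / 48
  z <- (v - e_v) / sqrt(var_v)
  p <- switch(alternative,
    two.sided = 2 * pnorm(-abs(z)),
    greater = pnorm(z, lower.tail = FALSE),
    less = pnorm(z)
  )
  structure(
    list(
      statistic = v, z = z, p.value = min(p, 1), n = n, n_zero = n_zero,
      alternative = alternative, degenerate = FALSE,
      method = "Wilcoxon signed rank (Pratt zeros, average ranks)"
    ),
    class = "wilcoxon_report"
  )
}

#' @export
print.wilcoxon_report <- function(x, ...) {
  if (x$degenerate) {
    cat("<wilcoxon_report: all paired differences zero - no test performed>\n")
  } else {
    cat(sprintf(
      "<wilcoxon_report: V = %g, Z = %.3f, p = %.4g (%s), n = %d (%d zeros)>\n",
      x$statistic, x$z, x$p.value, x$alternative, x$n, x$n_zero
    ))
  }
  invisible(x)
}

#' Normality-gated paired test between conditions
#'
#' The study's testing recipe for a paired outcome: the paired differences
#' are checked for normality with the Lilliefors variant of the
#' Kolmogorov-Smirnov test (mean and SD estimated from the sample); if not
#' rejected at `alpha`, a one-sided paired t test is used, otherwise the
#' one-sided Wilcoxon signed-rank test ([wilcoxon_signed_rank()]). The
#' default direction `"less"` tests the hypothesis that synchronous
#' stimulation lowers pain sensitivity relative to asynchronous (sync
#' deltas below async deltas).
#'
#' @param sync,async Paired numeric vectors of per-participant deltas
#'   (same length, n >= 5).
#' @param alpha Significance level of the normality gate; default 0.05.
#' @param alternative Direction for sync relative to async; default
#'   `"less"`.
#' @return A list of class `paired_test_report`: `branch` (`"t"` or
#'   `"wilcoxon"` or `"degenerate"`), `normality_p`, `statistic`, `p.value`,
#'   `n`, `alternative`.
#' @export
paired_condition_test <- function(sync, async, alpha = 0.05,
                                  alternative = c("less", "greater",
                                                  "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(sync) != length(async)) {
    stop_invalid("sync and async must be paired vectors of equal length")
  }
  if (length(sync) < 5) stop_invalid("need at least 5 pairs")
  d <- sync - async
  if (all(d == 0)) {
    return(structure(
      list(
        branch = "degenerate", normality_p = NA_real_,
        statistic = NA_real_, p.value = NA_real_, n = length(d),
        alternative = alternative
      ),
      class = "paired_test_report"
    ))
  }
  norm_p <- if (sd(d) == 0) 0 else nortest::lillie.test(d)$p.value
  if (norm_p > alpha) {
    tt <- t.test(sync, async, paired = TRUE, alternative = alternative)
    branch <- "t"
    statistic <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    wt <- wilcoxon_signed_rank(sync, async, alternative = alternative)
    branch <- "wilcoxon"
    statistic <- wt$statistic
    p <- wt$p.value
  }
  structure(
    list(
      branch = branch, normality_p = norm_p, statistic = statistic,
      p.value = p, n = length(d), alternative = alternative
    ),
    class = "paired_test_report"
  )
}

#' @export
print.paired_test_report <- function(x, ...) {
  if (x$branch == "degenerate") {
    cat("<paired_test_report: all differences zero - no test performed>\n")
  } else {
    cat(sprintf(
      "<paired_test_report: %s branch (normality p = %.3f), statistic = %.3f, p = %.4g>\n",
      x$branch, x$normality_p, x$statistic, x$p.value
    ))
  }
  invisible(x)
}

#' Ownership contrast between conditions
#'
#' Compares per-participant ownership scores between the synchronous and
#' asynchronous conditions with the Wilcoxon signed-rank test (ownership
#' ratings are ordinal and typically floor-skewed, so no normality gate is
#' applied). Scores may be supplied as per-participant composites or as
#' item matrices, which are first reduced to item means per participant.
#'
#' @param sync,async Per-participant ownership scores per condition: numeric
#'   vectors of composites, or matrices (participants x 7 items, 0-6).
#' @param alternative Test direction; default `"two.sided"`.
#' @return A list of class `ownership_report` wrapping the
#'   [wilcoxon_signed_rank()] result plus per-condition medians and IQRs.
#' @export
ownership_contrast <- function(sync, async,
                               alternative = c("two.sided", "greater",
                                               "less")) {
  alternative <- match.arg(alternative)
  as_composite <- function(x) {
    if (is.matrix(x) || is.data.frame(x)) {
      aggregate_ownership(x)$participant_composites
    } else {
      as.numeric(x)
    }
  }
  s <- as_composite(sync)
  a <- as_composite(async)
  if (length(s) != length(a)) {
    stop_invalid("sync and async must cover the same participants")
  }
  test <- wilcoxon_signed_rank(s, a, alternative = alternative)
  structure(
    list(
      test = test,
      median_sync = median(s), iqr_sync = unname(quantile(s, c(0.25, 0.75))),
      median_async = median(a), iqr_async = unname(quantile(a, c(0.25, 0.75)))
    ),
    class = "ownership_report"
  )
}

#' @export
print.ownership_report <- function(x, ...) {
  cat(sprintf(
    "<ownership_report: median sync %.2f (IQR %.2f-%.2f), async %.2f (IQR %.2f-%.2f)>\n",
    x$median_sync, x$iqr_sync[1], x$iqr_sync[2],
    x$median_async, x$iqr_async[1], x$iqr_async[2]
  ))
  print(x$test)
  invisible(x)
}
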