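test_that("SUS composite is the unweighted item mean", {
  # published item means for the three usability items
  s <- aggregate_sus(c(4.54, 4.36, 4.36))
  expect_equal(s$composite, 4.42, tolerance = 0.005)
  expect_equal(aggregate_sus(matrix(3, 10, 3))$composite, 3.0)
  expect_equal(aggregate_sus(matrix(5, 10, 3))$composite, 5.0)
  expect_error(aggregate_sus(c(4.5, 4.5)), "3 item")
  expect_error(aggregate_sus(matrix(6, 10, 3)), "\\[1, 5\\]")
})

test_that("SSQ composite is the unweighted item mean on the 1-4 scale", {
  expect_equal(aggregate_ssq(rep(1, 7))$composite, 1.0)
  expect_equal(aggregate_ssq(c(1, 1, 2, 1, 1, 1, 1))$composite, 8 / 7)
  expect_equal(aggregate_ssq(rep(4, 7))$composite, 4.0)
  expect_error(aggregate_ssq(matrix(5, 3, 7)), "\\[1, 4\\]")
})

test_that("participant composites and group composite agree for complete data", {
  set.seed(3)
  m <- matrix(sample(1:5, 60, replace = TRUE), ncol = 3)
  s <- aggregate_sus(m)
  expect_equal(mean(s$participant_composites), s$composite)
  expect_equal(s$item_means, colMeans(m), ignore_attr = TRUE)
})

# Build a minimal pain table for given block deltas; values are arranged so
# that bilateral means produce the requested pre/post difference.
pain_rows <- function(participant, condition, blocks, instrument, site,
                      pre, post) {
  do.call(rbind, lapply(seq_along(blocks), function(i) {
    expand.grid(
      participant = participant, block = blocks[i], condition = condition,
      phase = c("pre", "post"), instrument = instrument, site = site,
      side = c("left", "right"), stringsAsFactors = FALSE
    ) |> transform(value = ifelse(phase == "pre", pre[i], post[i]))
  }))
}

test_that("zero pre/post change gives zero deltas", {
  tab <- rbind(
    pain_rows(1, "sync", c(1, 2), "algopeg", "finger", c(3, 3), c(3, 3)),
    pain_rows(1, "async", c(3, 4), "algopeg", "finger", c(3, 3), c(3, 3))
  )
  d <- compute_pain_deltas(tab)
  expect_equal(d$delta, c(0, 0))
})

test_that("algopeg condition delta is the mean of post-minus-pre block deltas", {
  tab <- rbind(
    pain_rows(1, "sync", c(1, 3), "algopeg", "finger",
              pre = c(3.0, 3.0), post = c(2.9, 3.064)),
    pain_rows(1, "async", c(2, 4), "algopeg", "finger",
              pre = c(3, 3), post = c(3, 3))
  )
  d <- compute_pain_deltas(tab)
  sync <- d$delta[d$condition == "sync"]
  expect_equal(sync, mean(c(-0.1, 0.064)))
  expect_equal(sync, -0.018)
})

test_that("somedic delta is pre-minus-post: a dropped threshold is positive", {
  tab <- rbind(
    pain_rows(1, "sync", c(1, 2), "somedic", "finger",
              pre = c(350, 350), post = c(300, 300)),
    pain_rows(1, "async", c(3, 4), "somedic", "finger",
              pre = c(350, 350), post = c(350, 350))
  )
  d <- compute_pain_deltas(tab)
  expect_equal(d$delta[d$condition == "sync"], 50)
})

test_that("hyperalgesia yields positive deltas under both sign conventions", {
  tab <- rbind(
    pain_rows(1, "sync", c(1, 2), "algopeg", "finger",
              pre = c(3, 3), post = c(4, 4)), # ratings go up
    pain_rows(1, "sync", c(1, 2), "somedic", "finger",
              pre = c(350, 350), post = c(320, 330)), # thresholds drop
    pain_rows(1, "async", c(3, 4), "algopeg", "finger",
              pre = c(3, 3), post = c(3, 3)),
    pain_rows(1, "async", c(3, 4), "somedic", "finger",
              pre = c(350, 350), post = c(350, 350))
  )
  d <- compute_pain_deltas(tab)
  expect_true(all(d$delta[d$condition == "sync"] > 0))
})

test_that("pain delta computation is invariant to row order", {
  tab <- simulate_pain_table(n_participants = 5, seed = 21)
  d1 <- compute_pain_deltas(tab)
  d2 <- compute_pain_deltas(tab[sample(nrow(tab)), ])
  rownames(d1) <- rownames(d2) <- NULL
  expect_equal(d1, d2)
})

test_that("missing sides or phases raise errors naming the offending keys", {
  tab <- pain_rows(1, "sync", c(1, 2), "algopeg", "finger", c(3, 3), c(3, 3))
  no_side <- tab[!(tab$block == 1 & tab$phase == "post" & tab$side == "left"), ]
  expect_error(compute_pain_deltas(no_side), "bilateral")
  no_phase <- tab[!(tab$block == 1 & tab$phase == "post"), ]
  expect_error(compute_pain_deltas(no_phase), "1/sync")
  bad_site <- transform(tab, instrument = "somedic", site = "earlobe")
  expect_error(compute_pain_deltas(bad_site), "finger only")
  bad_val <- transform(tab, value = 12)
  expect_error(compute_pain_deltas(bad_val), "0-10")
})

test_that("simulated pain tables are complete and reproducible", {
  t1 <- simulate_pain_table(n_participants = 4, seed = 5)
  t2 <- simulate_pain_table(n_participants = 4, seed = 5)
  expect_identical(t1, t2)
  d <- compute_pain_deltas(t1)
  expect_equal(nrow(d), 4 * 2 * 3) # participants x conditions x instrument-site
})

test_that("identical conditions give a degenerate paired-test report", {
  x <- c(1, 2, 3, 4, 5, 6)
  r <- paired_condition_test(x, x)
  expect_identical(r$branch, "degenerate")
  expect_true(is.na(r$p.value))
  w <- wilcoxon_signed_rank(x, x)
  expect_true(w$degenerate)
})

test_that("normal differences take the t branch and match a textbook t test", {
  set.seed(10)
  n_reject_pkg <- 0
  n_reject_oracle <- 0
  n_rep <- 400
  for (i in seq_len(n_rep)) {
    async <- rnorm(20)
    sync <- rnorm(20, mean = -0.5) # true shift of 0.5 SD downwards
    r <- paired_condition_test(sync, async, alternative = "less")
    if (r$branch == "t" && r$p.value < 0.05) n_reject_pkg <- n_reject_pkg + 1
    d <- sync - async
    t_stat <- mean(d) / (sd(d) / sqrt(length(d)))
    p_oracle <- stats::pt(t_stat, df = length(d) - 1)
    if (p_oracle < 0.05) n_reject_oracle <- n_reject_oracle + 1
  }
  expect_lt(abs(n_reject_pkg - n_reject_oracle) / n_rep, 0.03)
})

test_that("heavily skewed differences are routed to the Wilcoxon branch", {
  set.seed(11)
  branches <- replicate(100, {
    async <- rep(0, 20)
    sync <- stats::rlnorm(20, 0, 2.5) # strongly right-skewed differences
    paired_condition_test(sync, async)$branch
  })
  expect_gte(mean(branches == "wilcoxon"), 0.95)
})

test_that("paired test contracts are enforced", {
  expect_error(paired_condition_test(1:6, 1:5), "equal length")
  expect_error(paired_condition_test(1:4, 2:5), "at least 5")
})

test_that("signed-rank statistic matches exhaustive enumeration for small n", {
  # worked fixture: Pratt ranks with zeros and ties
  r <- wilcoxon_signed_rank(c(3, 4, 2, 5, 0), c(1, 2, 2, 1, 0),
                            alternative = "greater")
  o <- oracle_signed_rank(c(2, 2, 0, 4, 0))
  expect_equal(r$statistic, o$statistic)
  expect_equal(r$statistic, 12)

  set.seed(12)
  for (rep in 1:10) {
    n <- sample(5:8, 1)
    d <- sample(-4:4, n, replace = TRUE)
    if (all(d == 0)) d[1] <- 1
    r <- wilcoxon_signed_rank(d)
    o <- oracle_signed_rank(d)
    expect_equal(r$statistic, o$statistic)
  }
})

test_that("uniform shift gives the maximal one-sided statistic", {
  async <- c(1, 2, 3, 0, 4)
  sync <- async + 1
  r <- wilcoxon_signed_rank(sync, async, alternative = "greater")
  expect_equal(r$statistic, sum(1:5)) # every rank positive
  expect_lt(r$p.value, 0.05)
})

test_that("signed-rank Z and p agree with the reference implementation when tie-free", {
  set.seed(13)
  x <- rnorm(15)
  y <- rnorm(15, 0.4)
  ours <- wilcoxon_signed_rank(x, y, alternative = "two.sided")
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                            correct = FALSE)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-9)
})

test_that("ownership contrast reports medians and a signed-rank test", {
  set.seed(14)
  q <- simulate_questionnaires(n_participants = 12, seed = 2)
  r <- ownership_contrast(q$ownership_sync, q$ownership_async)
  expect_s3_class(r$test, "wilcoxon_report")
  expect_true(r$median_sync >= 0 && r$median_sync <= 6)
  same <- ownership_contrast(q$ownership_sync, q$ownership_sync)
  expect_true(same$test$degenerate)
})
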