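test_that("epoch-to-minute aggregation sums counts within calendar minutes", {
  t0 <- as.POSIXct("2014-03-31 08:00:00", tz = "UTC")
  ep <- data.frame(subject_id = factor("S1"),
                   timestamp = t0 + seq(0, by = 10, length.out = 18),
                   axis1 = c(rep(50L, 6), rep(0L, 6), 0L, 0L, 0L, 100L, 0L, 0L))
  m <- aggregate_to_minutes(ep, 10)
  expect_equal(m$axis1, c(300L, 0L, 100L))
  ## partial trailing minute dropped
  m2 <- aggregate_to_minutes(ep[1:16, ], 10)
  expect_equal(nrow(m2), 2L)
  ## non-uniform spacing rejected
  ep$timestamp[4] <- ep$timestamp[4] + 1
  expect_error(aggregate_to_minutes(ep, 10), "non-uniform")
})

test_that("the non-wear rule flags runs per its window and tolerance", {
  run <- function(counts, ...) {
    m <- detect_nonwear(minutes_from_counts(counts), ...)
    sum(!m$wear)
  }
  expect_equal(run(c(10, rep(0, 70), 10)), 70)
  expect_equal(run(c(10, rep(0, 59), 10)), 0)
  expect_equal(run(c(10, rep(0, 60), 10)), 60)
  ## 30 zeros + 2-min interruption + 30 zeros: one 62-min run, all flagged
  expect_equal(run(c(10, rep(0, 30), 5, 5, rep(0, 30), 10)), 62)
  ## a 3-min interruption splits it into two sub-60 runs
  expect_equal(run(c(10, rep(0, 30), 5, 5, 5, rep(0, 30), 10)), 0)
  ## interruptions at the edge of the recording are not absorbed
  expect_equal(run(c(5, 5, rep(0, 60))), 60)
  ## the per-window "total" reading caps accumulated interruption minutes
  expect_equal(run(c(rep(0, 30), 5, rep(0, 30), 5, rep(0, 30)),
                   tolerance_mode = "total"), 92)
  expect_equal(run(c(rep(0, 30), 5, 5, rep(0, 30), 5, rep(0, 30)),
                   tolerance_mode = "consecutive"), 93)
})

test_that("non-wear detection matches the exhaustive-window oracle", {
  set.seed(1234)
  for (i in 1:150) {
    counts <- random_count_sequence(max_len = 360)
    m <- detect_nonwear(minutes_from_counts(counts))
    expect_identical(!m$wear, nonwear_oracle(counts),
                     label = paste("sequence", i))
  }
})

test_that("non-wear detection is idempotent and translation-invariant", {
  set.seed(99)
  counts <- random_count_sequence(360)
  m1 <- detect_nonwear(minutes_from_counts(counts))
  m2 <- detect_nonwear(m1)
  expect_identical(m1$wear, m2$wear)
  ## prepending a full day of wear leaves later flags unchanged
  active <- sample(60:800, 1440, replace = TRUE)
  shifted <- detect_nonwear(minutes_from_counts(c(active, counts)))
  expect_identical(shifted$wear[-(1:1440)], m1$wear)
})

test_that("minute classification respects the cut-point boundaries", {
  cuts <- cut_points()
  lab <- classify_minutes(c(0, 99, 100, 2019, 2020, 5998, 5999, 20000), cuts)
  expect_equal(as.character(lab),
               c("SED", "SED", "LPA", "LPA", "MPA", "MPA", "VPA", "VPA"))
  expect_error(classify_minutes(-5, cuts), "negative")
  expect_error(cut_points(sed_upper = 3000, lpa_upper = 2020), "cut-points")
})

test_that("daily summaries conserve minutes, percentages and cpm", {
  ## 600 worn minutes all at 50 cpm, after a wearable day structure:
  counts <- c(rep(50L, 600), rep(0L, 840))
  d <- summarize_days(detect_nonwear(minutes_from_counts(counts)))
  expect_equal(d$wear_minutes, 600)
  expect_equal(d$sed_min, 600)
  expect_equal(d$sed_pct, 100)
  expect_equal(d$cpm, 50)
  expect_true(d$valid_8h && d$valid_10h && !d$valid_12h)

  ## mixed-intensity synthetic day: conservation of minutes and percentages
  ch <- simulate_cohort(sim_config(n_subjects = 3, n_days = 7, seed = 31),
                        resolution = "minute")
  d <- reduce_cohort(ch)
  expect_equal(d$sed_min + d$lpa_min + d$mpa_min + d$vpa_min, d$wear_minutes)
  expect_equal(d$mvpa_min, d$mpa_min + d$vpa_min)
  ok <- d$wear_minutes > 0
  expect_equal(d$sed_pct[ok] + d$lpa_pct[ok] + d$mvpa_pct[ok],
               rep(100, sum(ok)), tolerance = 1e-9)
  expect_true(all(d$valid_8h >= d$valid_10h & d$valid_10h >= d$valid_12h))
})

test_that("day validity filtering and monotonicity behave as specified", {
  days <- data.frame(subject_id = factor("S1"), wear_minutes = c(490, 590, 610, 730))
  expect_equal(nrow(filter_valid_days(days, wear_criteria(10, 1))), 2)
  ## 490 min = 8.2 h, so all four days survive the >= 8 h criterion
  expect_equal(nrow(filter_valid_days(days, wear_criteria(8, 1))), 4)
  expect_equal(nrow(filter_valid_days(days, wear_criteria(9, 1))), 3)
  empty <- filter_valid_days(days[0, , drop = FALSE], wear_criteria(10, 1))
  expect_equal(nrow(empty), 0)
  expect_true(is.na(attr(empty, "retained_fraction")))

  d <- default_cohort_days()
  n_valid <- vapply(seq(6, 14, by = 2), function(h)
    nrow(filter_valid_days(d, wear_criteria(h, 1))), numeric(1))
  expect_true(all(diff(n_valid) <= 0))
})

test_that("weekly means use protocol weeks and the days-per-week criterion", {
  mk_days <- function(wear) data.frame(
    subject_id = factor("S1"), day_index = seq_along(wear),
    week_index = (seq_along(wear) - 1) %/% 7 + 1,
    wear_minutes = wear, cpm = 400, vm_cpm = 700, sed_min = 500,
    lpa_min = 150, mpa_min = 50, vpa_min = 5, mvpa_min = 55,
    sed_pct = 70, lpa_pct = 22, mvpa_pct = 8)
  ## week 1: 4 valid days, week 2: 3 valid days, week 3: all valid
  wear <- c(rep(700, 4), rep(300, 3), rep(700, 3), rep(300, 4), rep(700, 7))
  wk <- summarize_weeks(mk_days(wear), wear_criteria(10, 4))
  expect_equal(wk$week_index, c(1L, 3L))
  expect_equal(wk$n_valid_days, c(4L, 7L))
  expect_equal(attr(wk, "retained_fraction"), 2 / 3)
  ## all 21 days valid: three weeks of 7 days each
  wk <- summarize_weeks(mk_days(rep(700, 21)), wear_criteria(10, 4))
  expect_equal(wk$n_valid_days, rep(7L, 3))
  ## raising the day criterion never adds weeks
  d <- default_cohort_days()
  nw <- vapply(3:6, function(k)
    nrow(summarize_weeks(d, wear_criteria(10, k))), numeric(1))
  expect_true(all(diff(nw) <= 0))
})
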