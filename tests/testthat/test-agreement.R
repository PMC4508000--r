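test_that("week pairing anchors on week 1 and does the arithmetic", {
  wk <- data.frame(subject_id = factor(rep("A", 3)), week_index = 1:3,
                   cpm = c(500, 480, 520))
  p <- pair_weeks(wk, "cpm")
  expect_equal(p$pair, c("1v2", "1v3"))
  expect_equal(p$mean, c(490, 510))
  expect_equal(p$diff, c(20, -20))
  ## subjects without a valid week 1 contribute no pairs
  wk2 <- data.frame(subject_id = factor(rep("B", 2)), week_index = 2:3,
                    cpm = c(400, 410))
  expect_equal(nrow(pair_weeks(wk2, "cpm")), 0)
  ## identical weeks: zero difference
  wk3 <- data.frame(subject_id = factor(rep("C", 2)), week_index = 1:2,
                    cpm = c(444, 444))
  expect_equal(pair_weeks(wk3, "cpm")$diff, 0)
  ## optional week-2-vs-3 pairs
  expect_equal(nrow(pair_weeks(wk, "cpm", include_2v3 = TRUE)), 3)
})

test_that("pair counts track week availability subject by subject", {
  wk <- data.frame(
    subject_id = factor(rep(sprintf("S%02d", 1:87), each = 3)),
    week_index = rep(1:3, 87),
    cpm = rnorm(261, 480, 100))
  p <- pair_weeks(wk, "cpm")
  expect_equal(sum(p$pair == "1v2"), 87)
  expect_equal(sum(p$pair == "1v3"), 87)
  ## dropping one subject's week 3 decrements only the 1v3 count
  p2 <- pair_weeks(wk[-(3), ], "cpm")
  expect_equal(sum(p2$pair == "1v2"), 87)
  expect_equal(sum(p2$pair == "1v3"), 86)
  ## consistency: mean of pair means equals mean of per-pair week averages
  expect_equal(mean(p$mean[p$pair == "1v2"]),
               mean((wk$cpm[wk$week_index == 1] +
                     wk$cpm[wk$week_index == 2]) / 2))
})

test_that("limits of agreement come from the variance-component SEM", {
  wk <- data.frame(subject_id = factor(rep(1:10, each = 2)),
                   week_index = rep(1:2, 10),
                   cpm = rep(seq(300, 700, length.out = 10), each = 2))
  p <- pair_weeks(wk, "cpm")
  ba <- bland_altman(p, sem = 96.1)
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$loa_half_width, 96.1 * sqrt(2) * 1.96)
  expect_equal(round(ba$loa_half_width, 1), 266.4)
  expect_equal(ba$loa_half_width / 96.1, 2.7719, tolerance = 1e-4)
  ## zero differences and zero SEM collapse the bands
  ba0 <- bland_altman(p, sem = 0)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$loa_half_width, 0)
  expect_error(bland_altman(p[1:2, ], sem = 1), "at least 3")
  expect_error(bland_altman(p, sem = -1), "non-negative")
})

test_that("agreement bands cover the nominal share of simulated pairs", {
  d <- default_cohort_days()
  wks <- summarize_weeks(d, wear_criteria(10, 4))
  outs <- c("cpm", "sed_min", "lpa_min")
  crude <- weekly_reliability_table(wks, outcomes = outs)
  inside <- unlist(lapply(outs, function(o) {
    p <- pair_weeks(wks, o)
    ba <- bland_altman(p, crude$sem[crude$outcome == o], outcome = o)
    abs(p$diff - ba$mean_diff) <= ba$loa_half_width
  }))
  expect_gte(mean(inside), 0.93)
})

test_that("heteroscedasticity diagnostics calibrate under both regimes", {
  set.seed(77)
  n <- 59
  lvl <- runif(n, 200, 800)
  ## level-independent differences: slope near zero, usually not flagged
  p0 <- data.frame(subject_id = factor(seq_len(n)), pair = "1v2",
                   mean = lvl, diff = rnorm(n, 0, 50))
  h0 <- heteroscedasticity_check(p0)
  expect_lt(abs(h0$hetero_slope), 0.15)
  ## SD proportional to level: flagged
  p1 <- data.frame(subject_id = factor(seq_len(n)), pair = "1v2",
                   mean = lvl, diff = rnorm(n, 0, 0.25 * lvl))
  h1 <- heteroscedasticity_check(p1)
  expect_true(h1$heteroscedastic)
  expect_gt(h1$hetero_slope, 0)
  ## constant differences: slope exactly zero
  pc <- data.frame(subject_id = factor(seq_len(12)), pair = "1v2",
                   mean = seq_len(12) * 50, diff = rep(30, 12))
  expect_equal(heteroscedasticity_check(pc)$hetero_slope, 0)
  expect_error(heteroscedasticity_check(p0[1:5, ]), "at least 10")
})

test_that("null-calibration: false heteroscedasticity flags stay near 5%", {
  set.seed(123)
  flags <- replicate(200, {
    n <- 59
    p <- data.frame(subject_id = factor(seq_len(n)), pair = "1v2",
                    mean = runif(n, 200, 800), diff = rnorm(n, 0, 50))
    heteroscedasticity_check(p)$heteroscedastic
  })
  expect_lt(mean(flags), 0.10)
})

test_that("plotting a Bland-Altman object draws without error", {
  wk <- data.frame(subject_id = factor(rep(1:8, each = 3)),
                   week_index = rep(1:3, 8),
                   cpm = rnorm(24, 480, 80))
  ba <- bland_altman(pair_weeks(wk, "cpm"), sem = 50, outcome = "cpm")
  f <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(f)
  expect_silent(plot(ba))
  grDevices::dev.off()
  expect_true(file.exists(f))
})
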