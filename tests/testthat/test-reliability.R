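test_that("one-way components reproduce the balanced ANOVA closed form", {
  values <- c(10, 12, 20, 22, 30, 32)
  groups <- rep(c("a", "b", "c"), each = 2)
  vc <- oneway_components(values, groups)
  ## hand-computable: MSB = 200, MSW = 2, n0 = 2
  expect_equal(vc$sigma2_residual, 2)
  expect_equal(vc$sigma2_between, 99)
  expect_equal(vc$n0, 2)
  expect_equal(icc_single(vc), 99 / 101, tolerance = 1e-12)

  ## independent cross-check against stats::aov mean squares
  av <- summary(stats::aov(values ~ factor(groups)))[[1]]
  msb <- av["factor(groups)", "Mean Sq"]
  msw <- av["Residuals", "Mean Sq"]
  expect_equal(vc$sigma2_residual, msw)
  expect_equal(vc$sigma2_between, (msb - msw) / 2)
})

test_that("unbalanced components match the sums-of-squares oracle", {
  set.seed(42)
  for (i in 1:20) {
    k <- sample(3:10, 1)
    ni <- sample(1:6, k, replace = TRUE)
    if (all(ni < 2)) ni[1] <- 2
    g <- rep(seq_len(k), ni)
    y <- rnorm(length(g), mean = g)
    vc <- suppressWarnings(oneway_components(y, g))
    or <- oneway_oracle(y, g)
    expect_equal(vc$sigma2_between, or$sigma2_between, tolerance = 1e-9)
    expect_equal(vc$sigma2_residual, or$sigma2_residual, tolerance = 1e-9)
    expect_equal(vc$n0, or$n0, tolerance = 1e-12)
  }
})

test_that("degenerate inputs are flagged", {
  expect_error(oneway_components(1:3, c("a", "a", "a")), "2 groups")
  expect_error(oneway_components(1:3, c("a", "b", "c")), "singleton")
  vc <- oneway_components(rep(5, 6), rep(1:3, each = 2))
  expect_equal(vc$sigma2_between, 0)
  expect_equal(vc$sigma2_residual, 0)
  expect_error(icc_single(vc), "undefined")
  ## negative MoM estimate truncates to zero with a warning:
  ## identical group means, all variance within groups
  y <- rep(c(1, 5, 5, 1), 4)
  expect_warning(vc <- oneway_components(y, rep(1:4, each = 4)),
                 "truncated")
  expect_equal(vc$sigma2_between, 0)
  expect_true(vc$truncated)
})

test_that("method-of-moments and REML agree on well-behaved simulations", {
  set.seed(11)
  for (i in 1:5) {
    g <- rep(1:40, each = 8)
    y <- rnorm(40, sd = 2)[g] + rnorm(length(g), sd = 1)
    mom <- oneway_components(y, g)
    reml <- oneway_components(y, g, method = "reml")
    expect_equal(mom$sigma2_between, reml$sigma2_between, tolerance = 0.05)
    expect_equal(mom$sigma2_residual, reml$sigma2_residual,
                 tolerance = 0.05)
  }
})

test_that("the Spearman-Brown projection matches its closed form", {
  expect_equal(round(spearman_brown_days(0.29), 1), 9.8)
  expect_equal(round(spearman_brown_days(0.50), 1), 4.0)
  expect_equal(spearman_brown_days(0.80, 0.80), 1)
  ## N(icc, 0.80) = 4 (1 - icc) / icc identically; decreasing; N(x, x) = 1
  iccs <- seq(0.05, 0.95, by = 0.05)
  expect_equal(spearman_brown_days(iccs, 0.80), 4 * (1 - iccs) / iccs)
  expect_true(all(diff(spearman_brown_days(iccs, 0.80)) < 0))
  expect_equal(spearman_brown_days(iccs, iccs[1]),
               iccs[1] / (1 - iccs[1]) * (1 - iccs) / iccs)
  for (x in c(0.2, 0.5, 0.9)) expect_equal(spearman_brown_days(x, x), 1)
  expect_error(spearman_brown_days(0), "undefined")
  expect_error(spearman_brown_days(1), "undefined")
  expect_error(spearman_brown_days(0.5, 1), "icc_t")
})

test_that("SEM, LoA and typical error follow their defining formulas", {
  vc <- list(sigma2_between = 1, sigma2_residual = 4)
  expect_equal(sem_from_components(vc), 2)
  vc$sigma2_residual <- 0
  expect_equal(sem_from_components(vc), 0)
  expect_equal(sem_from_components(list(sigma2_residual = 9235.21)), 96.1,
               tolerance = 1e-4)
  expect_equal(loa_from_sem(0), 0)
  ## LoA / SEM is the constant 2.7719 to 4 decimals
  sems <- c(0.5, 3.4, 27.7, 96.1, 126.7)
  expect_equal(round(loa_from_sem(sems) / sems, 4), rep(2.7719, 5))
  expect_equal(typical_error_pct(0, 10), 0)
  expect_error(typical_error_pct(5, 0), "positive")
})

test_that("wear-adjusted components recover a known generating model", {
  ## y = 0.7 wear + b + e with known variances, 87 x 21
  set.seed(314)
  reps <- replicate(20, {
    g <- rep(1:87, each = 21)
    wear <- 813 + rnorm(length(g), sd = 60)
    y <- 0.7 * wear + rnorm(87, sd = sqrt(1900))[g] +
      rnorm(length(g), sd = sqrt(4600))
    vc <- adjusted_components(y, g, wear)
    c(vc$sigma2_between, vc$sigma2_residual, vc$beta)
  })
  expect_equal(mean(reps[1, ]), 1900, tolerance = 0.10)
  expect_equal(mean(reps[2, ]), 4600, tolerance = 0.10)
  expect_equal(mean(reps[3, ]), 0.7, tolerance = 0.02)
})

test_that("adjustment is inert when the covariate has no effect or range", {
  set.seed(2718)
  g <- rep(1:60, each = 10)
  y <- rnorm(60, sd = 2)[g] + rnorm(length(g))
  wear <- rnorm(length(g), 700, 50) # unrelated to y
  crude <- oneway_components(y, g)
  adj <- adjusted_components(y, g, wear)
  expect_equal(adj$sigma2_between, crude$sigma2_between, tolerance = 0.1)
  expect_equal(adj$sigma2_residual, crude$sigma2_residual, tolerance = 0.05)
  expect_warning(fb <- adjusted_components(y, g, rep(700, length(g))),
                 "zero variance")
  expect_false(fb$covariate_adjusted)
})

test_that("single-day reliability tables respond to the wear criterion", {
  d <- default_cohort_days()
  tab <- reliability_table(d, hours = c(8, 10, 12))
  expect_setequal(unique(tab$outcome),
                  c("cpm", "vm_cpm", "sed_min", "sed_pct", "lpa_min",
                    "lpa_pct", "mvpa_min", "mvpa_pct"))
  expect_true(all(tab$icc_s >= 0 & tab$icc_s <= 1))
  expect_true(all(tab$n_days_needed > 0))
  ## sedentary minutes: stricter criteria shrink the wear-driven noise,
  ## so the single-day ICC trends upward
  sed <- tab[tab$outcome == "sed_min", ]
  sed <- sed[order(sed$min_hours), ]
  expect_true(all(diff(sed$icc_s) > -0.02))
  expect_gt(sed$icc_s[3], sed$icc_s[1])
})

test_that("weekly reliability reproduces degenerate and adjusted patterns", {
  ## constant weekly values per subject: ICC 1, SEM 0, LoA 0
  wk <- data.frame(subject_id = factor(rep(1:10, each = 3)),
                   week_index = rep(1:3, 10),
                   n_valid_days = 7L,
                   wear_minutes = 800,
                   cpm = rep(seq(300, 700, length.out = 10), each = 3))
  tb <- weekly_reliability_table(wk, outcomes = "cpm")
  expect_equal(tb$icc_s, 1)
  expect_equal(tb$sem, 0)
  expect_equal(tb$loa, 0)

  ## week-level between variance 3x the within variance: ICC near 0.75
  set.seed(5)
  iccs <- replicate(10, {
    g <- rep(1:87, each = 3)
    y <- rnorm(87, sd = sqrt(3))[g] + rnorm(length(g))
    icc_single(oneway_components(y, g))
  })
  expect_equal(mean(iccs), 0.75, tolerance = 0.05 / 0.75)

  ## wear-coupled sedentary time: adjustment shrinks the SEM
  d <- default_cohort_days()
  wks <- summarize_weeks(d, wear_criteria(10, 4))
  crude <- weekly_reliability_table(wks, adjust = FALSE,
                                    outcomes = c("sed_min", "sed_pct"))
  adj <- weekly_reliability_table(wks, adjust = TRUE,
                                  outcomes = c("sed_min", "sed_pct"))
  expect_lt(adj$sem[adj$outcome == "sed_min"],
            crude$sem[crude$outcome == "sed_min"])
  ## the percentage form is essentially unaffected by adjustment
  expect_equal(adj$sem[adj$outcome == "sed_pct"],
               crude$sem[crude$outcome == "sed_pct"], tolerance = 0.05)
  ## reference level switch: median-based percentages differ but stay close
  med <- weekly_reliability_table(wks, outcomes = "sed_min",
                                  reference = "median")
  expect_equal(med$reference_level, median(wks$sed_min))
})

test_that("reliability estimates bundle the derived quantities coherently", {
  vc <- oneway_components(c(10, 12, 20, 22, 30, 32), rep(1:3, each = 2))
  est <- reliability_estimate(vc, reference_level = 21)
  expect_equal(est$icc_s, 99 / 101)
  expect_equal(est$sem, sqrt(2))
  expect_equal(est$loa, sqrt(2) * sqrt(2) * 1.96)
  expect_equal(est$sem_pct, 100 * sqrt(2) / 21)
  expect_equal(est$n_days_needed,
               spearman_brown_days(99 / 101, 0.80))
})
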