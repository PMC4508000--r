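# Independent oracles and shared fixtures for the test suite.

# Exhaustive-window non-wear oracle: a minute is non-wear iff it lies in some
# window [i, j] that starts and ends on zero-count minutes, spans >= window
# minutes, and whose interior non-zero stretches never exceed tol consecutive
# minutes. Scans every admissible start; independent of the rle-based
# implementation.
nonwear_oracle <- function(counts, window = 60, tol = 2) {
  n <- length(counts)
  nz <- counts > 0
  flag <- logical(n)
  for (i in seq_len(n)) {
    if (nz[i]) next
    streak <- 0L
    jbest <- NA_integer_
    for (j in i:n) {
      if (nz[j]) {
        streak <- streak + 1L
        if (streak > tol) break
      } else {
        streak <- 0L
        if (j - i + 1L >= window) jbest <- j
      }
    }
    if (!is.na(jbest)) flag[i:jbest] <- TRUE
  }
  flag
}

# Random minute sequences with realistic long zero runs: alternating zero and
# non-zero stretches of geometric lengths.
random_count_sequence <- function(max_len = 360) {
  n <- sample(30:max_len, 1)
  out <- integer(0)
  zero <- runif(1) < 0.5
  while (length(out) < n) {
    len <- if (zero) sample(1:120, 1) else sample(1:6, 1)
    out <- c(out, if (zero) integer(len) else sample(1:500, len, replace = TRUE))
    zero <- !zero
  }
  out[seq_len(n)]
}

# Direct ANOVA sums-of-squares oracle for one-way variance components.
oneway_oracle <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  N <- length(values)
  ni <- tabulate(groups)
  gm <- tapply(values, groups, mean)
  grand <- mean(values)
  msb <- sum(ni * (gm - grand)^2) / (k - 1)
  msw <- sum((values - gm[as.integer(groups)])^2) / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  list(sigma2_between = max((msb - msw) / n0, 0), sigma2_residual = msw,
       msb = msb, msw = msw, n0 = n0)
}

# Build a minute-level data frame for one subject from a plain count vector,
# starting at midnight UTC.
minutes_from_counts <- function(counts, subject = "S1",
                                start = "2014-03-31") {
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  data.frame(
    subject_id = factor(subject),
    timestamp = t0 + (seq_along(counts) - 1) * 60,
    axis1 = as.integer(counts),
    vm = as.numeric(counts)
  )
}

# A recovery-style configuration: wear fixed, weekend and wear-slope effects
# off, so realized sedentary day totals follow the declared generating
# equation exactly. `icc` sets the sedentary variance split at a paper-scale
# total daily variance of 6500 min^2.
recovery_config <- function(icc, seed, n_subjects = 87L, n_days = 21L) {
  sim_config(
    n_subjects = n_subjects, n_days = n_days, seed = seed,
    wear_sd_between = 0, wear_sd_within = 0, nonwear_bout_rate = 0,
    weekend_effect = 0, sed_wear_slope = 0,
    sigma2_between = c(cpm = 21600, sed_min = 6500 * icc,
                       lpa_min = 2830, mvpa_min = 680),
    sigma2_within = c(cpm = 48000, sed_min = 6500 * (1 - icc),
                      lpa_min = 2510, mvpa_min = 1520))
}

# Shared default-scale cohort, built once per test run.
.cache <- new.env(parent = emptyenv())
default_cohort_days <- function() {
  if (is.null(.cache$days)) {
    cohort <- simulate_cohort(sim_config(seed = 20140331L),
                              resolution = "minute")
    .cache$days <- reduce_cohort(cohort)
  }
  .cache$days
}

small_fixtures <- function() {
  if (is.null(.cache$fix)) .cache$fix <- make_fixtures(seed = 42L)
  .cache$fix
}
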