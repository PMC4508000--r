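#' Simulate an epoch-level accelerometer cohort with known ground truth
#'
#' Generates one contiguous count series per subject spanning `n_days` calendar
#' days. Behavior is generated at the minute level: each day receives a nightly
#' non-wear block plus a Poisson number of daytime device-off episodes (all-zero
#' stretches of at least 60 minutes); worn minutes are laid down in geometric
#' bouts of sedentary, light, moderate and vigorous activity whose per-minute
#' counts fall inside the generating state's cpm band; day-level outcome totals
#' follow the random-intercept model described in [sim_config()]. Minute counts
#' are then expanded to epochs by multinomial splitting, so epoch counts are
#' non-negative integers that sum exactly to the minute counts.
#'
#' Sedentary minutes are honored exactly (they carry the wear-time slope);
#' light and moderate-to-vigorous minutes share the remaining worn minutes in
#' proportion to their latent day totals, which closes the identity
#' SED + LPA + MPA + VPA = wear for every day. Counts-per-minute targets are
#' met by solving per-band mean intensities within the band bounds; days whose
#' latent CPM is infeasible given their behavioral composition are clamped to
#' the nearest feasible value.
#'
#' @param config A [sim_config()] object.
#' @param resolution `"epoch"` (default) also materialises the 10-s epoch
#'   series; `"minute"` stops at minute resolution (identical day-level totals,
#'   much lighter, suitable for large simulation studies).
#' @return An object of class `accel_cohort`: a list with elements
#'   * `epochs` — data frame (`subject_id`, `timestamp`, `axis1`, `axis2`,
#'     `axis3`, `vm`), one row per epoch, or `NULL` for minute resolution;
#'   * `minutes` — data frame (`subject_id`, `timestamp`, `axis1`, `axis2`,
#'     `axis3`, `vm`), one row per calendar minute;
#'   * `true_parameters` — ground truth: per-outcome true single-day ICC, the
#'     full configuration, realized subject intercepts.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 3, n_days = 7, seed = 2),
#'                           resolution = "minute")
#' head(cohort$minutes)
#' cohort$true_parameters$true_icc
#' @export
simulate_cohort <- function(config, resolution = c("epoch", "minute")) {
  stopifnot(inherits(config, "sim_config"))
  resolution <- match.arg(resolution)
  set.seed(config$seed)

  nS <- config$n_subjects
  nD <- config$n_days
  n_sd <- nS * nD
  n_min <- n_sd * 1440L
  subj <- sprintf("S%03d", seq_len(nS))

  day_of <- rep(seq_len(nD), times = nS)
  subj_of <- rep(seq_len(nS), each = nD)
  dates <- config$start_date + (day_of - 1L)
  weekend <- as.integer(format(dates, "%u")) >= 6L

  ## ---- wear time: base level, nightly block, daytime off-bouts ----
  u_wear <- stats::rnorm(nS, 0, config$wear_sd_between)
  W0 <- round(pmin(pmax(config$mean_wear_minutes + u_wear[subj_of] +
                          stats::rnorm(n_sd, 0, config$wear_sd_within),
                        240), 1380))
  sleep_len <- 1440L - as.integer(W0)  # >= 60 by the clamp above

  k_bouts <- stats::rpois(n_sd, config$nonwear_bout_rate)
  nonwear_idx <- .place_nonwear(sleep_len, k_bouts, W0,
                                config$nonwear_bout_mean)

  wear <- rep(TRUE, n_min)
  wear[nonwear_idx] <- FALSE
  day_of_min <- rep(seq_len(n_sd), each = 1440L)
  W <- as.integer(tabulate(day_of_min[wear], nbins = n_sd))

  ## ---- latent day-level outcomes ----
  outs <- names(config$outcome_means)
  b <- sapply(outs, function(o)
    stats::rnorm(nS, 0, sqrt(config$sigma2_between[[o]])))
  b <- matrix(b, nrow = nS, dimnames = list(subj, outs))
  lat <- sapply(outs, function(o) {
    gamma <- if (o == "sed_min") config$sed_wear_slope else 0
    config$outcome_means[[o]] + b[subj_of, o] +
      config$weekend_effect[[o]] * weekend +
      gamma * (W - config$mean_wear_minutes) +
      stats::rnorm(n_sd, 0, sqrt(config$sigma2_within[[o]]))
  })
  lat <- matrix(lat, nrow = n_sd, dimnames = list(NULL, outs))

  ## ---- close the behavioral composition against realized wear ----
  sed_m <- pmin(pmax(as.integer(round(lat[, "sed_min"])), 0L), W)
  rem <- W - sed_m
  l_l <- pmax(lat[, "lpa_min"], 1e-6)
  l_m <- pmax(lat[, "mvpa_min"], 0)
  lpa_m <- pmin(pmax(as.integer(round(rem * l_l / (l_l + l_m))), 0L), rem)
  mvpa_m <- rem - lpa_m
  vpa_m <- stats::rbinom(n_sd, mvpa_m, config$vpa_fraction)
  mpa_m <- mvpa_m - vpa_m

  ## ---- per-band mean intensities hitting the day's CPM target ----
  target_cpm <- pmax(lat[, "cpm"], 10)
  x <- .solve_band_means(target_cpm * W, sed_m, lpa_m, mpa_m, vpa_m)

  ## ---- lay out intensity states in geometric bouts, draw counts ----
  lab <- .lay_states(cbind(sed_m, lpa_m, mpa_m, vpa_m),
                     config$mean_bout_minutes)
  wm_idx <- which(wear)
  stopifnot(length(lab) == length(wm_idx))
  day_of_wear <- day_of_min[wm_idx]

  a1 <- integer(length(lab))
  i1 <- lab == 1L
  a1[i1] <- stats::rbinom(sum(i1), 99L, x$sed[day_of_wear[i1]] / 99)
  i2 <- lab == 2L
  a1[i2] <- 100L + stats::rbinom(sum(i2), 1919L,
                                 (x$lpa[day_of_wear[i2]] - 100) / 1919)
  i3 <- lab == 3L
  a1[i3] <- 2020L + stats::rbinom(sum(i3), 3978L,
                                  (x$mpa[day_of_wear[i3]] - 2020) / 3978)
  i4 <- lab == 4L
  a1[i4] <- 5999L + stats::rpois(sum(i4), x$vpa[day_of_wear[i4]] - 5999)

  n_w <- length(a1)
  a2 <- pmax(as.integer(round(a1 * stats::rnorm(n_w, 1.2, 0.06))), 0L)
  a3 <- pmax(as.integer(round(a1 * stats::rnorm(n_w, 0.9, 0.06))), 0L)

  axis1 <- integer(n_min); axis1[wm_idx] <- a1
  axis2 <- integer(n_min); axis2[wm_idx] <- a2
  axis3 <- integer(n_min); axis3[wm_idx] <- a3
  vm <- numeric(n_min)
  vm[wm_idx] <- sqrt(as.numeric(a1)^2 + as.numeric(a2)^2 + as.numeric(a3)^2)

  day_secs <- as.numeric(as.POSIXct(paste(dates, "00:00:00"), tz = "UTC"))
  ts_min <- rep(day_secs, each = 1440L) +
    (rep.int(seq_len(1440L), n_sd) - 1L) * 60
  sid_min <- structure(rep.int(seq_len(nS), rep.int(nD * 1440L, nS)),
                       levels = subj, class = "factor")

  minutes <- data.frame(
    subject_id = sid_min,
    timestamp = as.POSIXct(ts_min, origin = "1970-01-01", tz = "UTC"),
    axis1 = axis1, axis2 = axis2, axis3 = axis3, vm = vm,
    wear_truth = wear  # generator ground truth: FALSE inside inserted
                       # non-wear episodes
  )

  epochs <- NULL
  if (resolution == "epoch") {
    epochs <- .expand_epochs(minutes, wm_idx, a1, a2, a3,
                             config$epoch_seconds)
  }

  true_icc <- vapply(outs, function(o) {
    tot <- config$sigma2_between[[o]] + config$sigma2_within[[o]]
    if (tot == 0) NaN else config$sigma2_between[[o]] / tot
  }, numeric(1))

  structure(list(
    resolution = resolution,
    epochs = epochs,
    minutes = minutes,
    true_parameters = list(
      true_icc = true_icc,
      config = config,
      subject_intercepts = b,
      wear_subject_effects = stats::setNames(u_wear, subj)
    )
  ), class = "accel_cohort")
}

#' @export
print.accel_cohort <- function(x, ...) {
  cfg <- x$true_parameters$config
  cat(sprintf("Synthetic accelerometer cohort: %d subjects x %d days (%s resolution)\n",
              cfg$n_subjects, cfg$n_days, x$resolution))
  cat("True single-day ICC:\n")
  print(round(x$true_parameters$true_icc, 3))
  invisible(x)
}

## ---------------------------------------------------------------------------
## internals

## nightly sleep block at the start of each day plus k daytime off-bouts
## (60 + Exp(mean) minutes), placed without overlap; returns global minute
## indices that are non-wear
.place_nonwear <- function(sleep_len, k_bouts, W0, bout_mean) {
  n_sd <- length(sleep_len)
  offsets <- (seq_len(n_sd) - 1L) * 1440L
  sleep_idx <- sequence(sleep_len) + rep(offsets, times = sleep_len)

  bout_idx <- integer(0)
  with_bouts <- which(k_bouts > 0L)
  if (length(with_bouts)) {
    starts_all <- lens_all <- integer(0)
    for (r in with_bouts) {
      lens <- as.integer(round(60 + stats::rexp(k_bouts[r], 1 / bout_mean)))
      cap <- as.integer(W0[r]) - 120L
      while (length(lens) && sum(lens) > cap) lens <- lens[-length(lens)]
      if (!length(lens)) next
      lo <- sleep_len[r] + 1L
      placed <- matrix(integer(0), ncol = 2)
      for (len in lens) {
        hi <- 1440L - len + 1L
        if (hi < lo) next
        for (try in 1:25) {
          s <- sample.int(hi - lo + 1L, 1L) + lo - 1L
          e <- s + len - 1L
          if (!nrow(placed) ||
              all(e < placed[, 1] | s > placed[, 2])) {
            placed <- rbind(placed, c(s, e))
            starts_all <- c(starts_all, offsets[r] + s)
            lens_all <- c(lens_all, len)
            break
          }
        }
      }
    }
    if (length(starts_all))
      bout_idx <- sequence(lens_all) + rep(starts_all - 1L, times = lens_all)
  }
  c(sleep_idx, bout_idx)
}

## per-band mean intensities (sed, lpa, mpa, vpa) such that the weighted sum
## over state minutes approaches the target count total, within band bounds
.solve_band_means <- function(target_counts, sed, lpa, mpa, vpa) {
  n <- length(target_counts)
  q <- cbind(sed, lpa, mpa, vpa)
  ## SED floor of 10 cpm keeps worn sedentary minutes from being all-zero,
  ## which would let them merge into adjacent device-off runs
  lo <- c(10, 100, 2020, 5999)
  hi <- c(99, 2019, 5998, 30000)
  x <- matrix(rep(c(45, 550, 3300, 6500), each = n), nrow = n)
  t0 <- rowSums(x * q)
  delta <- target_counts - t0

  up <- delta > 0
  if (any(up)) {
    cap <- sweep(-x[up, , drop = FALSE], 2, hi, "+") * q[up, , drop = FALSE]
    tot <- rowSums(cap)
    f <- ifelse(tot > 0, pmin(delta[up] / tot, 1), 0)
    x[up, ] <- x[up, ] + f * sweep(-x[up, , drop = FALSE], 2, hi, "+")
  }
  dn <- delta < 0
  if (any(dn)) {
    cap <- sweep(x[dn, , drop = FALSE], 2, lo, "-") * q[dn, , drop = FALSE]
    tot <- rowSums(cap)
    f <- ifelse(tot > 0, pmin(-delta[dn] / tot, 1), 0)
    x[dn, ] <- x[dn, ] - f * sweep(x[dn, , drop = FALSE], 2, lo, "-")
  }
  x[] <- pmin(pmax(x, rep(lo, each = n)), rep(hi, each = n))
  list(sed = x[, 1], lpa = x[, 2], mpa = x[, 3], vpa = x[, 4])
}

## partition each quota into geometric bouts (bulk, exact totals)
.partition_geometric <- function(q, mean_len) {
  p <- 1 / pmax(mean_len, 1)
  res_g <- integer(0)
  res_l <- integer(0)
  remaining <- as.integer(q)
  repeat {
    idx <- which(remaining > 0L)
    if (!length(idx)) break
    expect <- remaining[idx] / pmax(mean_len[idx], 1)
    need <- as.integer(ceiling(expect) + ceiling(3 * sqrt(expect)) + 3L)
    pool_g <- rep(idx, need)
    lens <- 1L + stats::rgeom(length(pool_g), p[pool_g])
    cum <- stats::ave(lens, pool_g, FUN = cumsum)
    prev <- cum - lens
    keep <- prev < remaining[pool_g]
    kg <- pool_g[keep]
    kl <- pmin(lens[keep], remaining[kg] - prev[keep])
    res_g <- c(res_g, kg)
    res_l <- c(res_l, kl)
    got <- rowsum(as.numeric(kl), kg)
    gi <- as.integer(rownames(got))
    remaining[gi] <- remaining[gi] - as.integer(got[, 1])
  }
  list(group = res_g, len = as.integer(res_l))
}

## interleave state bouts within each day; returns per-wear-minute state codes
## (1 = SED, 2 = LPA, 3 = MPA, 4 = VPA), day-major, totals matching the quotas
.lay_states <- function(quotas, mean_bout_minutes) {
  n <- nrow(quotas)
  means <- mean_bout_minutes[c("sed", "lpa", "mpa", "vpa")]
  day_v <- state_v <- q_v <- m_v <- integer(0)
  for (s in 1:4) {
    nz <- which(quotas[, s] > 0L)
    day_v <- c(day_v, nz)
    state_v <- c(state_v, rep(s, length(nz)))
    q_v <- c(q_v, quotas[nz, s])
    m_v <- c(m_v, rep(means[[s]], length(nz)))
  }
  if (!length(day_v)) return(integer(0))
  part <- .partition_geometric(q_v, m_v)
  b_day <- day_v[part$group]
  b_state <- state_v[part$group]
  ord <- order(b_day, stats::runif(length(b_day)))
  rep.int(b_state[ord], part$len[ord])
}

## split minute counts into k epochs via sequential binomial thinning
.split_epochs <- function(m, k) {
  n <- length(m)
  out <- matrix(0L, n, k)
  rem <- as.integer(m)
  if (k == 1L) {
    out[, 1] <- rem
    return(out)
  }
  for (j in seq_len(k - 1L)) {
    e <- stats::rbinom(n, rem, 1 / (k - j + 1L))
    out[, j] <- e
    rem <- rem - e
  }
  out[, k] <- rem
  out
}

.expand_epochs <- function(minutes, wm_idx, a1, a2, a3, epoch_seconds) {
  k <- 60L %/% epoch_seconds
  n_min <- nrow(minutes)
  n_ep <- n_min * k
  e1 <- integer(n_ep); e2 <- integer(n_ep); e3 <- integer(n_ep)
  if (length(wm_idx)) {
    pos <- rep((wm_idx - 1L) * k, each = k) + rep.int(seq_len(k), length(wm_idx))
    e1[pos] <- as.vector(t(.split_epochs(a1, k)))
    e2[pos] <- as.vector(t(.split_epochs(a2, k)))
    e3[pos] <- as.vector(t(.split_epochs(a3, k)))
  }
  ts <- rep(as.numeric(minutes$timestamp), each = k) +
    rep.int(seq(0, 60 - epoch_seconds, by = epoch_seconds), n_min)
  data.frame(
    subject_id = rep(minutes$subject_id, each = k),
    timestamp = as.POSIXct(ts, origin = "1970-01-01", tz = "UTC"),
    axis1 = e1, axis2 = e2, axis3 = e3,
    vm = sqrt(as.numeric(e1)^2 + as.numeric(e2)^2 + as.numeric(e3)^2)
  )
}
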