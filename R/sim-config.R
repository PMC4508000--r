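#' Configuration for a synthetic accelerometer cohort
#'
#' Defines the generating model for a cohort of subjects wearing a hip
#' accelerometer for several consecutive days. Day-level totals of each outcome
#' follow a random-intercept model
#' \deqn{Y_{ij} = \mu + b_i + w \cdot \mathrm{weekend}_{ij} +
#'   \gamma (\mathrm{wear}_{ij} - \bar{\mathrm{wear}}) + e_{ij}}
#' with \eqn{b_i \sim N(0, \sigma^2_{between})} and
#' \eqn{e_{ij} \sim N(0, \sigma^2_{within})}. The slope \eqn{\gamma} is
#' `sed_wear_slope` for sedentary minutes and 0 for the other outcomes, so the
#' true single-day intraclass correlation of each outcome is
#' \eqn{\sigma^2_{between} / (\sigma^2_{between} + \sigma^2_{within})}.
#'
#' Default values emulate a free-living adult cohort: 87 subjects wearing the
#' device for 21 days, a mean wear time of 813 min/day, roughly 30% of days
#' failing a 10 h/day wear criterion, weekday activity above weekend activity,
#' and a strong coupling of sedentary minutes to wear time (0.7 min per minute
#' of wear). See the package vignette for how each default was calibrated.
#'
#' @param n_subjects Number of subjects.
#' @param n_days Number of consecutive monitoring days per subject.
#' @param epoch_seconds Epoch length in seconds; must divide 60.
#' @param start_date Calendar date of protocol day 1 (a `Date`). Weekends are
#'   Saturdays and Sundays of this calendar.
#' @param mean_wear_minutes Mean daily wear time, minutes (0, 1440].
#' @param wear_sd_between,wear_sd_within Between-subject and day-level SDs of
#'   the base wear time, minutes.
#' @param outcome_means Named numeric vector of daily outcome means: `cpm`
#'   (counts/min), `sed_min`, `lpa_min`, `mvpa_min` (minutes/day).
#' @param sigma2_between,sigma2_within Named numeric vectors (same names as
#'   `outcome_means`) of between-subject and residual day-level variances.
#' @param weekend_effect Named numeric vector: additive shift applied on
#'   weekend days, per outcome.
#' @param sed_wear_slope Minutes of sedentary time per minute of wear time.
#' @param nonwear_bout_rate Expected number of daytime device-off episodes per
#'   day (Poisson); each episode lasts at least 60 minutes.
#' @param nonwear_bout_mean Mean of the exponential tail of a daytime non-wear
#'   episode beyond its 60-minute minimum, minutes.
#' @param mean_bout_minutes Named vector of mean activity-bout lengths in
#'   minutes for states `sed`, `lpa`, `mpa`, `vpa` (geometric bout scheme).
#' @param vpa_fraction Fraction of moderate-to-vigorous minutes laid down in
#'   the vigorous band.
#' @param seed Integer seed; identical config + seed gives identical cohorts.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()], [true_single_day_icc()]
#' @examples
#' cfg <- sim_config(n_subjects = 5, n_days = 7, seed = 1)
#' true_single_day_icc(cfg, "cpm")
#' @export
sim_config <- function(n_subjects = 87L,
                       n_days = 21L,
                       epoch_seconds = 10L,
                       start_date = as.Date("2014-03-31"),
                       mean_wear_minutes = 813,
                       wear_sd_between = 20,
                       wear_sd_within = 110,
                       outcome_means = c(cpm = 486, sed_min = 564,
                                         lpa_min = 183, mvpa_min = 65.9),
                       sigma2_between = c(cpm = 21600, sed_min = 1900,
                                          lpa_min = 2830, mvpa_min = 680),
                       sigma2_within = c(cpm = 48000, sed_min = 4600,
                                         lpa_min = 2510, mvpa_min = 1520),
                       weekend_effect = c(cpm = -78, sed_min = 18,
                                          lpa_min = -7, mvpa_min = -11),
                       sed_wear_slope = 0.7,
                       nonwear_bout_rate = 0.8,
                       nonwear_bout_mean = 150,
                       mean_bout_minutes = c(sed = 20, lpa = 8, mpa = 6, vpa = 2),
                       vpa_fraction = 0.02,
                       seed = 1L) {
  outcomes <- c("cpm", "sed_min", "lpa_min", "mvpa_min")
  outcome_means <- .complete_named(outcome_means, outcomes, "outcome_means")
  sigma2_between <- .complete_named(sigma2_between, outcomes, "sigma2_between")
  sigma2_within <- .complete_named(sigma2_within, outcomes, "sigma2_within")
  weekend_effect <- .complete_named(weekend_effect, outcomes, "weekend_effect",
                                    default = 0)
  mean_bout_minutes <- .complete_named(mean_bout_minutes,
                                       c("sed", "lpa", "mpa", "vpa"),
                                       "mean_bout_minutes")

  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  if (n_days < 1L) stop("n_days must be >= 1")
  if (60L %% epoch_seconds != 0L) stop("epoch_seconds must divide 60")
  if (!inherits(start_date, "Date")) start_date <- as.Date(start_date)
  if (mean_wear_minutes <= 0 || mean_wear_minutes > 1440)
    stop("mean_wear_minutes must lie in (0, 1440]")
  if (any(c(sigma2_between, sigma2_within) < 0))
    stop("variances must be non-negative")
  if (wear_sd_between < 0 || wear_sd_within < 0)
    stop("wear SDs must be non-negative")
  if (nonwear_bout_rate < 0) stop("nonwear_bout_rate must be non-negative")
  if (vpa_fraction < 0 || vpa_fraction > 1)
    stop("vpa_fraction must lie in [0, 1]")
  behav <- sum(outcome_means[c("sed_min", "lpa_min", "mvpa_min")])
  if (behav > 1440)
    stop("implied daily behavioral minutes (SED + LPA + MVPA = ", behav,
         ") cannot fit in a 24 h day")

  structure(list(
    n_subjects = as.integer(n_subjects),
    n_days = as.integer(n_days),
    epoch_seconds = as.integer(epoch_seconds),
    start_date = start_date,
    mean_wear_minutes = mean_wear_minutes,
    wear_sd_between = wear_sd_between,
    wear_sd_within = wear_sd_within,
    outcome_means = outcome_means,
    sigma2_between = sigma2_between,
    sigma2_within = sigma2_within,
    weekend_effect = weekend_effect,
    sed_wear_slope = sed_wear_slope,
    nonwear_bout_rate = nonwear_bout_rate,
    nonwear_bout_mean = nonwear_bout_mean,
    mean_bout_minutes = mean_bout_minutes,
    vpa_fraction = vpa_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

## recycle a scalar, or check that all required names are present
.complete_named <- function(x, nms, what, default = NULL) {
  if (length(x) == 1L && is.null(names(x)))
    return(stats::setNames(rep(as.numeric(x), length(nms)), nms))
  if (is.null(names(x))) stop(what, " must be a named vector")
  miss <- setdiff(nms, names(x))
  if (length(miss)) {
    if (is.null(default))
      stop(what, " is missing entries for: ", paste(miss, collapse = ", "))
    x[miss] <- default
  }
  as.numeric(x[nms]) -> out
  stats::setNames(out, nms)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic accelerometer cohort configuration\n")
  cat(sprintf("  %d subjects x %d days, %d-s epochs, start %s\n",
              x$n_subjects, x$n_days, x$epoch_seconds,
              format(x$start_date)))
  cat(sprintf("  wear: mean %.0f min/day (SD between %.0f, within %.0f); %.2f off-bouts/day\n",
              x$mean_wear_minutes, x$wear_sd_between, x$wear_sd_within,
              x$nonwear_bout_rate))
  icc <- vapply(names(x$outcome_means), function(o) true_single_day_icc(x, o),
                numeric(1))
  tab <- data.frame(mean = x$outcome_means,
                    sigma2_between = x$sigma2_between,
                    sigma2_within = x$sigma2_within,
                    weekend_effect = x$weekend_effect,
                    true_icc = round(icc, 3))
  print(tab)
  cat(sprintf("  sed_wear_slope %.2f, seed %d\n", x$sed_wear_slope, x$seed))
  invisible(x)
}

#' True single-day intraclass correlation implied by a configuration
#'
#' Returns the generator's ground-truth single-day reliability for one outcome,
#' the between-subject share of the total day-level variance:
#' \eqn{\sigma^2_{between} / (\sigma^2_{between} + \sigma^2_{within})}.
#'
#' @param config A [sim_config()] object.
#' @param outcome One of `"cpm"`, `"sed_min"`, `"lpa_min"`, `"mvpa_min"`.
#' @return A number in \[0, 1\]. If both variances are zero the ICC is
#'   undefined and `NaN` is returned with a warning.
#' @examples
#' cfg <- sim_config(sigma2_between = 0.31, sigma2_within = 0.69)
#' true_single_day_icc(cfg, "cpm") # 0.31
#' @export
true_single_day_icc <- function(config, outcome) {
  stopifnot(inherits(config, "sim_config"))
  if (!outcome %in% names(config$sigma2_between))
    stop("unknown outcome: ", outcome)
  b <- config$sigma2_between[[outcome]]
  w <- config$sigma2_within[[outcome]]
  tot <- b + w
  if (tot == 0) {
    warning("zero total variance for ", outcome, "; ICC undefined")
    return(NaN)
  }
  b / tot
}
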