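## Random-intercept association models: wear time, weekday/weekend, and the
## week-weekend share of total variance.

.fit_stats <- function(fit, term, n_obs, n_subjects, outcome, covariate) {
  co <- summary(fit)$coefficients
  beta <- co[term, "Estimate"]
  se <- co[term, "Std. Error"]
  ## between-within denominator degrees of freedom:
  ## N - (number of subjects) - (number of fixed slopes)
  p <- nrow(co) - 1L
  ddf <- max(n_obs - n_subjects - p, 1L)
  f <- (beta / se)^2
  structure(list(
    beta = beta,
    se = se,
    ci_low = beta - stats::qnorm(0.975) * se,
    ci_high = beta + stats::qnorm(0.975) * se,
    f_stat = f,
    p_value = stats::pf(f, 1, ddf, lower.tail = FALSE),
    ddf = ddf,
    n_obs = n_obs,
    n_subjects = n_subjects,
    outcome_name = outcome,
    covariate_name = covariate
  ), class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf("%s ~ %s (random intercept per subject)\n",
              x$outcome_name, x$covariate_name))
  cat(sprintf("  beta = %.4g (95%% CI %.4g to %.4g), F = %.2f, p = %.3g\n",
              x$beta, x$ci_low, x$ci_high, x$f_stat, x$p_value))
  cat(sprintf("  %d observations, %d subjects\n", x$n_obs, x$n_subjects))
  invisible(x)
}

.check_outcome <- function(days, outcome) {
  if (!outcome %in% names(days))
    stop("unknown outcome column: ", outcome)
}

#' Association between daily wear time and an outcome
#'
#' Fits the linear mixed model `outcome ~ wear_minutes + (1 | subject)` by
#' restricted maximum likelihood on valid days and reports the wear-time
#' slope with its Wald 95% confidence interval and an F test (between-within
#' denominator degrees of freedom).
#'
#' @param days An `accel_days` data frame.
#' @param outcome Outcome column, e.g. `"sed_min"` or `"cpm"`.
#' @param min_hours Daily wear criterion (hours) applied before fitting.
#' @return A `mixed_model_fit` object: `beta`, `ci_low`, `ci_high`, `f_stat`,
#'   `p_value`, `n_obs`, `n_subjects`.
#' @export
wear_association <- function(days, outcome, min_hours = 10) {
  .check_outcome(days, outcome)
  d <- filter_valid_days(days, wear_criteria(min_hours, 1))
  d <- d[!is.na(d[[outcome]]), ]
  if (stats::var(d$wear_minutes) == 0) stop("wear time has no variation")
  dat <- data.frame(y = d[[outcome]], wear = d$wear_minutes,
                    subject = droplevels(factor(d$subject_id)))
  fit <- lme4::lmer(y ~ wear + (1 | subject), data = dat, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  .fit_stats(fit, "wear", nrow(dat), nlevels(dat$subject), outcome,
             "wear_minutes")
}

#' Weekday/weekend contrast, adjusted for wear time
#'
#' Fits `outcome ~ wear_minutes + weekday + (1 | subject)` on valid days,
#' where `weekday = 1` for Monday-Friday, and returns the weekday dummy's
#' fit (a positive coefficient means higher values on weekdays).
#'
#' @inheritParams wear_association
#' @return A `mixed_model_fit` for the weekday dummy.
#' @export
weekday_weekend_effect <- function(days, outcome, min_hours = 10) {
  .check_outcome(days, outcome)
  d <- filter_valid_days(days, wear_criteria(min_hours, 1))
  d <- d[!is.na(d[[outcome]]), ]
  if (length(unique(d$weekend)) < 2)
    stop("both weekday and weekend days are required")
  dat <- data.frame(y = d[[outcome]], wear = d$wear_minutes,
                    weekday = as.numeric(!d$weekend),
                    subject = droplevels(factor(d$subject_id)))
  fit <- lme4::lmer(y ~ wear + weekday + (1 | subject), data = dat,
                    REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  .fit_stats(fit, "weekday", nrow(dat), nlevels(dat$subject), outcome,
             "weekday (vs weekend)")
}

#' Share of total variance explained by the week/weekend distinction
#'
#' Three-component decomposition of a wear-adjusted outcome into subject,
#' day-type (week vs weekend) and residual variance. The day-type component
#' is the variance of the fitted day-type effect across the observed mix of
#' weekdays and weekend days, \eqn{p (1 - p) \delta^2} where \eqn{\delta} is
#' the adjusted weekday-weekend contrast and \eqn{p} the weekday proportion;
#' the returned value is its share of the total
#' \eqn{\sigma^2_{subject} + \sigma^2_{daytype} + \sigma^2_{residual}}.
#'
#' @inheritParams wear_association
#' @return A list: `ratio` (the day-type share, in \[0, 1\]),
#'   `sigma2_between`, `sigma2_daytype`, `sigma2_residual`, `delta`
#'   (the weekday contrast), `p_weekday`.
#' @export
weekweekend_variance_ratio <- function(days, outcome, min_hours = 10) {
  .check_outcome(days, outcome)
  d <- filter_valid_days(days, wear_criteria(min_hours, 1))
  d <- d[!is.na(d[[outcome]]), ]
  if (length(unique(d$weekend)) < 2)
    stop("both weekday and weekend days are required")
  dat <- data.frame(y = d[[outcome]], wear = d$wear_minutes,
                    weekday = as.numeric(!d$weekend),
                    subject = droplevels(factor(d$subject_id)))
  fit <- lme4::lmer(y ~ wear + weekday + (1 | subject), data = dat,
                    REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2b <- vc$vcov[vc$grp == "subject"]
  s2w <- vc$vcov[vc$grp == "Residual"]
  delta <- unname(lme4::fixef(fit)["weekday"])
  p <- mean(dat$weekday)
  s2d <- p * (1 - p) * delta^2
  list(ratio = s2d / (s2b + s2d + s2w),
       sigma2_between = s2b, sigma2_daytype = s2d, sigma2_residual = s2w,
       delta = delta, p_weekday = p)
}

#' Wear-time association table across outcomes
#'
#' Runs [wear_association()] for each outcome and collects the slopes,
#' confidence intervals and F tests in one table.
#'
#' @param days An `accel_days` data frame.
#' @param outcomes Outcome columns.
#' @param min_hours Daily wear criterion (hours).
#' @return Data frame: `outcome`, `beta`, `ci_low`, `ci_high`, `f`, `p`,
#'   `n_obs`, `n_subjects`.
#' @export
association_table <- function(days, outcomes = .std_outcomes,
                              min_hours = 10) {
  res <- lapply(outcomes, function(o) {
    f <- wear_association(days, o, min_hours)
    data.frame(outcome = o, beta = f$beta, ci_low = f$ci_low,
               ci_high = f$ci_high, f = f$f_stat, p = f$p_value,
               n_obs = f$n_obs, n_subjects = f$n_subjects)
  })
  do.call(rbind, res)
}
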