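#' One-way random-effect variance components
#'
#' Method-of-moments estimates from the one-way ANOVA decomposition with the
#' unbalanced-data effective group size
#' \eqn{n_0 = (N - \sum n_i^2 / N) / (k - 1)}:
#' the residual variance is the within-group mean square and the
#' between-subject variance is \eqn{(MS_B - MS_W) / n_0}, truncated at zero
#' (a truncation is flagged and warned about). With equal group sizes this
#' reproduces the textbook balanced closed forms exactly. A restricted
#' maximum likelihood alternative (`method = "reml"`) is available.
#'
#' @param values Numeric vector of observations (e.g. one outcome across all
#'   subject-days or subject-weeks).
#' @param groups Grouping labels (subjects), same length as `values`.
#' @param method `"mom"` (ANOVA method of moments, default) or `"reml"`.
#' @return An object of class `varcomp`: `sigma2_between`, `sigma2_residual`,
#'   `n_groups`, `n_obs`, `n0`, `covariate_adjusted = FALSE`, `truncated`.
#' @examples
#' vc <- oneway_components(c(10, 12, 20, 22, 30, 32), rep(1:3, each = 2))
#' vc$sigma2_between # 99
#' icc_single(vc)    # 0.9802
#' @export
oneway_components <- function(values, groups, method = c("mom", "reml")) {
  method <- match.arg(method)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  groups <- droplevels(groups)
  k <- nlevels(groups)
  N <- length(values)
  if (k < 2) stop("need at least 2 groups")
  ni <- tabulate(groups)
  if (all(ni < 2))
    stop("all groups are singletons; residual variance is undefined")

  if (method == "reml") {
    fit <- lme4::lmer(values ~ 1 + (1 | groups),
                      REML = TRUE,
                      control = lme4::lmerControl(calc.derivs = FALSE))
    vc <- as.data.frame(lme4::VarCorr(fit))
    s2b <- vc$vcov[vc$grp == "groups"]
    s2w <- vc$vcov[vc$grp == "Residual"]
    trunc <- FALSE
  } else {
    gm <- tapply(values, groups, mean)
    grand <- mean(values)
    msb <- sum(ni * (gm - grand)^2) / (k - 1)
    msw <- sum((values - gm[groups])^2) / (N - k)
    n0 <- (N - sum(ni^2) / N) / (k - 1)
    s2b <- (msb - msw) / n0
    trunc <- s2b < 0
    if (trunc) {
      warning("negative between-group variance estimate truncated to 0")
      s2b <- 0
    }
    s2w <- msw
  }
  structure(list(
    sigma2_between = s2b,
    sigma2_residual = s2w,
    sigma2_extra = NULL,
    n_groups = k,
    n_obs = N,
    n0 = (N - sum(ni^2) / N) / (k - 1),
    covariate_adjusted = FALSE,
    truncated = trunc,
    method = method
  ), class = "varcomp")
}

#' Covariate-adjusted variance components (two-way mixed model)
#'
#' Variance components of the mixed model
#' \eqn{y = \mu + \beta x + b_{group} + e}, with the covariate (typically wear
#' time) as a fixed effect, estimated by restricted maximum likelihood via
#' [lme4::lmer()]. When the covariate has no variation the function falls back
#' to [oneway_components()] with a warning.
#'
#' @param values,groups As in [oneway_components()].
#' @param covariate Numeric covariate observed for every observation.
#' @return A `varcomp` object with `covariate_adjusted = TRUE` and the fitted
#'   slope in `$beta`.
#' @export
adjusted_components <- function(values, groups, covariate) {
  ok <- !is.na(values) & !is.na(groups) & !is.na(covariate)
  values <- values[ok]
  groups <- droplevels(factor(groups[ok]))
  covariate <- covariate[ok]
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (stats::var(covariate) == 0) {
    warning("covariate has zero variance; returning unadjusted components")
    return(oneway_components(values, groups))
  }
  fit <- lme4::lmer(values ~ covariate + (1 | groups), REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  ni <- tabulate(groups)
  N <- length(values)
  k <- nlevels(groups)
  structure(list(
    sigma2_between = vc$vcov[vc$grp == "groups"],
    sigma2_residual = vc$vcov[vc$grp == "Residual"],
    sigma2_extra = NULL,
    n_groups = k,
    n_obs = N,
    n0 = (N - sum(ni^2) / N) / (k - 1),
    covariate_adjusted = TRUE,
    truncated = FALSE,
    beta = unname(lme4::fixef(fit)["covariate"]),
    method = "reml"
  ), class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf(
    "Variance components (%s%s): between = %.4g, residual = %.4g\n",
    x$method, if (x$covariate_adjusted) ", covariate-adjusted" else "",
    x$sigma2_between, x$sigma2_residual))
  cat(sprintf("  %d groups, %d observations, n0 = %.3f\n",
              x$n_groups, x$n_obs, x$n0))
  if (!is.null(x$beta)) cat(sprintf("  covariate slope = %.4g\n", x$beta))
  invisible(x)
}

#' Intraclass correlation from variance components
#'
#' The between-subject share of the total variance,
#' \eqn{\sigma^2_{between} / (\sigma^2_{between} + \sigma^2_{extra} +
#' \sigma^2_{residual})}.
#'
#' @param vc A `varcomp` object (or a list with `sigma2_between`,
#'   `sigma2_residual` and optionally `sigma2_extra`).
#' @return A number in \[0, 1\].
#' @export
icc_single <- function(vc) {
  extra <- if (is.null(vc$sigma2_extra)) 0 else vc$sigma2_extra
  tot <- vc$sigma2_between + extra + vc$sigma2_residual
  if (tot <= 0) stop("zero total variance; ICC undefined")
  vc$sigma2_between / tot
}

#' Spearman-Brown prophecy: days of monitoring needed
#'
#' Number of repeated measurement days needed to raise the reliability of a
#' single day, `icc_s`, to a target reliability `icc_t`:
#' \deqn{N = \frac{ICC_t}{1 - ICC_t} \cdot \frac{1 - ICC_s}{ICC_s}}
#' Returned unrounded; reporting layers round to one decimal.
#'
#' @param icc_s Single-day reliability, strictly inside (0, 1).
#' @param icc_t Target reliability, strictly inside (0, 1); default 0.80.
#' @return Days needed (numeric, vectorised over `icc_s`).
#' @examples
#' round(spearman_brown_days(0.29), 1) # 9.8
#' spearman_brown_days(0.8, 0.8)       # 1
#' @export
spearman_brown_days <- function(icc_s, icc_t = 0.80) {
  if (any(icc_s <= 0 | icc_s >= 1))
    stop("icc_s must lie strictly inside (0, 1); the projection is undefined at 0 and 1")
  if (icc_t <= 0 || icc_t >= 1) stop("icc_t must lie strictly inside (0, 1)")
  icc_t / (1 - icc_t) * (1 - icc_s) / icc_s
}

#' Standard error of measurement
#'
#' Square root of the residual (within-subject) variance, in outcome units.
#'
#' @param vc A `varcomp` object.
#' @return SEM (numeric).
#' @export
sem_from_components <- function(vc) {
  if (vc$sigma2_residual < 0) stop("negative residual variance")
  sqrt(vc$sigma2_residual)
}

#' 95% limits of agreement half-width from an SEM
#'
#' \eqn{LoA = SEM \cdot \sqrt{2} \cdot 1.96}: the expected bounds of a
#' test-retest difference.
#'
#' @param sem Non-negative SEM.
#' @return LoA half-width (numeric, vectorised).
#' @examples
#' round(loa_from_sem(96.1), 1) # 266.4
#' @export
loa_from_sem <- function(sem) {
  if (any(sem < 0)) stop("sem must be non-negative")
  sem * sqrt(2) * 1.96
}

#' Percentage typical error
#'
#' The SEM expressed as a percentage of a reference level of the outcome
#' (by default the sample mean; see Details of [weekly_reliability_table()]).
#'
#' @param sem Non-negative SEM.
#' @param reference_level Positive reference level in outcome units.
#' @return `100 * sem / reference_level`.
#' @examples
#' round(typical_error_pct(96.1, 486), 1) # 19.8
#' @export
typical_error_pct <- function(sem, reference_level) {
  if (any(reference_level <= 0)) stop("reference_level must be positive")
  100 * sem / reference_level
}

.std_outcomes <- c("cpm", "vm_cpm", "sed_min", "sed_pct", "lpa_min",
                   "lpa_pct", "mvpa_min", "mvpa_pct")

#' Single-day reliability across wear-time criteria
#'
#' For each outcome and daily hour criterion: filters valid days, estimates
#' one-way variance components across subject-days, and reports the single-day
#' ICC and the Spearman-Brown days needed to reach `icc_t`.
#'
#' @param days An `accel_days` data frame.
#' @param hours Numeric vector of daily wear criteria in hours.
#' @param outcomes Outcome columns to analyse.
#' @param icc_t Target reliability for the days-needed projection.
#' @return Data frame of class `reliability_table`: `outcome`, `min_hours`,
#'   `n_days_used`, `n_subjects`, `icc_s`, `n_days_needed`. Cells with fewer
#'   than 2 usable subjects are `NA`.
#' @export
reliability_table <- function(days, hours = c(8, 10, 12),
                              outcomes = .std_outcomes, icc_t = 0.80) {
  rows <- expand.grid(outcome = outcomes, min_hours = hours,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(rows)), function(r) {
    o <- rows$outcome[r]
    valid <- filter_valid_days(days, wear_criteria(rows$min_hours[r], 1))
    vals <- valid[[o]]
    grp <- valid$subject_id
    keep <- !is.na(vals)
    ns <- length(unique(grp[keep]))
    if (ns < 2 || sum(keep) < 3)
      return(data.frame(n_days_used = sum(keep), n_subjects = ns,
                        icc_s = NA_real_, n_days_needed = NA_real_))
    vc <- oneway_components(vals[keep], grp[keep])
    icc <- icc_single(vc)
    ndn <- if (icc > 0 && icc < 1) spearman_brown_days(icc, icc_t) else NA_real_
    data.frame(n_days_used = sum(keep), n_subjects = ns, icc_s = icc,
               n_days_needed = ndn)
  })
  out <- cbind(rows, do.call(rbind, res))
  attr(out, "icc_t") <- icc_t
  class(out) <- c("reliability_table", "data.frame")
  out
}

#' @export
print.reliability_table <- function(x, digits_icc = 2, digits_n = 1, ...) {
  y <- as.data.frame(x)
  y$icc_s <- round(y$icc_s, digits_icc)
  y$n_days_needed <- round(y$n_days_needed, digits_n)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Week-by-week reliability, with optional wear-time adjustment
#'
#' Per outcome, estimates variance components across the accumulated weekly
#' means and reports the week-level ICC, the standard error of measurement,
#' its percentage form, and the 95% limits of agreement. With
#' `adjust = TRUE` the weekly mean wear time enters as a fixed effect
#' (two-way mixed model via REML); otherwise the crude one-way random-effect
#' decomposition is used.
#'
#' The reference level for the percentage typical error defaults to the
#' sample mean of the weekly values; set `reference = "median"` for the
#' median.
#'
#' @param weeks An `accel_weeks` data frame from [summarize_weeks()].
#' @param adjust Adjust for weekly mean wear time?
#' @param outcomes Outcome columns to analyse.
#' @param icc_t Target reliability (kept as an attribute for reporting).
#' @param reference `"mean"` or `"median"` reference for the SEM percentage.
#' @return Data frame of class `reliability_table` with columns `outcome`,
#'   `adjusted`, `n_weeks`, `n_subjects`, `icc_s`, `sem`, `sem_pct`, `loa`,
#'   `reference_level`.
#' @export
weekly_reliability_table <- function(weeks, adjust = FALSE,
                                     outcomes = .std_outcomes,
                                     icc_t = 0.80,
                                     reference = c("mean", "median")) {
  reference <- match.arg(reference)
  res <- lapply(outcomes, function(o) {
    vals <- weeks[[o]]
    keep <- !is.na(vals)
    vals <- vals[keep]
    grp <- weeks$subject_id[keep]
    wearw <- weeks$wear_minutes[keep]
    vc <- if (adjust) adjusted_components(vals, grp, wearw)
          else oneway_components(vals, grp)
    sem <- sem_from_components(vc)
    ref <- if (reference == "mean") mean(vals) else stats::median(vals)
    data.frame(outcome = o, adjusted = adjust,
               n_weeks = vc$n_obs, n_subjects = vc$n_groups,
               icc_s = icc_single(vc), sem = sem,
               sem_pct = typical_error_pct(sem, ref),
               loa = loa_from_sem(sem),
               reference_level = ref)
  })
  out <- do.call(rbind, res)
  attr(out, "icc_t") <- icc_t
  class(out) <- c("weekly_reliability_table", "reliability_table",
                  "data.frame")
  out
}

#' @export
print.weekly_reliability_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$icc_s <- round(y$icc_s, 2)
  for (cn in c("sem", "sem_pct", "loa", "reference_level"))
    y[[cn]] <- round(y[[cn]], 1)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Reliability estimate for a single outcome
#'
#' Bundles the quantities describing one outcome's reliability: the ICC, the
#' SEM (absolute and percentage), the limits of agreement and the
#' Spearman-Brown days-needed projection.
#'
#' @param vc A `varcomp` object.
#' @param reference_level Positive reference level for the SEM percentage.
#' @param icc_t Target reliability.
#' @return Object of class `reliability_estimate`.
#' @export
reliability_estimate <- function(vc, reference_level, icc_t = 0.80) {
  icc <- icc_single(vc)
  sem <- sem_from_components(vc)
  structure(list(
    icc_s = icc,
    sem = sem,
    sem_pct = typical_error_pct(sem, reference_level),
    loa = loa_from_sem(sem),
    n_days_needed = if (icc > 0 && icc < 1)
      spearman_brown_days(icc, icc_t) else NA_real_,
    icc_t = icc_t,
    reference_level = reference_level,
    covariate_adjusted = isTRUE(vc$covariate_adjusted)
  ), class = "reliability_estimate")
}

#' @export
print.reliability_estimate <- function(x, ...) {
  cat(sprintf("ICC = %.2f, SEM = %.1f (%.1f%%), LoA = %.1f%s\n",
              x$icc_s, x$sem, x$sem_pct, x$loa,
              if (x$covariate_adjusted) " [wear-adjusted]" else ""))
  cat(sprintf("Days needed for ICC = %.2f: %.1f\n", x$icc_t,
              x$n_days_needed))
  invisible(x)
}
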