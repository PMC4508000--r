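## Week-by-week Bland-Altman agreement: paired weekly differences anchored on
## week 1, limits of agreement from the variance-component SEM, and a
## heteroscedasticity diagnostic.

#' Pair weekly means for Bland-Altman analysis
#'
#' For each subject, emits a (mean, difference) pair for weeks 1 and 2 and for
#' weeks 1 and 3 whenever both member weeks are present (valid under the
#' criteria that produced `weeks`). Differences are week 1 minus the later
#' week. Subjects lacking a valid week 1 contribute no pairs; set
#' `include_2v3 = TRUE` to add week 2 vs week 3 pairs.
#'
#' @param weeks An `accel_weeks` data frame.
#' @param outcome Outcome column to pair.
#' @param include_2v3 Also emit week 2 vs week 3 pairs?
#' @return Data frame: `subject_id`, `pair` (`"1v2"`, `"1v3"`, optionally
#'   `"2v3"`), `mean`, `diff`.
#' @export
pair_weeks <- function(weeks, outcome, include_2v3 = FALSE) {
  .check_outcome(weeks, outcome)
  pairs <- list(c(1L, 2L), c(1L, 3L))
  if (include_2v3) pairs <- c(pairs, list(c(2L, 3L)))
  out <- lapply(pairs, function(pr) {
    a <- weeks[weeks$week_index == pr[1], c("subject_id", outcome)]
    b <- weeks[weeks$week_index == pr[2], c("subject_id", outcome)]
    m <- merge(a, b, by = "subject_id", suffixes = c("_a", "_b"))
    if (!nrow(m)) return(NULL)
    data.frame(subject_id = m$subject_id,
               pair = sprintf("%dv%d", pr[1], pr[2]),
               mean = (m[[2]] + m[[3]]) / 2,
               diff = m[[2]] - m[[3]])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(subject_id = character(0), pair = character(0),
                      mean = numeric(0), diff = numeric(0))
  rownames(out) <- NULL
  out
}

#' Bland-Altman week-by-week agreement
#'
#' Mean week-by-week difference with 95% limits of agreement. The LoA
#' half-width is derived from the variance-component standard error of
#' measurement (`loa = sem * sqrt(2) * 1.96`), not from the SD of the pair
#' differences, so the agreement bands are consistent with the reliability
#' analysis that produced the SEM. A heteroscedasticity diagnostic
#' (regression of |difference| on pair mean) is attached when at least 10
#' pairs are available.
#'
#' @param pairs Output of [pair_weeks()] (at least 3 pairs).
#' @param sem The standard error of measurement for the outcome, either a
#'   number or a `reliability_estimate`/`varcomp` object.
#' @param outcome Optional outcome label for printing/plotting.
#' @return Object of class `bland_altman`: `pairs`, `mean_diff`,
#'   `loa_half_width`, `n_pairs_by_label`, `hetero_slope`, `hetero_p`,
#'   `heteroscedastic`.
#' @export
bland_altman <- function(pairs, sem, outcome = NULL) {
  if (nrow(pairs) < 3) stop("need at least 3 pairs")
  if (inherits(sem, "reliability_estimate")) sem <- sem$sem
  if (inherits(sem, "varcomp")) sem <- sem_from_components(sem)
  if (!is.numeric(sem) || length(sem) != 1 || sem < 0)
    stop("sem must be a single non-negative number")
  het <- if (nrow(pairs) >= 10 && stats::var(pairs$mean) > 0)
    heteroscedasticity_check(pairs)
  else list(hetero_slope = NA_real_, hetero_p = NA_real_,
            heteroscedastic = NA)
  structure(list(
    pairs = pairs,
    outcome = outcome,
    mean_diff = mean(pairs$diff),
    loa_half_width = loa_from_sem(sem),
    sem = sem,
    n_pairs_by_label = table(pairs$pair),
    hetero_slope = het$hetero_slope,
    hetero_p = het$hetero_p,
    heteroscedastic = het$heteroscedastic
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman week-by-week agreement%s\n",
              if (!is.null(x$outcome)) paste0(" [", x$outcome, "]") else ""))
  cat(sprintf("  mean difference = %.2f, LoA = +/- %.1f (SEM %.2f)\n",
              x$mean_diff, x$loa_half_width, x$sem))
  cat("  pairs: ", paste(sprintf("%s n=%d", names(x$n_pairs_by_label),
                                 as.integer(x$n_pairs_by_label)),
                         collapse = ", "), "\n", sep = "")
  if (!is.na(x$hetero_p))
    cat(sprintf("  |diff| ~ mean: slope = %.4g, p = %.3g (%s)\n",
                x$hetero_slope, x$hetero_p,
                if (isTRUE(x$heteroscedastic)) "heteroscedastic"
                else "homoscedastic"))
  invisible(x)
}

#' Plot a Bland-Altman agreement object
#'
#' Scatter of week-by-week differences against pair means: filled dots for
#' week 1 vs 2, open squares for week 1 vs 3, a solid line at the mean
#' difference and dotted lines at the 95% limits of agreement.
#'
#' @param x A `bland_altman` object.
#' @param ... Further arguments to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.bland_altman <- function(x, ...) {
  p <- x$pairs
  pch <- ifelse(p$pair == "1v2", 16L, ifelse(p$pair == "1v3", 0L, 2L))
  ylim <- range(c(p$diff, x$mean_diff + x$loa_half_width,
                  x$mean_diff - x$loa_half_width))
  args <- list(x = p$mean, y = p$diff, pch = pch,
               xlab = "Mean of the two weeks",
               ylab = "Difference between weeks", ylim = ylim,
               main = if (!is.null(x$outcome)) x$outcome else
                 "Week-by-week agreement")
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(graphics::plot, args)
  graphics::abline(h = x$mean_diff, lty = 1)
  graphics::abline(h = x$mean_diff + c(-1, 1) * x$loa_half_width, lty = 3)
  invisible(x)
}

#' Heteroscedasticity diagnostic for paired differences
#'
#' Ordinary least-squares regression of the absolute difference on the pair
#' mean; a two-sided p-value below `alpha` flags the variability as growing
#' (or shrinking) with the measured level.
#'
#' @param pairs Output of [pair_weeks()] (at least 10 pairs).
#' @param alpha Classification threshold.
#' @return List: `hetero_slope`, `hetero_p`, `heteroscedastic`.
#' @export
heteroscedasticity_check <- function(pairs, alpha = 0.05) {
  if (nrow(pairs) < 10) stop("need at least 10 pairs")
  if (stats::var(pairs$mean) == 0) stop("pair means have no variation")
  fit <- stats::lm(abs(diff) ~ mean, data = pairs)
  co <- summary(fit)$coefficients
  slope <- co["mean", "Estimate"]
  p <- co["mean", "Pr(>|t|)"]
  list(hetero_slope = slope, hetero_p = p, heteroscedastic = p < alpha)
}
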