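#' Intensity cut-points on minute-level vertical-axis counts
#'
#' Half-open counts-per-minute bands classifying each worn minute:
#' sedentary `[0, sed_upper)`, light `[sed_upper, lpa_upper)`, moderate
#' `[lpa_upper, mpa_upper)`, vigorous `[mpa_upper, Inf)`. Defaults are the
#' widely used adult hip cut-points: SED < 100 cpm, LPA 100-2019 cpm,
#' MPA 2020-5998 cpm, VPA >= 5999 cpm (MVPA >= 2020 cpm).
#'
#' @param sed_upper,lpa_upper,mpa_upper Exclusive upper bounds (cpm).
#' @return An object of class `cut_points`.
#' @examples
#' classify_minutes(c(99, 100, 2019, 2020, 5998, 5999), cut_points())
#' @export
cut_points <- function(sed_upper = 100, lpa_upper = 2020, mpa_upper = 5999) {
  if (!(0 < sed_upper && sed_upper < lpa_upper && lpa_upper < mpa_upper))
    stop("cut-points must satisfy 0 < sed_upper < lpa_upper < mpa_upper")
  structure(list(sed_upper = sed_upper, lpa_upper = lpa_upper,
                 mpa_upper = mpa_upper), class = "cut_points")
}

#' @export
print.cut_points <- function(x, ...) {
  cat(sprintf("Cut-points (cpm): SED [0, %g), LPA [%g, %g), MPA [%g, %g), VPA >= %g\n",
              x$sed_upper, x$sed_upper, x$lpa_upper, x$lpa_upper,
              x$mpa_upper, x$mpa_upper))
  invisible(x)
}

#' Wear-time validity criteria
#'
#' @param min_hours_per_day Minimum daily wear time (hours) for a valid day.
#' @param min_days_per_week Minimum valid days for a valid protocol week.
#' @return An object of class `wear_criteria`.
#' @export
wear_criteria <- function(min_hours_per_day = 10, min_days_per_week = 4) {
  if (min_hours_per_day <= 0 || min_hours_per_day > 24)
    stop("min_hours_per_day must lie in (0, 24]")
  if (min_days_per_week < 1 || min_days_per_week > 7)
    stop("min_days_per_week must lie in [1, 7]")
  structure(list(min_hours_per_day = min_hours_per_day,
                 min_days_per_week = as.integer(min_days_per_week)),
            class = "wear_criteria")
}

#' @export
print.wear_criteria <- function(x, ...) {
  cat(sprintf("Wear criteria: >= %g h/day, >= %d valid days/week\n",
              x$min_hours_per_day, x$min_days_per_week))
  invisible(x)
}

#' Aggregate an epoch series to calendar minutes
#'
#' Sums epoch counts (and vector-magnitude values) within each calendar
#' minute, per subject. Partial leading or trailing minutes (minutes not
#' covered by a full complement of epochs) are dropped.
#'
#' @param epochs Data frame with columns `subject_id`, `timestamp` (POSIXct),
#'   `axis1` and optionally `axis2`, `axis3`, `vm`.
#' @param epoch_seconds Epoch length in seconds; must divide 60. If `NULL`,
#'   inferred from the modal timestamp spacing.
#' @return Minute-level data frame (`subject_id`, `timestamp`, `axis1`, `vm`),
#'   one row per complete minute.
#' @export
aggregate_to_minutes <- function(epochs, epoch_seconds = NULL) {
  need <- c("subject_id", "timestamp", "axis1")
  if (!all(need %in% names(epochs)))
    stop("epochs must have columns ", paste(need, collapse = ", "))
  t_num <- as.numeric(epochs$timestamp)
  sid <- as.integer(factor(epochs$subject_id))
  ord <- order(sid, t_num)
  if (is.unsorted(ord)) {
    epochs <- epochs[ord, ]
    t_num <- t_num[ord]
    sid <- sid[ord]
  }
  d <- diff(t_num)
  d <- d[diff(sid) == 0L]
  if (is.null(epoch_seconds)) {
    if (!length(d)) stop("cannot infer epoch spacing from a single epoch")
    epoch_seconds <- sort(table(d), decreasing = TRUE)
    epoch_seconds <- as.numeric(names(epoch_seconds)[1])
  }
  if (length(d) && any(d != epoch_seconds))
    stop("non-uniform epoch spacing detected (expected ", epoch_seconds, " s)")
  if (60 %% epoch_seconds != 0) stop("epoch_seconds must divide 60")
  k <- 60L %/% as.integer(epoch_seconds)

  minute <- floor(t_num / 60)
  key <- sid * 2^32 + minute
  if (!"vm" %in% names(epochs)) {
    if (all(c("axis2", "axis3") %in% names(epochs)))
      epochs$vm <- sqrt(epochs$axis1^2 + epochs$axis2^2 + epochs$axis3^2)
    else epochs$vm <- as.numeric(epochs$axis1)
  }
  agg <- rowsum(cbind(axis1 = as.numeric(epochs$axis1), vm = epochs$vm,
                      n = 1), key, reorder = TRUE)
  ukey <- as.numeric(rownames(agg))
  complete <- agg[, "n"] == k
  usid <- as.integer(ukey %/% 2^32)
  uminute <- ukey - as.numeric(usid) * 2^32
  lev <- levels(factor(epochs$subject_id))
  data.frame(
    subject_id = factor(lev[usid[complete]], levels = lev),
    timestamp = as.POSIXct(uminute[complete] * 60, origin = "1970-01-01",
                           tz = "UTC"),
    axis1 = as.integer(agg[complete, "axis1"]),
    vm = agg[complete, "vm"],
    row.names = NULL
  )
}

#' Flag non-wear time in a minute series
#'
#' A maximal run of minutes is flagged non-wear when it is at least
#' `window_min` minutes long, consists of zero-count minutes apart from
#' interruptions of at most `tolerance_min` consecutive non-zero minutes, and
#' is terminated on both sides by a stretch of more than `tolerance_min`
#' consecutive non-zero minutes (or the start/end of the recording).
#' Interruption minutes inside a qualifying run are flagged non-wear; runs
#' begin and end on zero-count minutes. Detection operates on the full
#' per-subject series, so runs crossing midnight are flagged consistently on
#' both sides.
#'
#' @param minutes Minute-level data frame with `subject_id`, `timestamp`,
#'   `axis1` (counts per minute).
#' @param window_min Minimum run length in minutes (default 60).
#' @param tolerance_min Maximum tolerated interruption, minutes (default 2).
#' @param tolerance_mode `"consecutive"` (default): any single interruption of
#'   at most `tolerance_min` consecutive non-zero minutes is absorbed, with no
#'   cap on the number of interruptions per run. `"total"`: interruptions are
#'   absorbed greedily until the run's total non-zero minutes would exceed
#'   `tolerance_min`.
#' @return `minutes` with a logical `wear` column (TRUE = worn). The function
#'   is idempotent: flags are recomputed from the counts on each call.
#' @export
detect_nonwear <- function(minutes, window_min = 60, tolerance_min = 2,
                           tolerance_mode = c("consecutive", "total")) {
  tolerance_mode <- match.arg(tolerance_mode)
  if (window_min < 1) stop("window_min must be >= 1")
  if (tolerance_min < 0) stop("tolerance_min must be >= 0")
  stopifnot(all(c("subject_id", "timestamp", "axis1") %in% names(minutes)))
  if (any(minutes$axis1 < 0)) stop("negative counts")
  sidn <- as.integer(factor(minutes$subject_id))
  skey <- sidn * 2^34 + as.numeric(minutes$timestamp)
  if (is.unsorted(skey)) {
    minutes <- minutes[order(skey), ]
    rownames(minutes) <- NULL
  }
  flags <- unlist(lapply(
    split(minutes$axis1 > 0, minutes$subject_id, drop = TRUE),
    .nonwear_flags, window_min = window_min, tolerance_min = tolerance_min,
    mode = tolerance_mode), use.names = FALSE)
  minutes$wear <- !flags
  minutes
}

## run-length scan over one subject's nonzero indicator
.nonwear_flags <- function(nonzero, window_min, tolerance_min, mode) {
  n <- length(nonzero)
  if (!n) return(logical(0))
  r <- rle(nonzero)
  len <- r$lengths
  val <- r$values
  ends <- cumsum(len)
  starts <- ends - len + 1L
  m <- length(len)
  flag <- logical(n)
  i <- 1L
  while (i <= m) {
    if (val[i]) {
      i <- i + 1L
      next
    }
    j <- i
    nz_used <- 0L
    while (j + 2L <= m) {
      nzlen <- len[j + 1L]
      ok <- if (mode == "consecutive") nzlen <= tolerance_min
            else nz_used + nzlen <= tolerance_min
      if (!ok) break
      nz_used <- nz_used + nzlen
      j <- j + 2L
    }
    if (ends[j] - starts[i] + 1L >= window_min)
      flag[starts[i]:ends[j]] <- TRUE
    i <- j + 2L
  }
  flag
}

#' Classify minute counts into intensity bands
#'
#' @param counts_per_minute Numeric vector of vertical-axis counts per minute.
#' @param cuts A [cut_points()] object.
#' @return Factor with levels `SED`, `LPA`, `MPA`, `VPA`.
#' @export
classify_minutes <- function(counts_per_minute, cuts = cut_points()) {
  if (any(counts_per_minute < 0, na.rm = TRUE)) stop("negative counts")
  structure(.band_codes(counts_per_minute, cuts),
            levels = c("SED", "LPA", "MPA", "VPA"), class = "factor")
}

.band_codes <- function(counts_per_minute, cuts) {
  findInterval(counts_per_minute,
               c(cuts$sed_upper, cuts$lpa_upper, cuts$mpa_upper)) + 1L
}

#' Daily wear and activity summaries
#'
#' Reduces a wear-flagged minute series to one row per subject-day: wear
#' minutes, counts per minute over worn time (vertical axis and vector
#' magnitude), minutes and percentage of wear time in each intensity band,
#' the moderate + vigorous collapse (MVPA), weekend indicator, protocol day
#' and week indices, and validity flags at the 8, 10 and 12 h criteria. Days
#' are calendar days (midnight split). Days with zero wear minutes keep their
#' row with `NA` intensity summaries.
#'
#' @param minutes Output of [detect_nonwear()] (needs the `wear` column; it is
#'   computed with default settings when absent). A `vm` column is used for
#'   vector-magnitude cpm when present.
#' @param cuts A [cut_points()] object.
#' @return Data frame of class `accel_days` with columns `subject_id`, `date`,
#'   `day_index`, `week_index`, `weekend`, `wear_minutes`, `cpm`, `vm_cpm`,
#'   `sed_min`, `lpa_min`, `mpa_min`, `vpa_min`, `mvpa_min`, `sed_pct`,
#'   `lpa_pct`, `mvpa_pct`, `valid_8h`, `valid_10h`, `valid_12h`.
#' @export
summarize_days <- function(minutes, cuts = cut_points()) {
  if (!"wear" %in% names(minutes)) minutes <- detect_nonwear(minutes)
  if (!"vm" %in% names(minutes)) minutes$vm <- as.numeric(minutes$axis1)
  sid_f <- minutes$subject_id
  if (!is.factor(sid_f)) sid_f <- factor(sid_f)
  sid <- as.integer(sid_f)
  lev <- levels(sid_f)
  di <- as.integer(as.numeric(minutes$timestamp) %/% 86400L)  # UTC days
  key <- sid * 2^24 + (di - min(di))
  if (is.unsorted(key)) {
    ord <- order(key)
    minutes <- minutes[ord, ]
    sid <- sid[ord]
    di <- di[ord]
    key <- key[ord]
  }
  if (any(minutes$axis1 < 0)) stop("negative counts")
  new_day <- c(TRUE, diff(key) != 0)
  day_id <- cumsum(new_day)
  n_day <- day_id[length(day_id)]
  usid <- sid[new_day]
  udate <- as.Date(di[new_day], origin = "1970-01-01")

  w <- minutes$wear
  wi <- which(w)
  dw <- day_id[wi]
  band <- .band_codes(minutes$axis1[wi], cuts)
  wear_min <- tabulate(dw, nbins = n_day)
  bandcnt <- matrix(tabulate((dw - 1L) * 4L + band, nbins = 4L * n_day),
                    nrow = 4L)
  sums <- rowsum(cbind(minutes$axis1[wi], minutes$vm[wi]), dw,
                 reorder = TRUE)
  a1s <- vms <- numeric(n_day)
  present <- as.integer(rownames(sums))
  a1s[present] <- sums[, 1]
  vms[present] <- sums[, 2]

  pos <- wear_min > 0
  pct <- function(x) ifelse(pos, 100 * x / wear_min, NA_real_)
  days <- data.frame(
    subject_id = structure(usid, levels = lev, class = "factor"),
    date = udate,
    weekend = as.integer(format(udate, "%u")) >= 6L,
    wear_minutes = as.numeric(wear_min),
    cpm = ifelse(pos, a1s / wear_min, NA_real_),
    vm_cpm = ifelse(pos, vms / wear_min, NA_real_),
    sed_min = bandcnt[1, ],
    lpa_min = bandcnt[2, ],
    mpa_min = bandcnt[3, ],
    vpa_min = bandcnt[4, ],
    mvpa_min = bandcnt[3, ] + bandcnt[4, ],
    sed_pct = pct(bandcnt[1, ]),
    lpa_pct = pct(bandcnt[2, ]),
    mvpa_pct = pct(bandcnt[3, ] + bandcnt[4, ]),
    valid_8h = wear_min >= 480,
    valid_10h = wear_min >= 600,
    valid_12h = wear_min >= 720,
    row.names = NULL
  )
  first <- stats::ave(as.integer(days$date), days$subject_id, FUN = min)
  days$day_index <- as.integer(days$date) - first + 1L
  days$week_index <- (days$day_index - 1L) %/% 7L + 1L
  days <- days[c("subject_id", "date", "day_index", "week_index", "weekend",
                 "wear_minutes", "cpm", "vm_cpm", "sed_min", "lpa_min",
                 "mpa_min", "vpa_min", "mvpa_min", "sed_pct", "lpa_pct",
                 "mvpa_pct", "valid_8h", "valid_10h", "valid_12h")]
  class(days) <- c("accel_days", "data.frame")
  days
}

#' Retain days meeting a daily wear-time criterion
#'
#' @param days An `accel_days` data frame from [summarize_days()].
#' @param criteria A [wear_criteria()] object (only `min_hours_per_day` is
#'   used here).
#' @return The retained subset; the retained fraction (denominator: all input
#'   days) is attached as attribute `retained_fraction` (`NA` for empty input).
#' @export
filter_valid_days <- function(days, criteria = wear_criteria()) {
  keep <- days$wear_minutes >= 60 * criteria$min_hours_per_day
  out <- days[keep, , drop = FALSE]
  attr(out, "retained_fraction") <-
    if (nrow(days)) mean(keep) else NA_real_
  out
}

#' Weekly means over valid days
#'
#' Splits the protocol into fixed 7-day blocks (days 1-7, 8-14, 15-21, ...),
#' keeps days meeting the hour criterion, and computes per-outcome means over
#' the valid days of each subject-week. Weeks with fewer than
#' `min_days_per_week` valid days are dropped.
#'
#' @param days An `accel_days` data frame.
#' @param criteria A [wear_criteria()] object.
#' @return Data frame of class `accel_weeks`: `subject_id`, `week_index`,
#'   `n_valid_days`, and means of `wear_minutes`, `cpm`, `vm_cpm`, intensity
#'   minutes and percentages. The fraction of subject-weeks retained
#'   (denominator: all subject-weeks present in `days`) is attached as
#'   attribute `retained_fraction`.
#' @export
summarize_weeks <- function(days, criteria = wear_criteria()) {
  all_weeks <- unique(days[c("subject_id", "week_index")])
  valid <- days[days$wear_minutes >= 60 * criteria$min_hours_per_day, ,
                drop = FALSE]
  outs <- c("wear_minutes", "cpm", "vm_cpm", "sed_min", "lpa_min", "mpa_min",
            "vpa_min", "mvpa_min", "sed_pct", "lpa_pct", "mvpa_pct")
  if (!nrow(valid)) {
    out <- cbind(all_weeks[0, ], n_valid_days = integer(0))
    attr(out, "retained_fraction") <- if (nrow(all_weeks)) 0 else NA_real_
    class(out) <- c("accel_weeks", "data.frame")
    return(out)
  }
  sid <- as.integer(valid$subject_id)
  key <- sid * 1000L + valid$week_index
  agg <- rowsum(cbind(n = 1, as.matrix(valid[outs])), key, reorder = TRUE)
  ukey <- as.integer(rownames(agg))
  n <- agg[, "n"]
  out <- data.frame(
    subject_id = factor(levels(valid$subject_id)[ukey %/% 1000L],
                        levels = levels(valid$subject_id)),
    week_index = ukey %% 1000L,
    n_valid_days = as.integer(n)
  )
  for (o in outs) out[[o]] <- agg[, o] / n
  keep <- out$n_valid_days >= criteria$min_days_per_week
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "retained_fraction") <-
    if (nrow(all_weeks)) nrow(out) / nrow(all_weeks) else NA_real_
  class(out) <- c("accel_weeks", "data.frame")
  out
}

#' Reduce a cohort (or raw epoch data) to daily summaries
#'
#' Convenience wrapper running epoch-to-minute aggregation, non-wear
#' detection and daily summarisation.
#'
#' @param x An `accel_cohort`, an epoch-level data frame, or a minute-level
#'   data frame (`subject_id`, `timestamp`, `axis1`, optionally `vm`).
#' @param cuts A [cut_points()] object.
#' @param window_min,tolerance_min,tolerance_mode Passed to [detect_nonwear()].
#' @return An `accel_days` data frame.
#' @export
reduce_cohort <- function(x, cuts = cut_points(), window_min = 60,
                          tolerance_min = 2,
                          tolerance_mode = c("consecutive", "total")) {
  tolerance_mode <- match.arg(tolerance_mode)
  if (inherits(x, "accel_cohort")) {
    minutes <- if (x$resolution == "epoch")
      aggregate_to_minutes(x$epochs,
                           x$true_parameters$config$epoch_seconds)
    else x$minutes
  } else if (is.data.frame(x)) {
    spacing <- diff(as.numeric(x$timestamp[
      x$subject_id == x$subject_id[1]][1:2]))
    minutes <- if (isTRUE(spacing < 60)) aggregate_to_minutes(x) else x
  } else stop("x must be an accel_cohort or a data frame")
  minutes <- detect_nonwear(minutes, window_min, tolerance_min,
                            tolerance_mode)
  summarize_days(minutes, cuts)
}
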