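## End-to-end orchestration: simulate -> reduce -> reliability/association/
## agreement -> CSV tables, plots, manifest and log.

#' Configuration for a full pipeline run
#'
#' @param output_dir Directory for tables, plots, manifest and log.
#' @param simulation A [sim_config()] describing the synthetic cohort to
#'   generate, or `NULL` to analyse existing data given via `input`.
#' @param input Directory of epoch or minute CSVs (used when `simulation`
#'   is `NULL`).
#' @param hours,days Wear-criteria grids (hours/day and valid days/week) for
#'   the criterion-sensitivity tables; both must be non-empty.
#' @param primary_hours,primary_days The criterion used for the association,
#'   week-by-week reliability and agreement analyses.
#' @param cuts A [cut_points()] object.
#' @param icc_t Target reliability for days-needed projections, in (0, 1).
#' @param adjust_wear Also produce wear-adjusted week-by-week results?
#' @param resolution Simulation resolution passed to [simulate_cohort()].
#' @param seed Integer seed for the run (defaults to the simulation's seed).
#' @return An object of class `run_config`.
#' @export
run_config <- function(output_dir,
                       simulation = sim_config(),
                       input = NULL,
                       hours = c(8, 10, 12),
                       days = c(3, 4, 5),
                       primary_hours = 10,
                       primary_days = 4,
                       cuts = cut_points(),
                       icc_t = 0.80,
                       adjust_wear = TRUE,
                       resolution = "epoch",
                       seed = NULL) {
  if (!length(hours) || !length(days))
    stop("the wear-criteria grid (hours x days) must be non-empty")
  if (icc_t <= 0 || icc_t >= 1) stop("icc_t must lie strictly inside (0, 1)")
  if (is.null(simulation) && is.null(input))
    stop("either a simulation config or an input directory is required")
  if (!is.null(simulation)) stopifnot(inherits(simulation, "sim_config"))
  if (is.null(seed))
    seed <- if (!is.null(simulation)) simulation$seed else 1L
  structure(list(
    output_dir = output_dir, simulation = simulation, input = input,
    hours = hours, days = days, primary_hours = primary_hours,
    primary_days = primary_days, cuts = cuts, icc_t = icc_t,
    adjust_wear = adjust_wear, resolution = resolution,
    seed = as.integer(seed)
  ), class = "run_config")
}

.ba_outcomes <- c("wear_minutes", "cpm", "vm_cpm", "sed_min", "lpa_min",
                  "mvpa_min", "sed_pct", "lpa_pct", "mvpa_pct")

#' Run the full reliability pipeline
#'
#' Executes simulate (or load) -> reduce -> analyse -> report:
#' a wear-time association table, a single-day reliability table over the
#' hour-criteria grid, week-by-week reliability (crude and, optionally,
#' wear-adjusted) at the primary criterion, a weekly reliability grid over
#' all hour x day criteria, Bland-Altman pairs and plots, a JSON manifest
#' and a run log. Identical configuration and seed give byte-identical
#' tables.
#'
#' @param config A [run_config()] object.
#' @param quiet Suppress progress messages?
#' @return Invisibly, a list with the computed tables and the paths written.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  t0 <- Sys.time()
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, sprintf("[%s] %s",
                                       format(Sys.time(), "%H:%M:%S"), msg))
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    say("stage %s: start", name)
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say("stage %s: done", name)
    res
  }

  ## ---- data ----
  days <- if (!is.null(config$simulation)) {
    cohort <- stage("simulate", {
      cfg <- config$simulation
      cfg$seed <- config$seed
      simulate_cohort(cfg, resolution = config$resolution)
    })
    stage("reduce", reduce_cohort(cohort, cuts = config$cuts))
  } else {
    raw <- stage("load", {
      dat <- try(read_epoch_csv(config$input), silent = TRUE)
      if (inherits(dat, "try-error")) read_minute_csv(config$input) else dat
    })
    stage("reduce", reduce_cohort(raw, cuts = config$cuts))
  }
  say("reduced to %d subject-days (%d subjects)", nrow(days),
      nlevels(droplevels(days$subject_id)))

  ## ---- analyses ----
  tab_assoc <- stage("associate",
                     association_table(days, min_hours = config$primary_hours))
  tab_single <- stage("single-day reliability",
                      reliability_table(days, hours = config$hours,
                                        icc_t = config$icc_t))
  crit <- wear_criteria(config$primary_hours, config$primary_days)
  weeks <- stage("weekly means", summarize_weeks(days, crit))
  tab_weekly <- stage("weekly reliability", {
    crude <- weekly_reliability_table(weeks, adjust = FALSE,
                                      icc_t = config$icc_t)
    if (config$adjust_wear)
      rbind(crude, weekly_reliability_table(weeks, adjust = TRUE,
                                            icc_t = config$icc_t))
    else crude
  })
  tab_grid <- stage("weekly criteria grid", {
    grid <- expand.grid(min_hours = config$hours, min_days = config$days)
    res <- lapply(seq_len(nrow(grid)), function(i) {
      wk <- summarize_weeks(days, wear_criteria(grid$min_hours[i],
                                                grid$min_days[i]))
      tb <- weekly_reliability_table(wk, adjust = FALSE,
                                     icc_t = config$icc_t)
      cbind(min_hours = grid$min_hours[i], min_days = grid$min_days[i],
            n_weeks_retained = nrow(wk),
            pct_weeks_retained = 100 * attr(wk, "retained_fraction"),
            as.data.frame(tb))
    })
    do.call(rbind, res)
  })
  ba <- stage("agreement", {
    crude <- weekly_reliability_table(weeks, adjust = FALSE,
                                      outcomes = .ba_outcomes,
                                      icc_t = config$icc_t)
    lapply(stats::setNames(.ba_outcomes, .ba_outcomes), function(o) {
      pr <- pair_weeks(weeks, o)
      if (nrow(pr) < 3) return(NULL)
      bland_altman(pr, crude$sem[crude$outcome == o], outcome = o)
    })
  })

  ## ---- outputs ----
  paths <- list()
  wr <- function(obj, name) {
    p <- file.path(config$output_dir, name)
    utils::write.csv(as.data.frame(obj), p, row.names = FALSE)
    paths[[name]] <<- p
    say("wrote %s", p)
  }
  wr(tab_assoc, "table_wear_association.csv")
  wr(tab_single, "table_single_day_reliability.csv")
  wr(tab_weekly, "table_weekly_reliability.csv")
  wr(tab_grid, "table_weekly_criteria_grid.csv")
  all_pairs <- do.call(rbind, lapply(names(ba), function(o) {
    if (is.null(ba[[o]])) return(NULL)
    cbind(outcome = o, ba[[o]]$pairs)
  }))
  if (!is.null(all_pairs)) wr(all_pairs, "bland_altman_pairs.csv")

  plot_dir <- file.path(config$output_dir, "plots")
  dir.create(plot_dir, showWarnings = FALSE)
  use_svg <- isTRUE(capabilities("cairo"))
  for (o in names(ba)) {
    if (is.null(ba[[o]])) next
    p <- file.path(plot_dir,
                   paste0("bland_altman_", o, if (use_svg) ".svg" else ".pdf"))
    ok <- tryCatch({
      if (use_svg) grDevices::svg(p, width = 6, height = 5)
      else grDevices::pdf(p, width = 6, height = 5)
      plot(ba[[o]])
      grDevices::dev.off()
      TRUE
    }, error = function(e) {
      say("plot for %s skipped: %s", o, conditionMessage(e))
      FALSE
    })
    if (ok) paths[[basename(p)]] <- p
  }

  manifest <- list(
    package = "accelrel",
    package_version = as.character(utils::packageVersion("accelrel")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    icc_t = config$icc_t,
    hours = config$hours,
    days = config$days,
    primary_criteria = c(hours = config$primary_hours,
                         days = config$primary_days),
    cuts = unclass(config$cuts),
    simulated = !is.null(config$simulation),
    simulation = if (!is.null(config$simulation)) {
      cfg <- unclass(config$simulation)
      cfg$start_date <- format(cfg$start_date)
      lapply(cfg, function(v) if (is.numeric(v) && !is.null(names(v)))
        as.list(v) else v)
    },
    elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  mp <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths[["manifest.json"]] <- mp
  writeLines(log_lines, file.path(config$output_dir, "run.log"))

  invisible(list(days = days, weeks = weeks,
                 wear_association = tab_assoc,
                 single_day_reliability = tab_single,
                 weekly_reliability = tab_weekly,
                 weekly_criteria_grid = tab_grid,
                 bland_altman = ba,
                 paths = paths))
}

#' Small deterministic fixtures for tests and examples
#'
#' A tiny cohort (5 subjects, 21 days, minute resolution) plus hand-checkable
#' minute count sequences exercising the non-wear rule, each annotated with
#' the number of minutes the rule should flag.
#'
#' @param seed Integer seed.
#' @return List with `cohort` (an `accel_cohort`) and `sequences` (a named
#'   list; each element has `counts` and `expected_nonwear`).
#' @export
make_fixtures <- function(seed = 1L) {
  cohort <- simulate_cohort(
    sim_config(n_subjects = 5L, n_days = 21L, seed = seed),
    resolution = "minute")
  seqs <- list(
    zeros_59 = list(counts = c(50, rep(0, 59), 50),
                    expected_nonwear = 0L),
    zeros_70 = list(counts = c(50, rep(0, 70), 50),
                    expected_nonwear = 70L),
    interrupted_62 = list(counts = c(50, rep(0, 30), 120, 80, rep(0, 30), 50),
                          expected_nonwear = 62L),
    interruption_too_long = list(
      counts = c(50, rep(0, 30), 120, 80, 90, rep(0, 30), 50),
      expected_nonwear = 0L),
    exact_60 = list(counts = c(50, rep(0, 60), 50),
                    expected_nonwear = 60L)
  )
  list(cohort = cohort, sequences = seqs)
}
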