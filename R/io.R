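## Plain-text interchange: per-subject epoch CSVs, minute CSVs, ground-truth
## JSON, and structured (YAML/JSON) simulation configs.

#' Write a simulated cohort to per-subject CSV files
#'
#' Writes one CSV per subject with columns `subject_id`, `timestamp`
#' (ISO 8601, UTC), `axis1`, `axis2`, `axis3`, one row per epoch (or per
#' minute for minute-resolution cohorts), plus `true_parameters.json` with the
#' generator ground truth next to them.
#'
#' @param cohort An `accel_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "accel_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dat <- if (cohort$resolution == "epoch") cohort$epochs else cohort$minutes
  for (s in levels(dat$subject_id)) {
    d <- dat[dat$subject_id == s, ]
    out <- data.frame(
      subject_id = as.character(d$subject_id),
      timestamp = format(d$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      axis1 = d$axis1, axis2 = d$axis2, axis3 = d$axis3
    )
    utils::write.csv(out, file.path(dir, paste0(s, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  tp <- cohort$true_parameters
  cfg <- tp$config
  cfg$start_date <- format(cfg$start_date)
  jsonlite::write_json(
    list(true_icc = as.list(tp$true_icc),
         config = unclass(cfg),
         subject_intercepts = as.data.frame(tp$subject_intercepts),
         wear_subject_effects = as.list(tp$wear_subject_effects)),
    file.path(dir, "true_parameters.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

.read_count_csv <- function(path, cols) {
  files <- if (dir.exists(path))
    list.files(path, pattern = "\\.csv$", full.names = TRUE)
  else path
  files <- setdiff(files, files[basename(files) == "true_parameters.json"])
  if (!length(files)) stop("no CSV files found at ", path)
  dat <- do.call(rbind, lapply(files, function(f)
    utils::read.csv(f, stringsAsFactors = FALSE)))
  miss <- setdiff(cols, names(dat))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  dat$subject_id <- factor(dat$subject_id)
  dat$timestamp <- as.POSIXct(dat$timestamp, tz = "UTC",
                              tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                             "%Y-%m-%dT%H:%M:%OS",
                                             "%Y-%m-%d %H:%M:%OS"))
  dat
}

#' Read epoch-level count CSVs
#'
#' Reads the per-subject epoch CSV dialect written by [write_cohort()]:
#' columns `subject_id`, `timestamp` (ISO 8601), `axis1` and optionally
#' `axis2`, `axis3`. A `vm` column (per-epoch vector magnitude) is computed
#' from the axes when absent.
#'
#' @param path A CSV file or a directory of CSV files.
#' @return Epoch-level data frame.
#' @export
read_epoch_csv <- function(path) {
  dat <- .read_count_csv(path, c("subject_id", "timestamp", "axis1"))
  if (!"vm" %in% names(dat)) {
    dat$vm <- if (all(c("axis2", "axis3") %in% names(dat)))
      sqrt(dat$axis1^2 + dat$axis2^2 + dat$axis3^2)
    else as.numeric(dat$axis1)
  }
  dat
}

#' Read pre-aggregated minute-level count CSVs
#'
#' Accepts minute-resolution data with columns `subject_id`, `timestamp`,
#' `axis1` and optionally `vm` (vector-magnitude counts per minute).
#'
#' @param path A CSV file or a directory of CSV files.
#' @return Minute-level data frame.
#' @export
read_minute_csv <- function(path) {
  dat <- .read_count_csv(path, c("subject_id", "timestamp", "axis1"))
  if (!"vm" %in% names(dat)) dat$vm <- as.numeric(dat$axis1)
  dat
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file mirrors the [sim_config()] argument names; omitted fields keep
#' their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(lst), known)
  if (length(unknown))
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "))
  for (nm in c("outcome_means", "sigma2_between", "sigma2_within",
               "weekend_effect", "mean_bout_minutes"))
    if (!is.null(lst[[nm]])) lst[[nm]] <- unlist(lst[[nm]])
  if (!is.null(lst$start_date)) lst$start_date <- as.Date(lst$start_date)
  do.call(sim_config, lst)
}
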