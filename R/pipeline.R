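#' Read and write the canonical registry files
#'
#' The pipeline's canonical on-disk format is three tab-delimited text
#' files with ISO-8601 dates: `patients.tsv` (`patient_id`, `sex`,
#' `birth_year`, `death_year`, `death_month`), `dispensings.tsv`
#' (`patient_id`, `dispense_date`, `atc_code`, `n_units`, `n_ddd`,
#' `formulation`) and `population_counts.tsv` (`year`, `age`, `sex`,
#' `drug_group`, `users`, `population`).
#'
#' @param registry list with `patients` and `dispensings` data.frames.
#' @param dir directory for the files (created if needed).
#' @return `write_registry()` returns the paths invisibly;
#'   `read_registry()` returns a list with validated `patients` and
#'   `dispensings`.
#' @export
write_registry <- function(registry, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(patients = file.path(dir, "patients.tsv"),
             dispensings = file.path(dir, "dispensings.tsv"))
  utils::write.table(registry$patients, paths["patients"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  disp <- registry$dispensings
  disp$dispense_date <- format(disp$dispense_date)
  utils::write.table(disp, paths["dispensings"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' @rdname write_registry
#' @export
read_registry <- function(dir) {
  patients <- utils::read.delim(file.path(dir, "patients.tsv"),
                                colClasses = c(patient_id = "character",
                                               sex = "character"))
  dispensings <- utils::read.delim(file.path(dir, "dispensings.tsv"),
                                   colClasses = c(patient_id = "character",
                                                  atc_code = "character"))
  dispensings$dispense_date <- as.Date(dispensings$dispense_date)
  validate_registry(patients, dispensings)
  list(patients = patients, dispensings = dispensings)
}

#' @rdname write_registry
#' @param pop population counts data.frame.
#' @param path file path.
#' @export
write_population_counts <- function(pop, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(pop, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_population_counts <- function(path) {
  pop <- utils::read.delim(path, colClasses = c(sex = "character",
                                                drug_group = "character"))
  req <- c("year", "age", "sex", "drug_group", "users", "population")
  missing_cols <- setdiff(req, names(pop))
  if (length(missing_cols))
    stop("population counts file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- which(pop$users > pop$population | pop$users < 0)
  if (length(bad))
    stop("population counts: users outside [0, population] at row(s) ",
         paste(utils::head(bad), collapse = ", "))
  pop
}

#' Validate registry tables
#'
#' Schema and content checks for the two individual-level registry tables;
#' violations raise an error identifying the offending rows.
#'
#' @param patients,dispensings registry tables.
#' @return `TRUE` invisibly.
#' @export
validate_registry <- function(patients, dispensings) {
  req_p <- c("patient_id", "sex", "birth_year", "death_year", "death_month")
  req_d <- c("patient_id", "dispense_date", "atc_code", "n_units")
  miss <- setdiff(req_p, names(patients))
  if (length(miss))
    stop("patients table lacks column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(req_d, names(dispensings))
  if (length(miss))
    stop("dispensings table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(!patients$sex %in% c("male", "female"))
  if (length(bad))
    stop("patients: invalid sex at row(s) ",
         paste(utils::head(bad), collapse = ", "))
  bad <- which(!is.na(patients$death_year) &
                 patients$death_year < patients$birth_year)
  if (length(bad))
    stop("patients: death before birth at row(s) ",
         paste(utils::head(bad), collapse = ", "))
  if (nrow(dispensings)) {
    bad <- which(!is_valid_atc(dispensings$atc_code) |
                   nchar(dispensings$atc_code) != 7)
    if (length(bad))
      stop("dispensings: malformed ATC code at row(s) ",
           paste(utils::head(bad), collapse = ", "))
    bad <- which(is.na(dispensings$dispense_date))
    if (length(bad))
      stop("dispensings: unparseable date at row(s) ",
           paste(utils::head(bad), collapse = ", "))
    bad <- which(dispensings$n_units < 1)
    if (length(bad))
      stop("dispensings: n_units < 1 at row(s) ",
           paste(utils::head(bad), collapse = ", "))
  }
  invisible(TRUE)
}

#' Simulate a registry and write the canonical input files
#'
#' Wraps [simulate_registry()] and [simulate_population_counts()]: writes
#' `patients.tsv`, `dispensings.tsv`, `population_counts.tsv` and a
#' `manifest.txt` recording the generator parameters (including the seed)
#' so a run can be reproduced exactly.
#'
#' @param config a [sim_config()].
#' @param dir output directory.
#' @param target_prevalence,population_per_cell passed to
#'   [simulate_population_counts()].
#' @return Invisibly, the named vector of file paths.
#' @export
run_simulate <- function(config, dir,
                         target_prevalence = default_gp_prevalence(),
                         population_per_cell = 10000) {
  stopifnot(inherits(config, "sim_config"))
  reg <- simulate_registry(config)
  pop <- simulate_population_counts(config, target_prevalence,
                                    population_per_cell)
  paths <- write_registry(reg, dir)
  paths["population_counts"] <-
    write_population_counts(pop, file.path(dir, "population_counts.tsv"))
  manifest <- c(
    sprintf("seed=%d", config$seed),
    sprintf("n_patients=%d", config$n_patients),
    sprintf("calendar_span=%d-%d", config$calendar_span[1],
            config$calendar_span[2]),
    sprintf("initiation_years=%d-%d", config$initiation_years[1],
            config$initiation_years[2]),
    sprintf("persistent_fraction=%g", config$persistent_fraction),
    sprintf("dropout_fraction=%g", config$dropout_fraction),
    sprintf("sex_ratio_female=%g", config$sex_ratio_female),
    sprintf("population_per_cell=%g", population_per_cell),
    sprintf("n_dispensing_rows=%d", nrow(reg$dispensings)),
    sprintf("n_population_rows=%d", nrow(pop)))
  paths["manifest"] <- file.path(dir, "manifest.txt")
  writeLines(manifest, paths["manifest"])
  invisible(paths)
}

#' Analyze a registry directory and write result tables
#'
#' Reads the three canonical registry files from `dir`, runs
#' [achei_study()] and writes the result tables to `out_dir` as
#' tab-delimited text: `cohort.tsv`, `exclusions.tsv`, `cohort_summary.tsv`,
#' `prevalence.tsv`, `combinations.tsv`, `any_of_groups.tsv`,
#' `gp_adjusted.tsv`, `report.tsv`, plus a `run.log` recording parameter
#' values and row counts per stage. Outputs contain no timestamps, so a
#' rerun on identical inputs is byte-identical. An empty registry yields
#' empty tables and a warning, not an error.
#'
#' @param dir directory holding the canonical registry files.
#' @param out_dir output directory.
#' @param ... passed to [achei_study()].
#' @return The `achei_study` object, invisibly.
#' @export
run_analyze <- function(dir, out_dir, ...) {
  reg <- read_registry(dir)
  pop_path <- file.path(dir, "population_counts.tsv")
  pop <- if (file.exists(pop_path)) read_population_counts(pop_path)
  else NULL
  fit <- withCallingHandlers(
    achei_study(reg$patients, reg$dispensings, pop, ...),
    warning = function(w) {
      message("warning: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- c(sprintf("input_dir=%s", dir),
           sprintf("n_patients=%d", nrow(reg$patients)),
           sprintf("n_dispensings=%d", nrow(reg$dispensings)),
           sprintf("population_table=%s", !is.null(pop)),
           sprintf("index_window=%s..%s", fit$params$index_window[1],
                   fit$params$index_window[2]),
           sprintf("conf_level=%g", fit$params$conf_level),
           sprintf("suppress_below=%g", fit$params$suppress_below),
           sprintf("n_members=%d", nrow(fit$cohort$members)),
           sprintf("n_excluded=%d", nrow(fit$cohort$exclusions)))

  wt <- function(x, name) {
    if (is.null(x)) x <- data.frame()
    df <- x
    for (cn in names(df)) if (inherits(df[[cn]], "Date"))
      df[[cn]] <- format(df[[cn]])
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log <<- c(log, sprintf("%s=%d rows", name, nrow(df)))
  }
  wt(fit$cohort$members, "cohort.tsv")
  wt(fit$cohort$exclusions, "exclusions.tsv")
  wt(fit$cohort_summary, "cohort_summary.tsv")
  wt(fit$prevalence, "prevalence.tsv")
  wt(fit$combinations, "combinations.tsv")
  wt(fit$any_of_groups, "any_of_groups.tsv")
  wt(fit$gp, "gp_adjusted.tsv")
  wt(fit$report, "report.tsv")
  writeLines(log, file.path(out_dir, "run.log"))
  message(paste(log, collapse = "\n"))
  invisible(fit)
}
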