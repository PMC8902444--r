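#' Select the study cohort of persistent incident AChEI users
#'
#' Applies the inclusion/exclusion cascade to every patient with at least
#' one AChEI dispensing: build use periods, select the index period, then
#' exclude — in this fixed order, logging the first reason that triggers —
#' candidates who
#' \enumerate{
#'   \item are not demonstrably incident (index date within `gap_days` of
#'     the start of registry coverage, so the washout cannot be verified);
#'   \item are not persistent by the refill-pattern rules
#'     ([classify_persistent()]);
#'   \item have an index date outside the inclusion window
#'     (default 2008-01-01 to 2013-12-31);
#'   \item are older than the age cap at index (default 88, the limit set
#'     by the 0-89 age resolution of the general-population reference);
#'   \item died within 2 years after the year of initiation
#'     (`death_year <= index_year + 2`; death is recorded at year/month
#'     resolution and the rule counts calendar years);
#'   \item have no dispensing of any drug in days 365-729 after index
#'     (absent from the registry in the second year, e.g. moved to a
#'     nursing home).
#' }
#' Age is `index_year - birth_year` throughout (the registry carries birth
#' year only). Members are stratified into two age groups at `age_break`
#' (default 80).
#'
#' @param patients patient table (`patient_id`, `sex`, `birth_year`,
#'   `death_year`, `death_month`).
#' @param dispensings dispensing records (`patient_id`, `dispense_date`,
#'   `atc_code`, `n_units`).
#' @param index_window two Dates, the inclusion window for index dates.
#' @param age_cap maximum age at index (inclusive).
#' @param age_break boundary between the two age strata; ages `<=
#'   age_break` fall in the first stratum.
#' @param age_group_labels labels for the two strata.
#' @param gap_days washout / period-splitting gap (days).
#' @param horizon_days,supply_days persistence-rule parameters, see
#'   [classify_persistent()].
#' @param rates a [daily_rate_table()].
#' @param data_start first date of registry coverage; defaults to the
#'   earliest dispensing date. An index date before `data_start +
#'   gap_days` cannot have a verified washout.
#' @param registry_window day range (relative to index) in which at least
#'   one dispensing of any drug is required (default `c(365, 729)`).
#' @return List of class `achei_cohort`: `members` (one row per included
#'   patient: `patient_id`, `sex`, `birth_year`, `index_date`,
#'   `index_year`, `age_at_index`, `age_group`, `n_prescriptions`,
#'   `treatment_length`, `persistence_rule`) and `exclusions` (one row per
#'   excluded candidate: `patient_id`, `reason`).
#' @export
select_cohort <- function(patients, dispensings,
                          index_window = as.Date(c("2008-01-01",
                                                   "2013-12-31")),
                          age_cap = 88, age_break = 80,
                          age_group_labels = c("37-80", "81-88"),
                          gap_days = 365, horizon_days = 240,
                          supply_days = 210,
                          rates = daily_rate_table(),
                          data_start = NULL,
                          registry_window = c(365L, 729L)) {
  empty_members <- data.frame(
    patient_id = character(), sex = character(), birth_year = integer(),
    index_date = as.Date(character()), index_year = integer(),
    age_at_index = integer(), age_group = character(),
    n_prescriptions = integer(), treatment_length = integer(),
    persistence_rule = integer())
  empty_excl <- data.frame(patient_id = character(), reason = character())
  out <- function(members, exclusions)
    structure(list(members = members, exclusions = exclusions),
              class = "achei_cohort")
  if (nrow(dispensings) == 0) return(out(empty_members, empty_excl))

  is_achei <- startsWith(dispensings$atc_code, "N06DA")
  achei <- dispensings[is_achei, , drop = FALSE]
  if (nrow(achei) == 0) return(out(empty_members, empty_excl))
  achei <- achei[order(achei$patient_id, achei$dispense_date), , drop = FALSE]
  if (is.null(data_start)) data_start <- min(dispensings$dispense_date)

  # index period per AChEI-ever patient
  per_patient <- split(
    data.frame(date = achei$dispense_date, atc_code = achei$atc_code,
               n_units = achei$n_units),
    achei$patient_id)
  cand <- do.call(rbind, lapply(names(per_patient), function(pid) {
    idx <- select_index_period(
      build_use_periods(per_patient[[pid]], gap_days, rates))
    cls <- classify_persistent(idx, horizon_days, supply_days, rates)
    data.frame(patient_id = pid, index_date = idx$start_date,
               n_prescriptions = idx$n_prescriptions,
               treatment_length = treatment_length(idx),
               persistent = cls$persistent,
               persistence_rule = cls$rule)
  }))

  pi <- match(cand$patient_id, patients$patient_id)
  if (anyNA(pi))
    stop("dispensing records reference patients missing from the patient table: ",
         paste(utils::head(cand$patient_id[is.na(pi)]), collapse = ", "))
  cand$sex <- patients$sex[pi]
  cand$birth_year <- patients$birth_year[pi]
  cand$death_year <- patients$death_year[pi]
  cand$index_year <- as.integer(format(cand$index_date, "%Y"))
  cand$age_at_index <- cand$index_year - cand$birth_year

  # >=1 dispensing of any drug in the second year after index
  di <- match(dispensings$patient_id, cand$patient_id)
  day <- as.integer(dispensings$dispense_date - cand$index_date[di])
  present_ids <- unique(dispensings$patient_id[
    !is.na(di) & day >= registry_window[1] & day <= registry_window[2]])
  cand$present_y2 <- cand$patient_id %in% present_ids

  reason <- rep(NA_character_, nrow(cand))
  flag <- function(cond, label) ifelse(is.na(reason) & cond, label, reason)
  reason <- flag(cand$index_date < data_start + gap_days, "not_incident")
  reason <- flag(!cand$persistent, "not_persistent")
  reason <- flag(cand$index_date < index_window[1] |
                   cand$index_date > index_window[2],
                 "index_outside_window")
  reason <- flag(cand$age_at_index > age_cap, "over_age_cap")
  reason <- flag(!is.na(cand$death_year) &
                   cand$death_year <= cand$index_year + 2,
                 "died_within_2y")
  reason <- flag(!cand$present_y2, "absent_from_registry_y2")

  members <- cand[is.na(reason), , drop = FALSE]
  members$age_group <- ifelse(members$age_at_index <= age_break,
                              age_group_labels[1], age_group_labels[2])
  members <- members[c("patient_id", "sex", "birth_year", "index_date",
                       "index_year", "age_at_index", "age_group",
                       "n_prescriptions", "treatment_length",
                       "persistence_rule")]
  rownames(members) <- NULL
  exclusions <- data.frame(patient_id = cand$patient_id[!is.na(reason)],
                           reason = reason[!is.na(reason)])
  out(members, exclusions)
}

#' @export
print.achei_cohort <- function(x, ...) {
  cat(sprintf("AChEI study cohort: %d members, %d excluded candidates\n",
              nrow(x$members), nrow(x$exclusions)))
  if (nrow(x$exclusions)) {
    tab <- table(x$exclusions$reason)
    for (r in names(tab)) cat(sprintf("  excluded %-24s %6d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Summarize the cohort by sex and age group
#'
#' @param members cohort member data.frame from [select_cohort()].
#' @return data.frame with one row per age group plus an `"all"` row:
#'   counts overall and by sex, and percent female. Empty for an empty
#'   cohort.
#' @export
summarize_cohort <- function(members) {
  if (nrow(members) == 0)
    return(data.frame(age_group = character(), n = integer(),
                      n_female = integer(), n_male = integer(),
                      pct_female = numeric()))
  one <- function(m, label) data.frame(
    age_group = label, n = nrow(m),
    n_female = sum(m$sex == "female"),
    n_male = sum(m$sex == "male"),
    pct_female = 100 * mean(m$sex == "female"))
  groups <- sort(unique(members$age_group))
  rows <- lapply(groups, function(g)
    one(members[members$age_group == g, , drop = FALSE], g))
  rbind(do.call(rbind, rows), one(members, "all"))
}
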