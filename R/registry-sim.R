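#' Configuration for the synthetic registry generator
#'
#' Defines the statistical structure of a synthetic prescription registry
#' emulating a nationwide dispensing database: every simulated patient is
#' an AChEI initiator (mirroring a registry extract of all persons ever
#' dispensed an AChEI), with longitudinal refill streams per co-medication
#' group, a configurable fraction of streams satisfying the persistence
#' rules, an age-dependent death process and an institutionalization-style
#' dropout that hard-stops all dispensings.
#'
#' @param n_patients number of simulated AChEI initiators.
#' @param calendar_span two-element integer vector, first and last calendar
#'   year covered by the registry (default 2004-2016).
#' @param initiation_years two-element integer vector, the years in which
#'   index AChEI dispensings occur (default 2008-2013); must lie within
#'   `calendar_span`.
#' @param sex_ratio_female probability that a patient is female
#'   (default 0.63, the share of women among AChEI initiators).
#' @param age_at_index named numeric vector `c(mean, sd, min, max)` of the
#'   truncated-normal age-at-initiation distribution. The default
#'   (mean 79, sd 6.5, range 45-92) centres initiation in the late 70s and
#'   deliberately extends past the 88-year study cap so the age-cap
#'   exclusion is exercised.
#' @param persistent_fraction probability that an initiator's refill stream
#'   satisfies the persistence rules; the remainder receive streams
#'   violating all three rules.
#' @param achei_shares named probability vector over full AChEI ATC codes
#'   (default: donepezil N06DA02 0.75, rivastigmine N06DA03 0.15,
#'   galantamine N06DA04 0.10).
#' @param refill_interval_days two-element integer vector; refill intervals
#'   are drawn uniformly from this range (default 25-95 days).
#' @param treatment_duration_days two-element integer vector; intended
#'   AChEI treatment length of persistent users, drawn uniformly (default
#'   270-1800 days; the lower end keeps refills running past the
#'   persistence horizon).
#' @param drug_use_probability named list/vector mapping co-medication
#'   group name to the probability of at least one dispensing of that
#'   group per 365-day follow-up window; each element is either a single
#'   probability or a named vector `c(male = , female = )`.
#' @param background_use_probability per-window probability of at least one
#'   dispensing of an unrelated background drug (paracetamol, N02BE01);
#'   keeps living, non-institutionalized patients visible in the registry.
#' @param dropout_fraction fraction of patients whose dispensings cease
#'   permanently (institutionalization proxy) from a random day 241-729
#'   after the index date.
#' @param annual_death_hazard function of age returning the annual death
#'   probability; the default is a Gompertz-type hazard
#'   `min(0.5, 2e-5 * exp(0.1 * age))`, about 6% per year at age 80.
#'   Deaths are simulated from the initiation year onwards (patients are
#'   alive at initiation by construction) and never before day 241 after
#'   index, so truncation cannot undo a generated persistent stream.
#' @param seed integer seed; a fixed seed makes the generated registry
#'   byte-identical across runs.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_patients = 1000,
                       calendar_span = c(2004L, 2016L),
                       initiation_years = c(2008L, 2013L),
                       sex_ratio_female = 0.63,
                       age_at_index = c(mean = 79, sd = 6.5,
                                        min = 45, max = 92),
                       persistent_fraction = 0.8,
                       achei_shares = c(N06DA02 = 0.75, N06DA03 = 0.15,
                                        N06DA04 = 0.10),
                       refill_interval_days = c(25L, 95L),
                       treatment_duration_days = c(270L, 1800L),
                       drug_use_probability = c(
                         haloperidol = 0.012,
                         citalopram_escitalopram = 0.15,
                         verapamil = 0.014,
                         betablockers = 0.28,
                         digitalis = 0.035),
                       background_use_probability = 0.98,
                       dropout_fraction = 0.05,
                       annual_death_hazard = function(age)
                         pmin(0.5, 2e-5 * exp(0.1 * age)),
                       seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              calendar_span = as.integer(calendar_span),
              initiation_years = as.integer(initiation_years),
              sex_ratio_female = sex_ratio_female,
              age_at_index = age_at_index,
              persistent_fraction = persistent_fraction,
              achei_shares = achei_shares,
              refill_interval_days = as.integer(refill_interval_days),
              treatment_duration_days = as.integer(treatment_duration_days),
              drug_use_probability = as.list(drug_use_probability),
              background_use_probability = background_use_probability,
              dropout_fraction = dropout_fraction,
              annual_death_hazard = annual_death_hazard,
              seed = as.integer(seed))

  probs <- c(sex_ratio_female, persistent_fraction,
             background_use_probability, dropout_fraction,
             unlist(cfg$drug_use_probability))
  if (any(probs < 0 | probs > 1))
    stop("configuration error: all probabilities must be in [0, 1]")
  if (cfg$n_patients < 0)
    stop("configuration error: n_patients must be >= 0")
  if (length(cfg$calendar_span) != 2 ||
      cfg$calendar_span[1] > cfg$calendar_span[2])
    stop("configuration error: empty calendar span")
  if (length(cfg$initiation_years) != 2 ||
      cfg$initiation_years[1] > cfg$initiation_years[2])
    stop("configuration error: empty initiation year range")
  if (cfg$initiation_years[1] < cfg$calendar_span[1] ||
      cfg$initiation_years[2] > cfg$calendar_span[2])
    stop("configuration error: initiation years outside calendar span")
  if (abs(sum(cfg$achei_shares) - 1) > 1e-8)
    stop("configuration error: achei_shares must sum to 1")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic registry config: %d patients, span %d-%d, initiation %d-%d,\n  persistent fraction %.2f, dropout %.2f, seed %d\n",
    x$n_patients, x$calendar_span[1], x$calendar_span[2],
    x$initiation_years[1], x$initiation_years[2],
    x$persistent_fraction, x$dropout_fraction, x$seed))
  invisible(x)
}

# per-window use probability for one group, possibly sex-specific
.use_prob <- function(cfg, group, sex) {
  p <- cfg$drug_use_probability[[group]]
  if (length(p) == 1) rep(unname(p), length(sex)) else unname(p[sex])
}

# full ATC codes dispensed for each synthetic co-medication group
.group_atc_pool <- function(group) {
  switch(group,
         haloperidol = "N05AD01",
         citalopram_escitalopram = c("N06AB10", "N06AB04"),
         verapamil = "C08DA01",
         betablockers = c("C07AB02", "C07AB03", "C07AG02"),
         digitalis = c("C01AA05", "C01AA04"),
         diuretics = c("C03CA01", "C03AA03"),
         "N02BE01")
}

.last_day_of_month <- function(year, month) {
  first_next <- as.Date(sprintf("%d-%02d-01",
                                year + (month == 12L),
                                ifelse(month == 12L, 1L, month + 1L)))
  first_next - 1L
}

# AChEI refill stream for one patient: day offsets and unit counts.
# Persistent streams keep continuous supply (each dispensing outlasts its
# refill gap by 10 days) and run past the persistence horizon; short
# streams violate all three rules by construction.
.achei_stream <- function(persistent, rate, cfg) {
  if (persistent) {
    dur <- sample(cfg$treatment_duration_days[1]:cfg$treatment_duration_days[2], 1)
    days <- integer(0)
    t <- 0L
    while (t <= dur) {
      days <- c(days, t)
      t <- t + sample(cfg$refill_interval_days[1]:cfg$refill_interval_days[2], 1)
    }
    gaps <- c(diff(days), sample(cfg$refill_interval_days[1]:cfg$refill_interval_days[2], 1))
    units <- as.integer(ceiling((gaps + 10L) * rate))
  } else {
    u1 <- sample(20:90, 1)
    days <- 0L
    supply <- u1
    if (stats::runif(1) < 0.5) {
      i <- sample(30:110, 1)
      u2 <- sample(20:90, 1)  # i + u2 <= 200 < 210: rule 3 cannot fire
      days <- c(days, i)
      supply <- c(supply, u2)
    }
    units <- as.integer(ceiling(supply * rate))
  }
  list(day = days, n_units = units)
}

#' Generate a synthetic dispensing registry
#'
#' Simulates patients and their individual dispensing records according to
#' a [sim_config()]. Every patient is an AChEI initiator; the configured
#' `persistent_fraction` receive refill streams satisfying the persistence
#' rules and the remainder streams violating all three. Co-medication
#' dispensings are placed window-by-window around each patient's index
#' date with the configured per-window use probabilities. Deaths truncate
#' all dispensings at the end of the death month; institutionalized
#' dropouts cease dispensing from their cessation day.
#'
#' @param config a [sim_config()].
#' @return List with elements `patients` (data.frame: `patient_id`, `sex`,
#'   `birth_year`, `death_year`, `death_month`), `dispensings` (data.frame:
#'   `patient_id`, `dispense_date`, `atc_code`, `n_units`, `n_ddd`,
#'   `formulation`, sorted by patient and date) and `truth` (data.frame of
#'   generator-level ground truth per patient: `index_date`, `index_year`,
#'   `age_at_index`, `persistent`, `dropout_day`).
#' @examples
#' reg <- simulate_registry(sim_config(n_patients = 50, seed = 7))
#' head(reg$dispensings)
#' @export
simulate_registry <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  empty_patients <- data.frame(
    patient_id = character(), sex = character(), birth_year = integer(),
    death_year = integer(), death_month = integer())
  empty_disp <- data.frame(
    patient_id = character(), dispense_date = as.Date(character()),
    atc_code = character(), n_units = integer(), n_ddd = numeric(),
    formulation = character())
  empty_truth <- data.frame(
    patient_id = character(), index_date = as.Date(character()),
    index_year = integer(), age_at_index = integer(),
    persistent = logical(), dropout_day = integer())
  if (n == 0)
    return(list(patients = empty_patients, dispensings = empty_disp,
                truth = empty_truth))

  span_start <- as.Date(sprintf("%d-01-01", config$calendar_span[1]))
  span_end <- as.Date(sprintf("%d-12-31", config$calendar_span[2]))

  patient_id <- sprintf("P%06d", seq_len(n))
  sex <- ifelse(stats::runif(n) < config$sex_ratio_female,
                "female", "male")
  init_year <- sample(config$initiation_years[1]:config$initiation_years[2],
                      n, replace = TRUE)
  index_date <- as.Date(sprintf("%d-01-01", init_year)) +
    sample(0:364, n, replace = TRUE)

  ai <- config$age_at_index
  age <- round(stats::rnorm(n, ai[["mean"]], ai[["sd"]]))
  while (any(bad <- age < ai[["min"]] | age > ai[["max"]]))
    age[bad] <- round(stats::rnorm(sum(bad), ai[["mean"]], ai[["sd"]]))
  age <- as.integer(age)
  birth_year <- init_year - age

  persistent <- stats::runif(n) < config$persistent_fraction
  achei_code <- sample(names(config$achei_shares), n, replace = TRUE,
                       prob = config$achei_shares)
  achei_rate <- ifelse(achei_code == "N06DA03", 2, 1)

  # -- AChEI refill streams ------------------------------------------------
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    s <- .achei_stream(persistent[i], achei_rate[i], config)
    streams[[i]] <- data.frame(
      patient_id = patient_id[i],
      dispense_date = index_date[i] + s$day,
      atc_code = achei_code[i],
      n_units = s$n_units)
  }
  achei_disp <- do.call(rbind, streams)

  # -- co-medication and background dispensings ----------------------------
  windows <- follow_up_windows()
  groups <- names(config$drug_use_probability)
  pieces <- list(achei_disp)
  for (g in c(groups, ".background")) {
    pool <- .group_atc_pool(if (g == ".background") "background" else g)
    for (w in seq_len(nrow(windows))) {
      p <- if (g == ".background")
        rep(config$background_use_probability, n)
      else .use_prob(config, g, sex)
      hit <- which(stats::runif(n) < p)
      if (!length(hit)) next
      extra <- hit[stats::runif(length(hit)) < 0.4]
      who <- c(hit, extra)
      day <- windows$day_start[w] + sample(0:364, length(who), replace = TRUE)
      pieces[[length(pieces) + 1L]] <- data.frame(
        patient_id = patient_id[who],
        dispense_date = index_date[who] + day,
        atc_code = sample(pool, length(who), replace = TRUE),
        n_units = sample(30:100, length(who), replace = TRUE))
    }
  }
  disp <- do.call(rbind, pieces)

  # -- death process (never before day 241 after index) --------------------
  death_year <- rep(NA_integer_, n)
  death_month <- rep(NA_integer_, n)
  alive <- rep(TRUE, n)
  for (year in config$initiation_years[1]:config$calendar_span[2]) {
    at_risk <- alive & init_year <= year
    q <- config$annual_death_hazard(year - birth_year)
    dies <- at_risk & stats::runif(n) < q
    death_year[dies] <- year
    death_month[dies] <- sample(1:12, sum(dies), replace = TRUE)
    alive[dies] <- FALSE
  }
  dead <- which(!is.na(death_year))
  if (length(dead)) {
    floor_date <- index_date[dead] + 241L
    death_end <- .last_day_of_month(death_year[dead], death_month[dead])
    late <- death_end < floor_date
    death_year[dead[late]] <-
      as.integer(format(floor_date[late], "%Y"))
    death_month[dead[late]] <-
      as.integer(format(floor_date[late], "%m"))
  }

  # -- institutionalization-style dropout ----------------------------------
  dropout_day <- rep(NA_integer_, n)
  drops <- which(stats::runif(n) < config$dropout_fraction)
  dropout_day[drops] <- sample(241:729, length(drops), replace = TRUE)

  # -- truncation: span, dropout, death ------------------------------------
  keep <- disp$dispense_date >= span_start & disp$dispense_date <= span_end
  pi <- match(disp$patient_id, patient_id)
  cease <- index_date[pi] + dropout_day[pi]
  keep <- keep & (is.na(cease) | disp$dispense_date < cease)
  dm_end <- rep(as.Date(NA), n)
  if (length(dead))
    dm_end[dead] <- .last_day_of_month(death_year[dead], death_month[dead])
  keep <- keep & (is.na(dm_end[pi]) | disp$dispense_date <= dm_end[pi])
  disp <- disp[keep, , drop = FALSE]

  disp$n_ddd <- round(disp$n_units / ifelse(disp$atc_code == "N06DA03", 2, 1), 1)
  disp$formulation <- ifelse(disp$atc_code == "N06DA03", "capsule", "tablet")
  disp <- disp[order(disp$patient_id, disp$dispense_date, disp$atc_code), ,
               drop = FALSE]
  rownames(disp) <- NULL

  list(
    patients = data.frame(patient_id = patient_id, sex = sex,
                          birth_year = birth_year,
                          death_year = death_year,
                          death_month = death_month),
    dispensings = disp,
    truth = data.frame(patient_id = patient_id, index_date = index_date,
                       index_year = init_year, age_at_index = age,
                       persistent = persistent, dropout_day = dropout_day)
  )
}

#' Target prevalence profiles for the synthetic general population
#'
#' Plausible general-population use prevalences of the studied drug groups
#' with the qualitative age and sex patterns seen in Nordic prescription
#' statistics: betablocker, verapamil and digitalis use rising steeply with
#' age; citalopram/escitalopram more prevalent in women; haloperidol rare
#' throughout.
#'
#' @return Named list mapping drug-group name to a data.frame with columns
#'   `age_lo`, `age_hi`, `male`, `female` (prevalence by age band and sex),
#'   usable as `target_prevalence` in [simulate_population_counts()].
#' @export
default_gp_prevalence <- function() {
  band <- function(age_lo, age_hi, male, female)
    data.frame(age_lo = age_lo, age_hi = age_hi, male = male, female = female)
  list(
    haloperidol = band(c(0, 65), c(64, 89), c(0.002, 0.005), c(0.002, 0.005)),
    citalopram_escitalopram = band(c(0, 50, 70), c(49, 69, 89),
                                   c(0.01, 0.03, 0.04),
                                   c(0.02, 0.055, 0.07)),
    verapamil = band(c(0, 50, 80), c(49, 79, 89),
                     c(0.001, 0.014, 0.022), c(0.001, 0.014, 0.024)),
    betablockers = band(c(0, 50, 70, 80), c(49, 69, 79, 89),
                        c(0.02, 0.18, 0.30, 0.38),
                        c(0.015, 0.15, 0.27, 0.33)),
    digitalis = band(c(0, 60, 80), c(59, 79, 89),
                     c(0.001, 0.025, 0.055), c(0.001, 0.020, 0.042)),
    `betablockers+citalopram_escitalopram` =
      band(c(0, 60, 80), c(59, 79, 89),
           c(0.001, 0.012, 0.018), c(0.001, 0.014, 0.024)),
    `verapamil+citalopram_escitalopram` =
      band(c(0, 60), c(59, 89), c(0.0002, 0.0008), c(0.0002, 0.001))
  )
}

# vectorized prevalence lookup for one group's target specification
.resolve_prev <- function(spec, age, sex) {
  if (is.data.frame(spec)) {
    out <- numeric(length(age))
    for (r in seq_len(nrow(spec))) {
      in_band <- age >= spec$age_lo[r] & age <= spec$age_hi[r]
      if (!is.null(spec$male)) {
        out[in_band & sex == "male"] <- spec$male[r]
        out[in_band & sex == "female"] <- spec$female[r]
      } else {
        out[in_band] <- spec$prev[r]
      }
    }
    out
  } else if (!is.null(names(spec)) && all(c("male", "female") %in% names(spec))) {
    unname(spec[sex])
  } else {
    rep(unname(spec[1]), length(age))
  }
}

#' Generate consistent aggregate general-population counts
#'
#' Builds the aggregate general-population reference table: users of each
#' drug group and population size by calendar year, 1-year age (0-89,
#' the registry's age resolution limit) and sex, with `users =
#' round(population * target_prevalence)` per cell.
#'
#' @param config a [sim_config()]; sets the calendar span and seed.
#' @param target_prevalence named list mapping drug-group name to a target
#'   prevalence specification: a single proportion, a named vector
#'   `c(male = , female = )`, or a data.frame of age bands (`age_lo`,
#'   `age_hi`, then `male`/`female` or `prev` columns). Default
#'   [default_gp_prevalence()].
#' @param population_per_cell population size of every year-age-sex cell
#'   (default 10000).
#' @return data.frame with columns `year`, `age`, `sex`, `drug_group`,
#'   `users`, `population`.
#' @export
simulate_population_counts <- function(config,
                                       target_prevalence = default_gp_prevalence(),
                                       population_per_cell = 10000) {
  stopifnot(inherits(config, "sim_config"))
  if (any(unlist(lapply(target_prevalence, function(s)
    if (is.data.frame(s)) unlist(s[setdiff(names(s), c("age_lo", "age_hi"))])
    else unname(unlist(s)))) > 1))
    stop("configuration error: target prevalence > 1")
  if (population_per_cell < 1)
    stop("configuration error: population_per_cell must be positive")

  grid <- expand.grid(
    year = config$calendar_span[1]:config$calendar_span[2],
    age = 0:89,
    sex = c("male", "female"),
    drug_group = names(target_prevalence),
    stringsAsFactors = FALSE)
  grid$population <- as.integer(population_per_cell)
  prev <- numeric(nrow(grid))
  for (g in names(target_prevalence)) {
    rows <- grid$drug_group == g
    prev[rows] <- .resolve_prev(target_prevalence[[g]],
                                grid$age[rows], grid$sex[rows])
  }
  if (any(prev < 0 | prev > 1))
    stop("configuration error: target prevalence outside [0, 1]")
  grid$users <- as.integer(round(grid$population * prev))
  grid[order(grid$drug_group, grid$sex, grid$year, grid$age),
       c("year", "age", "sex", "drug_group", "users", "population")]
}
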