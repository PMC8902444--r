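# Shared fixtures: hand-built dispensing streams and an independent
# day-walking implementation of the persistence rules.

DAY0 <- as.Date("2010-01-01")

# dispensing stream for one patient, dates as day offsets from DAY0
mk_rx <- function(days, units, atc = "N06DA02", origin = DAY0) {
  data.frame(date = origin + days,
             atc_code = rep_len(atc, length(days)),
             n_units = as.integer(rep_len(units, length(days))))
}

mk_period <- function(days, units, atc = "N06DA02", origin = DAY0) {
  use_period(mk_rx(days, units, atc, origin))
}

# random AChEI dispensing stream: mixed drugs, arbitrary refill pattern
random_stream <- function() {
  n <- sample(1:8, 1)
  days <- sort(sample(0:320, n))
  days[1] <- 0L
  mk_rx(days,
        units = sample(5:250, n, replace = TRUE),
        atc = sample(c("N06DA02", "N06DA03", "N06DA04"), n, replace = TRUE))
}

# Independent re-implementation of the three persistence rules built on
# day-by-day supply walking, never on classify_persistent() internals.
oracle_classify <- function(period, supply_days = 210, horizon_days = 240) {
  rx <- period$prescriptions
  day <- as.integer(rx$date - period$start_date)
  rate <- ifelse(startsWith(rx$atc_code, "N06DA03"), 2, 1)

  # days a dispensing lasts, counted one day at a time
  walk_days <- function(units, r) {
    d <- 0L
    consumed <- 0
    while (consumed < units) {
      consumed <- consumed + r
      d <- d + 1L
    }
    d
  }

  rule1 <- any(day >= supply_days & day <= horizon_days)

  early <- which(day < supply_days)
  rule2 <- sum(vapply(early, function(i)
    walk_days(rx$n_units[i], rate[i]), integer(1))) >= supply_days

  rule3 <- FALSE
  if (length(early)) {
    i <- early[which.max(day[early])]
    solo <- use_period(rx[i, , drop = FALSE])
    # coverage array indexed from the solo dispensing's own date
    cov <- supply_coverage(solo, horizon_days = supply_days - day[i] + 1L)
    rule3 <- cov[supply_days - day[i] + 1L] >= 1L
  }

  rule <- if (rule1) 1L else if (rule2) 2L else if (rule3) 3L else NA_integer_
  list(persistent = !is.na(rule), rule = rule)
}

# tiny registry: one hand-built patient with a guaranteed-persistent index
# stream (rule 2) starting at `index`, plus a background dispensing in the
# second year after index for registry presence
mk_patient_registry <- function(pid = "P1", sex = "female",
                                birth_year = 1935,
                                death_year = NA, death_month = NA,
                                index = as.Date("2010-06-15"),
                                persistent = TRUE,
                                present_y2 = TRUE) {
  achei_days <- if (persistent) c(0, 90, 180) else 0
  achei_units <- if (persistent) 100L else 60L
  disp <- data.frame(
    patient_id = pid,
    dispense_date = index + achei_days,
    atc_code = "N06DA02",
    n_units = achei_units)
  if (present_y2)
    disp <- rbind(disp, data.frame(patient_id = pid,
                                   dispense_date = index + 400,
                                   atc_code = "N02BE01", n_units = 100L))
  patients <- data.frame(patient_id = pid, sex = sex,
                         birth_year = birth_year,
                         death_year = death_year,
                         death_month = death_month)
  list(patients = patients, dispensings = disp)
}

merge_registries <- function(...) {
  regs <- list(...)
  list(patients = do.call(rbind, lapply(regs, `[[`, "patients")),
       dispensings = do.call(rbind, lapply(regs, `[[`, "dispensings")))
}

# small shared synthetic registry for property-style tests
small_registry <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_registry(sim_config(n_patients = 800, seed = 202))
    cache
  }
})
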