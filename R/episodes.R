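#' Daily consumption rate table
#'
#' Units assumed consumed per day for each drug, used to convert a dispensed
#' unit count into days of supply. The default encodes the standard
#' assumption for the AChEIs: two units per day for rivastigmine (ATC
#' N06DA03, dosed twice daily) and one unit per day for every other drug.
#'
#' Lookup is by longest matching ATC prefix, so a rate can be set for a full
#' 7-character code or for a therapeutic group prefix.
#'
#' @param rates named numeric vector mapping ATC codes (or prefixes) to
#'   units consumed per day; all rates must be positive.
#' @param default rate used for codes not matched by `rates`.
#' @return An object of class `daily_rate_table`.
#' @examples
#' rt <- daily_rate_table()
#' daily_rate(rt, "N06DA03")  # rivastigmine: 2 units/day
#' daily_rate(rt, "N06DA02")  # donepezil: 1 unit/day
#' @export
daily_rate_table <- function(rates = c(N06DA03 = 2), default = 1) {
  rates <- unlist(rates)
  if (length(rates) && (is.null(names(rates)) || any(!nzchar(names(rates)))))
    stop("'rates' must be a named vector of ATC codes/prefixes")
  if (any(rates <= 0) || default <= 0)
    stop("all daily rates must be > 0")
  structure(list(rates = rates, default = default),
            class = "daily_rate_table")
}

#' @rdname daily_rate_table
#' @param table a `daily_rate_table`.
#' @param atc_code character vector of ATC codes.
#' @return `daily_rate()`: numeric vector of units/day, one per code.
#' @export
daily_rate <- function(table, atc_code) {
  stopifnot(inherits(table, "daily_rate_table"))
  out <- rep(table$default, length(atc_code))
  if (length(table$rates)) {
    prefixes <- names(table$rates)
    # longest prefix wins so a full-code entry overrides a group entry
    for (p in prefixes[order(nchar(prefixes))]) {
      hit <- startsWith(atc_code, p)
      out[hit] <- table$rates[[p]]
    }
  }
  out
}

#' Days of supply of a dispensing
#'
#' A dispensing of `n_units` units of a drug consumed at `rate` units/day
#' supplies `ceiling(n_units / rate)` days: a partial final day counts as a
#' treated day, matching the convention that supply lasts until the day the
#' dispensed drug was supposed to be consumed.
#'
#' @param n_units integer vector of dispensed unit counts.
#' @param rate numeric vector of units consumed per day.
#' @return Integer vector of days of supply.
#' @export
days_of_supply <- function(n_units, rate) {
  as.integer(ceiling(n_units / rate))
}

#' Construct a use period
#'
#' A use period is a maximal run of dispensings of one drug class with
#' bounded inter-dispensing gaps, extended past the last dispensing by that
#' dispensing's days of supply.
#'
#' @param prescriptions data.frame with columns `date` (Date), `atc_code`
#'   (character) and `n_units` (integer), sorted by date.
#' @param rates a [daily_rate_table()].
#' @return An object of class `use_period`: a list with `start_date`,
#'   `end_date` (last date through which supply from the final dispensing
#'   runs), `n_prescriptions` and the `prescriptions` themselves.
#' @export
use_period <- function(prescriptions, rates = daily_rate_table()) {
  stopifnot(nrow(prescriptions) >= 1)
  last <- nrow(prescriptions)
  supply <- days_of_supply(prescriptions$n_units[last],
                           daily_rate(rates, prescriptions$atc_code[last]))
  structure(list(
    start_date = prescriptions$date[1],
    end_date = prescriptions$date[last] + supply - 1L,
    n_prescriptions = last,
    prescriptions = prescriptions
  ), class = "use_period")
}

#' @export
print.use_period <- function(x, ...) {
  cat(sprintf("Use period: %s to %s (%d prescription%s, %d days)\n",
              format(x$start_date), format(x$end_date), x$n_prescriptions,
              if (x$n_prescriptions == 1) "" else "s", treatment_length(x)))
  invisible(x)
}

#' Partition a dispensing stream into use periods
#'
#' Splits one patient's AChEI dispensing stream into maximal runs in which
#' consecutive dispensings are at most `gap_days` apart; a gap of more than
#' `gap_days` (the washout criterion for incident use) starts a new period.
#' A gap of exactly `gap_days` keeps the run together.
#'
#' @param records data.frame with columns `date` (Date), `atc_code`,
#'   `n_units`, sorted by `date` (an error is raised otherwise).
#' @param gap_days maximum allowed gap, in days, within a period
#'   (default 365).
#' @param rates a [daily_rate_table()].
#' @return List of [use_period()] objects in chronological order; an empty
#'   list for empty input.
#' @examples
#' recs <- data.frame(date = as.Date("2010-01-01") + c(0, 366),
#'                    atc_code = "N06DA02", n_units = 98L)
#' length(build_use_periods(recs))  # gap 366 > 365: two periods
#' @export
build_use_periods <- function(records, gap_days = 365,
                              rates = daily_rate_table()) {
  if (is.null(records) || nrow(records) == 0) return(list())
  if (is.unsorted(as.numeric(records$date)))
    stop("dispensing records must be sorted by date")
  gaps <- diff(as.numeric(records$date))
  period_id <- cumsum(c(1L, as.integer(gaps > gap_days)))
  lapply(split(records, period_id), use_period, rates = rates)
}

#' Select the index use period
#'
#' The index period is the one that initiates follow-up: the period with the
#' largest number of prescriptions. Ties are broken by longer duration
#' (end minus start), then by earlier start date, reconciling "most
#' prescriptions" with "longest period" when the two descriptions disagree.
#'
#' @param periods non-empty list of [use_period()] objects.
#' @return The selected `use_period`; its `start_date` is the index date.
#' @export
select_index_period <- function(periods) {
  if (length(periods) == 0) stop("no use periods to select from")
  n <- vapply(periods, function(p) p$n_prescriptions, integer(1))
  dur <- vapply(periods, function(p)
    as.numeric(p$end_date - p$start_date), numeric(1))
  start <- vapply(periods, function(p) as.numeric(p$start_date), numeric(1))
  periods[[order(-n, -dur, start)[1]]]
}

#' Treatment length of a use period
#'
#' Number of days from the period's first dispensing (the index date, day 0)
#' through the day the final dispensing's supply was supposed to be
#' consumed, inclusive.
#'
#' @param period a [use_period()].
#' @return Integer number of days.
#' @export
treatment_length <- function(period) {
  stopifnot(inherits(period, "use_period"))
  as.integer(period$end_date - period$start_date) + 1L
}

#' Classify persistence of an incident user
#'
#' An incident user is persistent if treatment demonstrably continues to the
#' persistence horizon (default 240 days, i.e. 8 months) after the index
#' date, by any of three refill-pattern rules:
#' \enumerate{
#'   \item a new prescription is dispensed between day 210 and day 240
#'     after initiation (both ends inclusive);
#'   \item drug for at least 210 days of consumption is dispensed during the
#'     first 210 days (days 0-209) from initiation;
#'   \item the last prescription dispensed before day 210 has supply lasting
#'     to day 210 or beyond.
#' }
#' Day 0 is the index date. A dispensing dated exactly day 210 counts
#' towards rule 1, not rule 2 or 3, so no dispensing is double counted
#' across the day-210 boundary.
#'
#' @param index_period the index [use_period()]; day 0 is its start date.
#' @param horizon_days persistence horizon; the upper end of the rule-1
#'   refill window (default 240).
#' @param supply_days day threshold for rules 2 and 3 (default 210).
#' @param rates a [daily_rate_table()].
#' @return List with `persistent` (logical) and `rule` (integer 1, 2 or 3:
#'   the lowest-numbered rule that fired, or `NA` if none).
#' @examples
#' p <- use_period(data.frame(date = as.Date("2010-01-01"),
#'                            atc_code = "N06DA02", n_units = 210L))
#' classify_persistent(p)  # persistent by rule 2
#' @export
classify_persistent <- function(index_period, horizon_days = 240,
                                supply_days = 210,
                                rates = daily_rate_table()) {
  stopifnot(inherits(index_period, "use_period"))
  rx <- index_period$prescriptions
  day <- as.integer(rx$date - index_period$start_date)
  supply <- days_of_supply(rx$n_units, daily_rate(rates, rx$atc_code))

  rule1 <- any(day >= supply_days & day <= horizon_days)
  early <- day < supply_days
  rule2 <- sum(supply[early]) >= supply_days
  rule3 <- if (any(early)) {
    i <- which(early)[which.max(day[early])]
    day[i] + supply[i] - 1L >= supply_days
  } else FALSE

  rule <- if (rule1) 1L else if (rule2) 2L else if (rule3) 3L else NA_integer_
  list(persistent = !is.na(rule), rule = rule)
}

#' Day-by-day supply coverage of a use period
#'
#' Brute-force daily bookkeeping of drug supply, intended as an independent
#' check on the refill-pattern rules. Day 0 is the period's start date.
#'
#' In the default (no-stockpiling) mode each dispensing's supply occupies
#' the consecutive days starting on its own dispensing date, and the value
#' for a day is the number of dispensings whose supply covers it (overlaps
#' are visible, not summed forward). In stockpiling mode unconsumed supply
#' carries over: dispensings are consumed in order at one ration per day
#' from the first dispensing, and the value for a day is 1 while the pooled
#' supply lasts.
#'
#' @param index_period a [use_period()].
#' @param horizon_days length of the returned array.
#' @param stockpile logical; carry unconsumed supply forward (default
#'   `FALSE`).
#' @param rates a [daily_rate_table()].
#' @return Integer vector of length `horizon_days`; element `d + 1` is the
#'   supply covering day `d`.
#' @export
supply_coverage <- function(index_period, horizon_days = 240,
                            stockpile = FALSE,
                            rates = daily_rate_table()) {
  stopifnot(inherits(index_period, "use_period"), horizon_days >= 1)
  rx <- index_period$prescriptions
  cov <- integer(horizon_days)
  if (is.null(rx) || nrow(rx) == 0) return(cov)
  day <- as.integer(rx$date - index_period$start_date)
  supply <- days_of_supply(rx$n_units, daily_rate(rates, rx$atc_code))

  if (!stockpile) {
    for (i in seq_along(day)) {
      d <- day[i]
      while (d < day[i] + supply[i] && d < horizon_days) {
        if (d >= 0) cov[d + 1L] <- cov[d + 1L] + 1L
        d <- d + 1L
      }
    }
  } else {
    pool <- 0L
    d <- day[1]
    repeat {
      pool <- pool + sum(supply[day == d])
      if (pool > 0L) {
        if (d >= 0 && d < horizon_days) cov[d + 1L] <- 1L
        pool <- pool - 1L
      } else if (any(day > d)) {
        d <- min(day[day > d]) - 1L  # jump to the next dispensing
      } else break
      d <- d + 1L
      if (d >= horizon_days && !any(day >= d)) break
    }
  }
  cov
}
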