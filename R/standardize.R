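#' Window-to-shift mapping for general-population comparison
#'
#' The cohort is followed over six years around its index date, but the
#' general population (GP) cannot be followed longitudinally; instead, when
#' comparing window X years before/after initiation, the GP dispensing
#' years and ages are shifted by X years. Windows -4..-1 shift by -4..-1;
#' the first post-index window (+1) shifts by 0 — the first year after
#' initiation is the initiation year itself — and window +2 shifts by +1.
#'
#' @param window window ordinal in `c(-4, -3, -2, -1, 1, 2)`.
#' @return Integer shift in years.
#' @export
shift_for_window <- function(window) {
  stopifnot(all(window %in% c(-4L, -3L, -2L, -1L, 1L, 2L)))
  ifelse(window < 0, window, window - 1L)
}

#' General-population comparison cells for a window
#'
#' The exact set of (calendar year, age) general-population cells a cohort
#' stratum is compared against in a given follow-up window. For reference
#' ages 81-88 and initiation years 2008-2013, window -4 yields ages 77-84
#' in years 2004-2009 and window +2 yields ages 82-89 in years 2009-2014.
#'
#' @param window window ordinal.
#' @param ref_ages integer vector of cohort ages at index.
#' @param init_years initiation (index) years, default 2008-2013.
#' @return data.frame with columns `year` and `age`, one row per cell.
#' @export
gp_comparison_cells <- function(window, ref_ages, init_years = 2008:2013) {
  shift <- shift_for_window(window)
  cells <- expand.grid(year = sort(unique(init_years)) + shift,
                       age = sort(unique(ref_ages)) + shift)
  cells[order(cells$year, cells$age), , drop = FALSE]
}

#' Cohort age distribution used as standardization reference
#'
#' Counts of cohort members by initiation year and 1-year age at index,
#' the reference weights for direct age standardization of the general
#' population ("the actual year as reference"). Compute it on a subset of
#' members (one sex, one age group) to standardize for that stratum.
#'
#' @param members cohort data.frame with columns `index_year` and
#'   `age_at_index`.
#' @return data.frame with columns `init_year`, `age`, `weight` (counts).
#' @export
cohort_age_distribution <- function(members) {
  if (nrow(members) == 0)
    return(data.frame(init_year = integer(), age = integer(),
                      weight = integer()))
  out <- stats::aggregate(
    list(weight = members$patient_id),
    list(init_year = members$index_year, age = members$age_at_index),
    FUN = length)
  out[order(out$init_year, out$age), , drop = FALSE]
}

#' Age-adjusted user and population numbers for one initiation year
#'
#' Direct age standardization of one year of general-population data to a
#' reference age distribution, with the year/age shift applied: the
#' age-adjusted number of users is `u_y = sum_a w(a) * rate(year + shift,
#' a + shift, sex, group)` and the reference population is `N_y =
#' sum_a w(a)`, with the reference weights `w` expressed as counts.
#' Reference ages whose shifted age falls outside the 0-89 range covered by
#' the population table are dropped from both sums (a renormalization),
#' with a warning.
#'
#' @param pop population counts data.frame with columns `year`, `age`,
#'   `sex`, `drug_group`, `users`, `population`.
#' @param ref reference age distribution: data.frame with columns `age`
#'   and `weight` (non-negative, positive sum).
#' @param year initiation year being standardized.
#' @param shift year/age shift (see [shift_for_window()]).
#' @param sex `"male"` or `"female"`.
#' @param group drug-group name as it appears in `pop$drug_group`.
#' @return List with `u` (age-adjusted users), `n` (reference population)
#'   and `cells` (the (year, age) GP cells used).
#' @export
age_adjust_one_year <- function(pop, ref, year, shift, sex, group) {
  stopifnot(all(ref$weight >= 0), sum(ref$weight) > 0)
  gp_year <- year + shift
  sub <- pop[pop$year == gp_year & pop$sex == sex &
               pop$drug_group == group, , drop = FALSE]
  if (nrow(sub) == 0)
    stop(sprintf("population table has no year %d (sex %s, group %s)",
                 gp_year, sex, group))
  gp_age <- ref$age + shift
  i <- match(gp_age, sub$age)
  if (anyNA(i)) {
    dropped <- ref$age[is.na(i)]
    warning(sprintf(
      "dropping %d reference age(s) (%s) with shifted age outside the population table; weights renormalized",
      length(dropped), paste(dropped, collapse = ", ")))
    ref <- ref[!is.na(i), , drop = FALSE]
    gp_age <- gp_age[!is.na(i)]
    i <- i[!is.na(i)]
    if (nrow(ref) == 0) stop("no reference ages left after shifting")
  }
  rate <- sub$users[i] / sub$population[i]
  list(u = sum(ref$weight * rate),
       n = sum(ref$weight),
       cells = data.frame(year = gp_year, age = gp_age))
}

#' Age-adjusted general-population prevalence for a follow-up window
#'
#' Aggregates [age_adjust_one_year()] over the initiation years: the
#' adjusted prevalence is `sum_y u_y / sum_y N_y`, where `u_y` and `N_y`
#' are the age-adjusted number of users and the reference population for
#' initiation year `y`, and each year uses the age distribution of that
#' year's initiators as reference.
#'
#' @inheritParams age_adjust_one_year
#' @param ref_by_year data.frame with columns `init_year`, `age`, `weight`
#'   (see [cohort_age_distribution()]).
#' @param window follow-up window ordinal; sets the shift via
#'   [shift_for_window()].
#' @param init_years initiation years to aggregate over (default
#'   2008-2013).
#' @return Object of class `adjusted_prevalence`: list with `value` (the
#'   adjusted proportion), `sex`, `window`, `drug_group` and `components`
#'   (per-year `u_y`, `N_y`).
#' @export
adjusted_prevalence <- function(pop, ref_by_year, window, sex, group,
                                init_years = 2008:2013) {
  shift <- shift_for_window(window)
  comp <- lapply(init_years, function(y) {
    ref <- ref_by_year[ref_by_year$init_year == y, c("age", "weight")]
    if (nrow(ref) == 0 || sum(ref$weight) == 0) return(NULL)
    adj <- age_adjust_one_year(pop, ref, y, shift, sex, group)
    data.frame(init_year = y, u = adj$u, n = adj$n)
  })
  comp <- do.call(rbind, comp)
  if (is.null(comp)) stop("no reference weights for any initiation year")
  structure(list(
    value = sum(comp$u) / sum(comp$n),
    sex = sex, window = window, drug_group = group,
    components = comp
  ), class = "adjusted_prevalence")
}

#' @export
print.adjusted_prevalence <- function(x, ...) {
  cat(sprintf(
    "Age-adjusted GP prevalence of %s, window %+d, %s: %.4f\n",
    x$drug_group, x$window, x$sex, x$value))
  invisible(x)
}

#' Prevalence ratio study population vs general population
#'
#' @param sp_proportion prevalence in the study population (cohort cell
#'   proportion).
#' @param gp_value age-adjusted general-population prevalence (an
#'   [adjusted_prevalence()] object or its numeric value).
#' @return Numeric ratio `sp / gp`; `NA` (missing) where the GP prevalence
#'   is zero, in which case the ratio is undefined.
#' @export
prevalence_ratio <- function(sp_proportion, gp_value) {
  if (inherits(gp_value, "adjusted_prevalence")) gp_value <- gp_value$value
  ifelse(gp_value > 0, sp_proportion / gp_value, NA_real_)
}
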