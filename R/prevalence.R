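#' Follow-up windows around the index date
#'
#' Six consecutive 365-day windows partitioning the follow-up interval from
#' 1,460 days (4 years) before the index date to 729 days (2 years) after
#' it. Day 0 is the index date; window ordinals are -4, -3, -2, -1 (years
#' before initiation) and +1, +2 (years after). Windows are fixed 365-day
#' day-count offsets; leap days are ignored.
#'
#' @return data.frame with columns `window` (ordinal), `day_start`,
#'   `day_end` (inclusive day offsets relative to index).
#' @export
follow_up_windows <- function() {
  data.frame(
    window = c(-4L, -3L, -2L, -1L, 1L, 2L),
    day_start = c(-1460L, -1095L, -730L, -365L, 0L, 365L),
    day_end = c(-1096L, -731L, -366L, -1L, 364L, 729L)
  )
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param n_users number of successes (vectorised).
#' @param n_total number of trials; must be at least 1.
#' @param conf_level confidence level (default 0.95).
#' @return data.frame with columns `low` and `high`, clipped to \[0, 1\].
#'   The lower bound is exactly 0 when `n_users == 0` and the upper bound
#'   exactly 1 when `n_users == n_total`.
#' @examples
#' wilson_ci(50, 100)  # (0.4038, 0.5962)
#' @export
wilson_ci <- function(n_users, n_total, conf_level = 0.95) {
  if (any(n_total < 1)) stop("n_total must be >= 1")
  if (any(n_users < 0) || any(n_users > n_total))
    stop("n_users must be in [0, n_total]")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  x <- n_users
  n <- n_total
  centre <- (x + z^2 / 2) / (n + z^2)
  half <- z * sqrt(x * (n - x) / n + z^2 / 4) / (n + z^2)
  low <- pmax(0, centre - half)
  high <- pmin(1, centre + half)
  low[x == 0] <- 0
  high[x == n] <- 1
  data.frame(low = low, high = high)
}

# Day offset of each dispensing relative to its patient's index date, with
# the window it falls in (NA outside follow-up). Only member dispensings kept.
.member_dispensing_windows <- function(members, dispensings,
                                       windows = follow_up_windows()) {
  idx <- match(dispensings$patient_id, members$patient_id)
  keep <- !is.na(idx)
  d <- dispensings[keep, , drop = FALSE]
  day <- as.integer(d$dispense_date - members$index_date[idx[keep]])
  breaks <- c(windows$day_start, windows$day_end[nrow(windows)] + 1L)
  w <- findInterval(day, breaks)
  w[w < 1L | w > nrow(windows)] <- NA_integer_
  data.frame(patient_id = d$patient_id, atc_code = d$atc_code,
             day = day, window = windows$window[w])
}

# Unique (patient, window) pairs with >=1 dispensing matching `group`.
.patient_window_hits <- function(members, dispensings, group, windows) {
  dw <- .member_dispensing_windows(members, dispensings, windows)
  dw <- dw[!is.na(dw$window) & match_group(dw$atc_code, group), , drop = FALSE]
  unique(dw[c("patient_id", "window")])
}

# Turn unique (patient, window) hits into prevalence cells by stratum.
.cells_from_hits <- function(hits, members, windows, by, group_name,
                             conf_level, suppress_below) {
  strata <- unique(members[by])
  grid <- merge(strata, data.frame(window = windows$window))
  totals <- stats::aggregate(list(n_total = members$patient_id),
                             members[by], FUN = length)
  grid <- merge(grid, totals, by = by)

  hits <- merge(hits, members[c("patient_id", by)], by = "patient_id")
  if (nrow(hits)) {
    counts <- stats::aggregate(list(n_users = hits$patient_id),
                               hits[c("window", by)], FUN = length)
    grid <- merge(grid, counts, by = c("window", by), all.x = TRUE)
    grid$n_users[is.na(grid$n_users)] <- 0L
  } else {
    grid$n_users <- 0L
  }
  grid$proportion <- grid$n_users / grid$n_total
  ci <- wilson_ci(grid$n_users, grid$n_total, conf_level)
  grid$ci_low <- ci$low
  grid$ci_high <- ci$high
  grid$suppressed <- grid$n_users < suppress_below
  grid <- cbind(drug_group = group_name, grid)
  grid[order(grid$window, do.call(paste, grid[by])), , drop = FALSE]
}

#' Windowed prevalence of a drug group in the cohort
#'
#' For each follow-up window and stratum, the proportion of cohort members
#' who filled at least one prescription matching the drug group within the
#' window, with a Wilson confidence interval and a small-cell suppression
#' flag. The cohort is fixed (a persistent-survivor design), so `n_total`
#' is constant across windows within a stratum. Suppression (`n_users`
#' below the threshold, default 5) flags cells for display only; counts and
#' proportions are always computed.
#'
#' @param members cohort data.frame from [select_cohort()] (columns
#'   `patient_id`, `index_date` and the stratifiers in `by`).
#' @param dispensings dispensing records data.frame (columns `patient_id`,
#'   `dispense_date`, `atc_code`).
#' @param group a [drug_group()].
#' @param windows window table, default [follow_up_windows()].
#' @param by stratifier column names (default sex and age group).
#' @param conf_level Wilson CI confidence level.
#' @param suppress_below suppression threshold on the user count.
#' @return data.frame of prevalence cells: `drug_group`, `window`, the
#'   `by` columns, `n_users`, `n_total`, `proportion`, `ci_low`, `ci_high`,
#'   `suppressed`.
#' @export
window_prevalence <- function(members, dispensings, group,
                              windows = follow_up_windows(),
                              by = c("sex", "age_group"),
                              conf_level = 0.95, suppress_below = 5) {
  hits <- .patient_window_hits(members, dispensings, group, windows)
  .cells_from_hits(hits, members, windows, by, group$name,
                   conf_level, suppress_below)
}

#' Windowed prevalence of concomitant use of two drug groups
#'
#' A member counts as a concomitant user in a window when they filled at
#' least one prescription of each group within that same 365-day window;
#' no overlap of supply is required.
#'
#' @inheritParams window_prevalence
#' @param group_a,group_b the two [drug_group()]s.
#' @return data.frame of prevalence cells as in [window_prevalence()], with
#'   `drug_group` set to `"<a>+<b>"`.
#' @export
combination_prevalence <- function(members, dispensings, group_a, group_b,
                                   windows = follow_up_windows(),
                                   by = c("sex", "age_group"),
                                   conf_level = 0.95, suppress_below = 5) {
  ha <- .patient_window_hits(members, dispensings, group_a, windows)
  hb <- .patient_window_hits(members, dispensings, group_b, windows)
  hits <- merge(ha, hb, by = c("patient_id", "window"))
  .cells_from_hits(hits, members, windows, by,
                   paste(group_a$name, group_b$name, sep = "+"),
                   conf_level, suppress_below)
}

#' Windowed prevalence of use of any of several drug groups
#'
#' A member counts as a user in a window when they filled at least one
#' prescription matching the union of the groups' ATC prefixes.
#'
#' @inheritParams window_prevalence
#' @param groups list of [drug_group()]s.
#' @param name label for the union group in the output (default
#'   `"any_of_<k>_groups"`).
#' @return data.frame of prevalence cells as in [window_prevalence()].
#' @export
any_of_groups_prevalence <- function(members, dispensings, groups,
                                     windows = follow_up_windows(),
                                     by = c("sex", "age_group"),
                                     conf_level = 0.95, suppress_below = 5,
                                     name = NULL) {
  union_group <- drug_group(
    name %||% sprintf("any_of_%d_groups", length(groups)),
    unlist(lapply(groups, `[[`, "prefixes"))
  )
  window_prevalence(members, dispensings, union_group, windows, by,
                    conf_level, suppress_below)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
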