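#' Run the full AChEI co-medication utilization study
#'
#' The package's central analysis. From a dispensing registry (and
#' optionally an aggregate general-population table) it
#' \enumerate{
#'   \item selects the cohort of persistent incident AChEI users
#'     ([select_cohort()]);
#'   \item computes windowed prevalence of each co-medication group and
#'     each concomitant-use pair, by sex and age group, with Wilson CIs
#'     and small-cell suppression ([window_prevalence()],
#'     [combination_prevalence()]);
#'   \item computes the prevalence of use of at least one of the single
#'     groups, by sex ([any_of_groups_prevalence()]);
#'   \item if a population table is supplied, computes the year-shifted
#'     age-adjusted general-population prevalence for every group present
#'     in the table ([adjusted_prevalence()]) and the study/general
#'     population prevalence ratios ([prevalence_ratio()]), merged into a
#'     single report table.
#' }
#'
#' @param patients,dispensings registry tables, see [select_cohort()].
#' @param population optional general-population counts table
#'   (`year`, `age`, `sex`, `drug_group`, `users`, `population`).
#' @param groups named list of [drug_group()]s
#'   (default [default_drug_groups()]).
#' @param combinations list of two-element lists of [drug_group()]s
#'   (default [default_combinations()]).
#' @param index_window inclusion window for index dates; also sets the
#'   initiation years the standardization aggregates over.
#' @param conf_level Wilson CI confidence level.
#' @param suppress_below small-cell suppression threshold.
#' @param ... further arguments passed to [select_cohort()] (`age_cap`,
#'   `age_break`, `gap_days`, `horizon_days`, `supply_days`, `rates`,
#'   `data_start`, `registry_window`).
#' @return Object of class `achei_study` with elements `cohort`
#'   (members + exclusion log), `cohort_summary`, `prevalence`,
#'   `combinations`, `any_of_groups` (each a cell table), `gp`
#'   (age-adjusted general-population prevalence, or `NULL`), `report`
#'   (merged study-vs-GP table with prevalence ratios, or `NULL`) and
#'   `params`.
#' @examples
#' reg <- simulate_registry(sim_config(n_patients = 300, seed = 42))
#' pop <- simulate_population_counts(sim_config(seed = 42))
#' fit <- achei_study(reg$patients, reg$dispensings, pop)
#' print(fit)
#' @export
achei_study <- function(patients, dispensings, population = NULL,
                        groups = default_drug_groups(),
                        combinations = default_combinations(),
                        index_window = as.Date(c("2008-01-01",
                                                 "2013-12-31")),
                        conf_level = 0.95, suppress_below = 5, ...) {
  cohort <- select_cohort(patients, dispensings,
                          index_window = index_window, ...)
  members <- cohort$members
  windows <- follow_up_windows()
  init_years <- as.integer(format(index_window[1], "%Y")):
    as.integer(format(index_window[2], "%Y"))

  if (nrow(members) == 0) {
    warning("empty cohort: no persistent incident users passed the cascade")
    return(structure(list(cohort = cohort,
                          cohort_summary = summarize_cohort(members),
                          prevalence = NULL, combinations = NULL,
                          any_of_groups = NULL, gp = NULL, report = NULL,
                          params = list(index_window = index_window,
                                        conf_level = conf_level,
                                        suppress_below = suppress_below)),
                     class = "achei_study"))
  }

  prev <- do.call(rbind, lapply(groups, function(g)
    window_prevalence(members, dispensings, g, windows,
                      conf_level = conf_level,
                      suppress_below = suppress_below)))
  rownames(prev) <- NULL

  comb <- do.call(rbind, lapply(combinations, function(pair)
    combination_prevalence(members, dispensings, pair[[1]], pair[[2]],
                           windows, conf_level = conf_level,
                           suppress_below = suppress_below)))
  rownames(comb) <- NULL

  any_of <- any_of_groups_prevalence(members, dispensings, groups,
                                     windows, by = "sex",
                                     conf_level = conf_level,
                                     suppress_below = suppress_below)

  gp <- NULL
  report <- NULL
  if (!is.null(population)) {
    gp <- gp_adjusted_table(population, members,
                            group_names = intersect(
                              unique(c(prev$drug_group, comb$drug_group)),
                              unique(population$drug_group)),
                            windows = windows, init_years = init_years)
    sp <- rbind(prev, comb)
    report <- merge(sp, gp,
                    by = c("drug_group", "window", "sex", "age_group"),
                    all.x = TRUE)
    names(report)[names(report) == "proportion"] <- "prop_sp"
    report$ratio <- prevalence_ratio(report$prop_sp, report$prop_gp)
    report <- report[order(report$drug_group, report$window, report$sex,
                           report$age_group), , drop = FALSE]
    rownames(report) <- NULL
  }

  structure(list(cohort = cohort,
                 cohort_summary = summarize_cohort(members),
                 prevalence = prev, combinations = comb,
                 any_of_groups = any_of, gp = gp, report = report,
                 params = list(index_window = index_window,
                               conf_level = conf_level,
                               suppress_below = suppress_below,
                               groups = names(groups))),
            class = "achei_study")
}

#' Age-adjusted general-population prevalence table
#'
#' Applies the year-shifted direct age standardization stratum by stratum:
#' for each sex and age group the reference weights are the cohort's
#' initiators of that stratum, counted by initiation year and 1-year age.
#'
#' @param population general-population counts table.
#' @param members cohort members data.frame.
#' @param group_names drug-group names (as in `population$drug_group`).
#' @param windows window table.
#' @param init_years initiation years aggregated over.
#' @return data.frame with columns `drug_group`, `window`, `sex`,
#'   `age_group`, `prop_gp`.
#' @export
gp_adjusted_table <- function(population, members, group_names,
                              windows = follow_up_windows(),
                              init_years = 2008:2013) {
  strata <- unique(members[c("sex", "age_group")])
  rows <- list()
  for (s in seq_len(nrow(strata))) {
    sub <- members[members$sex == strata$sex[s] &
                     members$age_group == strata$age_group[s], ,
                   drop = FALSE]
    ref <- cohort_age_distribution(sub)
    for (g in group_names) for (w in windows$window) {
      ap <- adjusted_prevalence(population, ref, w, strata$sex[s], g,
                                init_years)
      rows[[length(rows) + 1L]] <- data.frame(
        drug_group = g, window = w, sex = strata$sex[s],
        age_group = strata$age_group[s], prop_gp = ap$value)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.achei_study <- function(x, ...) {
  cs <- x$cohort_summary
  cat("AChEI co-medication utilization study\n")
  cat(sprintf("  cohort: %d persistent incident users (%s women)\n",
              nrow(x$cohort$members),
              if (nrow(cs)) sprintf("%.0f%%", cs$pct_female[cs$age_group == "all"])
              else "-"))
  cat(sprintf("  excluded candidates: %d\n", nrow(x$cohort$exclusions)))
  if (!is.null(x$prevalence))
    cat(sprintf("  prevalence cells: %d (%s)\n", nrow(x$prevalence),
                paste(unique(x$prevalence$drug_group), collapse = ", ")))
  if (!is.null(x$report))
    cat(sprintf("  report: %d rows with GP comparison and prevalence ratios\n",
                nrow(x$report)))
  invisible(x)
}

#' @export
summary.achei_study <- function(object, ...) {
  structure(list(cohort_summary = object$cohort_summary,
                 exclusions = if (nrow(object$cohort$exclusions))
                   as.data.frame(table(reason = object$cohort$exclusions$reason),
                                 responseName = "n")
                 else NULL,
                 year2 = if (!is.null(object$prevalence))
                   object$prevalence[object$prevalence$window == 2L, ,
                                     drop = FALSE]
                 else NULL,
                 any_of_year2 = if (!is.null(object$any_of_groups))
                   object$any_of_groups[object$any_of_groups$window == 2L, ,
                                        drop = FALSE]
                 else NULL),
            class = "summary.achei_study")
}

#' @export
print.summary.achei_study <- function(x, ...) {
  cat("Cohort composition:\n")
  print(x$cohort_summary, row.names = FALSE, digits = 3)
  if (!is.null(x$exclusions)) {
    cat("\nExclusions:\n")
    print(x$exclusions, row.names = FALSE)
  }
  if (!is.null(x$year2)) {
    cat("\nPrevalence in the second year after initiation:\n")
    y2 <- x$year2
    y2$proportion <- sprintf("%.1f%%", 100 * y2$proportion)
    print(y2[c("drug_group", "sex", "age_group", "n_users", "n_total",
               "proportion", "suppressed")], row.names = FALSE)
  }
  if (!is.null(x$any_of_year2)) {
    cat("\nAny studied group, second year after initiation:\n")
    a2 <- x$any_of_year2
    a2$proportion <- sprintf("%.1f%%", 100 * a2$proportion)
    print(a2[c("sex", "n_users", "n_total", "proportion")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Plot windowed prevalence for one drug group
#'
#' Proportion of users versus follow-up window, one panel per sex, with
#' Wilson confidence bars for the study population (open circles) and the
#' age-adjusted general-population prevalence (filled bullets, when
#' available). Cells suppressed for small counts are not drawn.
#'
#' @param x an `achei_study`.
#' @param group drug-group name to plot (default: first group).
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.achei_study <- function(x, group = NULL, ...) {
  stopifnot(!is.null(x$prevalence))
  cells <- rbind(x$prevalence, x$combinations)
  group <- group %||% cells$drug_group[1]
  cells <- cells[cells$drug_group == group, , drop = FALSE]
  if (nrow(cells) == 0) stop("no prevalence cells for group ", group)
  gp <- if (!is.null(x$gp))
    x$gp[x$gp$drug_group == group, , drop = FALSE] else NULL

  sexes <- sort(unique(cells$sex))
  old <- graphics::par(mfrow = c(1, length(sexes)))
  on.exit(graphics::par(old))
  ylim <- c(0, max(cells$ci_high[!cells$suppressed], gp$prop_gp, 0.02,
                   na.rm = TRUE))
  for (s in sexes) {
    cs <- cells[cells$sex == s, , drop = FALSE]
    graphics::plot(NA, xlim = c(-4.5, 2.5), ylim = ylim,
                   xlab = "Years before/after initiation",
                   ylab = "Proportion of users",
                   main = sprintf("%s (%s)", group, s), ...)
    graphics::abline(v = 0, lty = 2, col = "grey50")
    ags <- sort(unique(cs$age_group))
    for (k in seq_along(ags)) {
      a <- cs[cs$age_group == ags[k], , drop = FALSE]
      a <- a[order(a$window), , drop = FALSE]
      shown <- !a$suppressed
      graphics::points(a$window[shown], a$proportion[shown],
                       pch = 1, col = k)
      graphics::lines(a$window[shown], a$proportion[shown],
                      lty = 3, col = k)
      graphics::segments(a$window[shown], a$ci_low[shown],
                         a$window[shown], a$ci_high[shown], col = k)
      if (!is.null(gp)) {
        g <- gp[gp$sex == s & gp$age_group == ags[k], , drop = FALSE]
        g <- g[order(g$window), , drop = FALSE]
        graphics::points(g$window, g$prop_gp, pch = 16, col = k)
      }
    }
    graphics::legend("topleft", legend = ags, col = seq_along(ags),
                     pch = 1, bty = "n", title = "Age group")
  }
  invisible(x)
}
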