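test_that("ATC prefix matching selects therapeutic groups", {
  g <- default_drug_groups()
  expect_true(match_group("C07AB02", g$betablockers))
  expect_false(match_group("C08DA01", g$betablockers))
  expect_true(match_group("C01AA05", g$digitalis))
  expect_true(match_group("N06AB04", g$citalopram_escitalopram))
  expect_true(match_group("N06AB10", g$citalopram_escitalopram))
  expect_false(match_group("N06AB05", g$citalopram_escitalopram))
  expect_error(match_group("7C0AB02", g$betablockers), "malformed")
  expect_error(drug_group("empty", character(0)), "prefix")
})

test_that("Wilson intervals match the closed form and its boundary cases", {
  ci <- wilson_ci(50, 100)
  expect_equal(round(ci$low, 4), 0.4038)
  expect_equal(round(ci$high, 4), 0.5962)

  expect_identical(wilson_ci(0, 50)$low, 0)
  expect_identical(wilson_ci(100, 100)$high, 1)
  # degenerate upper bound at x = 0 is z^2 / (n + z^2)
  z <- qnorm(0.975)
  expect_equal(wilson_ci(0, 50)$high, z^2 / (50 + z^2))
  expect_error(wilson_ci(1, 0), "n_total")
  expect_error(wilson_ci(5, 3), "n_users")

  # interval always contains the point estimate
  x <- c(0, 1, 7, 25, 50)
  ci <- wilson_ci(x, 50)
  expect_true(all(ci$low <= x / 50 & x / 50 <= ci$high))
})

test_that("window boundaries are inclusive at -1460 and 729, exclusive beyond", {
  members <- data.frame(patient_id = c("A", "B", "C", "D"),
                        sex = "female", age_group = "37-80",
                        index_date = as.Date("2010-01-01"))
  disp <- data.frame(
    patient_id = c("A", "B", "C", "D"),
    dispense_date = as.Date("2010-01-01") + c(-1460, -1461, 729, 730),
    atc_code = "C07AB02", n_units = 50L)
  cells <- window_prevalence(members, disp, drug_group("bb", "C07"))
  users <- structure(cells$n_users, names = as.character(cells$window))
  expect_equal(users[["-4"]], 1L)  # day -1460 counts
  expect_equal(users[["2"]], 1L)   # day 729 counts
  expect_equal(sum(cells$n_users), 2L)  # -1461 and 730 count nowhere
  expect_true(all(cells$n_total == 4L))
})

test_that("concomitant use requires both groups in the same window", {
  members <- data.frame(patient_id = c("X", "Y"), sex = "female",
                        age_group = "37-80",
                        index_date = as.Date("2010-01-01"))
  disp <- data.frame(
    patient_id = c("X", "X", "Y", "Y"),
    dispense_date = as.Date("2010-01-01") + c(-100, 100, 100, 150),
    atc_code = c("C07AB02", "N06AB10", "C07AB02", "N06AB10"),
    n_units = 50L)
  g <- default_drug_groups()
  comb <- combination_prevalence(members, disp, g$betablockers,
                                 g$citalopram_escitalopram)
  # X has the two drugs in different windows, Y in the same window
  expect_equal(sum(comb$n_users), 1L)
  expect_equal(comb$n_users[comb$window == 1], 1L)
})

test_that("combination of a group with itself is the marginal prevalence", {
  reg <- small_registry()
  co <- select_cohort(reg$patients, reg$dispensings)
  g <- default_drug_groups()$betablockers
  marg <- window_prevalence(co$members, reg$dispensings, g)
  self <- combination_prevalence(co$members, reg$dispensings, g, g)
  expect_equal(self$n_users, marg$n_users)
  expect_equal(self$proportion, marg$proportion)
})

test_that("union prevalence adds disjoint users exactly", {
  members <- data.frame(patient_id = sprintf("P%d", 1:20), sex = "male",
                        age_group = "37-80",
                        index_date = as.Date("2010-01-01"))
  disp <- data.frame(
    patient_id = c("P1", "P2", "P3", "P4"),
    dispense_date = as.Date("2010-01-01") + 100,
    atc_code = c("C07AB02", "C07AG02", "N06AB10", "N06AB04"),
    n_units = 50L)
  g <- default_drug_groups()
  u <- any_of_groups_prevalence(members, disp,
                                g[c("betablockers",
                                    "citalopram_escitalopram")])
  expect_equal(u$proportion[u$window == 1], 0.2)  # 10% + 10%, no overlap
})

test_that("prevalence cells obey the set-theoretic and design invariants", {
  reg <- small_registry()
  co <- select_cohort(reg$patients, reg$dispensings)
  g <- default_drug_groups()
  key <- function(d) paste(d$window, d$sex, d$age_group)

  bb <- window_prevalence(co$members, reg$dispensings, g$betablockers)
  ci <- window_prevalence(co$members, reg$dispensings,
                          g$citalopram_escitalopram)
  comb <- combination_prevalence(co$members, reg$dispensings,
                                 g$betablockers, g$citalopram_escitalopram)
  u <- any_of_groups_prevalence(
    co$members, reg$dispensings,
    g[c("betablockers", "citalopram_escitalopram")])

  ci <- ci[match(key(bb), key(ci)), ]
  comb <- comb[match(key(bb), key(comb)), ]
  u <- u[match(key(bb), key(u)), ]

  expect_true(all(comb$n_users <= pmin(bb$n_users, ci$n_users)))
  expect_true(all(u$n_users >= pmax(bb$n_users, ci$n_users)))
  expect_true(all(u$n_users <= bb$n_users + ci$n_users))

  # the cohort is fixed: n_total constant across windows within stratum
  totals <- tapply(bb$n_total, paste(bb$sex, bb$age_group),
                   function(x) length(unique(x)))
  expect_true(all(totals == 1))

  # suppression flags exactly the cells below the threshold
  all_cells <- rbind(bb, ci, comb, u)
  expect_identical(all_cells$suppressed, all_cells$n_users < 5)

  # Wilson bounds bracket every proportion
  expect_true(all(all_cells$ci_low <= all_cells$proportion &
                    all_cells$proportion <= all_cells$ci_high))
})
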