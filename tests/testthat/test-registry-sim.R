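test_that("configuration errors are caught", {
  expect_error(sim_config(persistent_fraction = 1.2), "probabilities")
  expect_error(sim_config(calendar_span = c(2010, 2004)), "calendar span")
  expect_error(sim_config(initiation_years = c(2014, 2008)),
               "initiation year")
  expect_error(sim_config(calendar_span = c(2006, 2016),
                          initiation_years = c(2004, 2013)),
               "outside calendar span")
  expect_error(sim_config(drug_use_probability = c(betablockers = -0.1)),
               "probabilities")
})

test_that("the generator is empty at n=0 and byte-deterministic under a seed", {
  empty <- simulate_registry(sim_config(n_patients = 0))
  expect_equal(nrow(empty$patients), 0)
  expect_equal(nrow(empty$dispensings), 0)

  cfg <- sim_config(n_patients = 120, seed = 5)
  expect_identical(simulate_registry(cfg), simulate_registry(cfg))
  # a different seed changes the draw
  other <- simulate_registry(sim_config(n_patients = 120, seed = 6))
  expect_false(identical(simulate_registry(cfg)$dispensings, other$dispensings))
})

test_that("the configured persistent fraction is realized exactly", {
  classify_all <- function(reg) {
    achei <- reg$dispensings[startsWith(reg$dispensings$atc_code, "N06DA"), ]
    vapply(split(achei, achei$patient_id), function(d) {
      d <- data.frame(date = d$dispense_date, atc_code = d$atc_code,
                      n_units = d$n_units)
      idx <- select_index_period(build_use_periods(d))
      classify_persistent(idx)$persistent
    }, logical(1))
  }
  all_pers <- simulate_registry(sim_config(
    n_patients = 500, persistent_fraction = 1, seed = 8))
  expect_true(all(classify_all(all_pers)))

  none_pers <- simulate_registry(sim_config(
    n_patients = 200, persistent_fraction = 0, seed = 9))
  expect_false(any(classify_all(none_pers)))
})

test_that("dispensings respect the death month and the calendar span", {
  reg <- simulate_registry(sim_config(n_patients = 600, seed = 12))
  span <- range(reg$dispensings$dispense_date)
  expect_true(span[1] >= as.Date("2004-01-01"))
  expect_true(span[2] <= as.Date("2016-12-31"))

  dead <- reg$patients[!is.na(reg$patients$death_year), ]
  expect_gt(nrow(dead), 0)
  for (i in seq_len(nrow(dead))) {
    pd <- reg$dispensings[reg$dispensings$patient_id == dead$patient_id[i], ]
    month_end <- as.Date(sprintf("%d-%02d-01", dead$death_year[i],
                                 dead$death_month[i]))
    month_end <- seq(month_end, by = "month", length.out = 2)[2] - 1
    if (nrow(pd)) expect_true(all(pd$dispense_date <= month_end))
  }
})

test_that("per-window use probabilities are recovered empirically", {
  cfg <- sim_config(n_patients = 4000, persistent_fraction = 1,
                    dropout_fraction = 0,
                    annual_death_hazard = function(age) 0 * age,
                    seed = 14)
  reg <- simulate_registry(cfg)
  truth <- reg$truth
  bb <- reg$dispensings[startsWith(reg$dispensings$atc_code, "C07"), ]
  day <- as.integer(bb$dispense_date -
                      truth$index_date[match(bb$patient_id,
                                             truth$patient_id)])
  for (w in c(-4, -1, 2)) {
    rng <- follow_up_windows()
    rng <- rng[rng$window == w, ]
    users <- length(unique(bb$patient_id[day >= rng$day_start &
                                           day <= rng$day_end]))
    p_hat <- users / nrow(truth)
    p <- 0.28
    expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / nrow(truth)))
  }
})

test_that("population counts honour the target prevalence", {
  cfg <- sim_config(seed = 4)
  zero <- simulate_population_counts(cfg, list(betablockers = 0))
  expect_true(all(zero$users == 0))

  half <- simulate_population_counts(cfg, list(betablockers = 0.5),
                                     population_per_cell = 1000)
  expect_true(all(half$users == 500L))
  expect_true(all(half$population > 0))
  expect_true(all(half$users <= half$population))
  expect_error(simulate_population_counts(cfg, list(betablockers = 1.3)),
               "prevalence")

  # an age-rising target shows up as an age gradient in crude prevalence
  rising <- simulate_population_counts(
    cfg, list(betablockers = data.frame(age_lo = c(0, 70),
                                        age_hi = c(69, 89),
                                        prev = c(0.1, 0.4))))
  crude <- function(a) {
    sub <- rising[rising$age == a, ]
    sum(sub$users) / sum(sub$population)
  }
  expect_gt(crude(85), crude(50))

  # sex-specific targets land in the right stratum
  bysex <- simulate_population_counts(
    cfg, list(citalopram_escitalopram = c(male = 0.03, female = 0.06)))
  m <- bysex[bysex$sex == "male", ]
  f <- bysex[bysex$sex == "female", ]
  expect_true(all(m$users == round(m$population * 0.03)))
  expect_true(all(f$users == round(f$population * 0.06)))
})
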