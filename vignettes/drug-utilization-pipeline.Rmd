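---
title: "Methods: a refill-based AChEI drug-utilization pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a refill-based AChEI drug-utilization pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acheiuse)
```

## The problem and the design

Acetylcholinesterase inhibitors (AChEIs; ATC `N06DA`) are first-line
symptomatic treatment in Alzheimer's disease. Because both AChEIs and
several commonly co-prescribed drug classes slow the heart or prolong the
QT interval, the co-medication burden of AChEI users is a safety question
in its own right. `acheiuse` implements a *new-user, persistent-survivor*
utilization design on individual-level pharmacy dispensing data: patients
are anchored at their AChEI initiation (index) date, required to persist
on treatment and to survive the follow-up horizon, and their use of five
drug groups — haloperidol (`N05AD01`), citalopram/escitalopram
(`N06AB10`/`N06AB04`), verapamil (`C08DA01`), betablockers (`C07`) and
digitoxin/digoxin (`C01A`) — plus two concomitant pairs is measured in six
fixed 365-day windows from 4 years before to 2 years after index. A
diuretics group (`C03`) can be configured the same way but is not part of
the default set.

The fundamental measurement unit throughout is *filled at least one
prescription in a window*. The design deliberately does not quantify dose,
DDD-weighted intensity or supply overlap; a "concomitant" pair means one
dispensing of each group within the same 365-day window.

## Episodes, supply and persistence

Dispensing registries record what was dispensed, not what was consumed.
The package converts a dispensing of $n$ units into days of supply as
$\lceil n / r \rceil$ with a consumption rate $r$ of 2 units/day for
rivastigmine (`N06DA03`, dosed twice daily) and 1 unit/day otherwise;
the partial final day counts as a treated day ("supposed to be consumed").
`daily_rate_table()` makes the rates configurable by ATC prefix.

A patient's AChEI stream is split into **use periods**: maximal runs with
inter-dispensing gaps of at most 365 days (a gap of exactly 365 days keeps
the run together; 366 splits it — the washout criterion is *more than* 365
drug-free days). The **index period** is the one with the largest number
of prescriptions; ties go to the longer period, then to the earlier start.
The tie-break reconciles the two natural readings — "most prescriptions"
and "longest period" — which coincide for almost all realistic streams;
where they differ, prescription count is taken as primary because the
persistence rules are phrased in terms of refills. The period's
`treatment_length` is `end_date − start_date + 1` days, the end date being
the last day the final dispensing's supply was supposed to be consumed.

An incident user is **persistent** when any of three refill-pattern rules
holds, with day 0 the index date:

1. a refill dated in the closed interval [210, 240];
2. at least 210 days of supply dispensed on days 0–209;
3. the last dispensing dated before day 210 has supply reaching day 210.

The 240-day (8-month) horizon reflects treatment-evaluation guidelines
(90–180 days plus allowance for delay). Day arithmetic is chosen so no
dispensing is double-counted across the day-210 boundary: a dispensing
dated exactly day 210 counts towards rule 1 only. Rules use no
stockpiling: each dispensing's supply starts on its own date and overlaps
are not carried forward — rule 2 separately handles cumulative supply.
`supply_coverage()` exposes both the no-stockpiling and the carry-over
bookkeeping as day-by-day arrays, so the rule semantics are testable
against brute force.

One subtlety is worth stating plainly: **rule 3 is not monotone** in the
dispensing stream. Because it inspects only the *last* pre-210
prescription, a small late top-up (say 4 tablets on day 205, after a
115-day supply dispensed on day 100) displaces the large supply as "last"
and can undo rule-3 persistence while the rule-2 total stays below 210.
This is the literal rule semantics and the package keeps it; the test
suite asserts monotonicity where it genuinely holds (rules 1 and 2) and
pins the rule-3 counterexample explicitly.

## The inclusion/exclusion cascade

`select_cohort()` applies a fixed cascade to every AChEI-ever patient and
logs the *first* triggering reason per excluded candidate, so the
exclusion counts partition the candidates:

1. `not_incident` — index date within 365 days of the start of registry
   coverage, so the washout cannot be verified (with coverage from 2004,
   the earliest verifiable index date is 2005-01-01);
2. `not_persistent`;
3. `index_outside_window` — outside 2008-01-01 … 2013-12-31, the window
   that leaves 4 years of look-back and 2 years of follow-up inside
   2004–2016 coverage;
4. `over_age_cap` — older than 88 at index. The cap exists because the
   general-population reference has 1-year age resolution only up to 89,
   and the second follow-up year shifts ages by +1;
5. `died_within_2y` — death year ≤ index year + 2. Death is recorded at
   year/month resolution and the rule is phrased in calendar years
   ("within 2 years after *the year of* initiation"), so the year-based
   reading is used rather than a 730-day one;
6. `absent_from_registry_y2` — no dispensing of *any* drug in days
   365–729 after index, the operational proxy for having left
   community pharmacy care (typically nursing-home admission).

Age is everywhere `calendar year − birth year`: the registry carries only
birth year, so exact birthdays are unavailable by design. Patients with
earlier AChEI use 2–4 years before the index period (possible under the
1-year washout) are retained. No lower age bound is enforced; the "37" in
the default stratum label is the observed minimum in the design this
package operationalizes, not a criterion.

## Prevalence, intervals and suppression

For each window × sex × age-group cell, `window_prevalence()` counts
members with ≥ 1 matching dispensing inside the member's own window day
range (window −4 is days [−1460, −1096], …, window +2 is days [365, 729];
a dispensing dated exactly index − 1460 counts, index − 1461 does not).
Windows are fixed 365-day day-count offsets; leap days are ignored since
the design counts days, not calendar years. The cohort is fixed, so
`n_total` is constant across windows within a stratum.

Binomial confidence intervals use the Wilson score form with
$z = \Phi^{-1}(0.975)$:
$$\frac{x + z^2/2}{n + z^2} \pm \frac{z\sqrt{x(n-x)/n + z^2/4}}{n + z^2},$$
clipped to [0, 1]; the lower bound is exactly 0 at $x = 0$ and the upper
exactly 1 at $x = n$. Cells with fewer than 5 users are flagged
`suppressed`. Suppression is applied at *reporting* (tables carry the
flag, plots drop the cells) while counts and proportions are always
computed, so downstream standardization and ratios never operate on
censored inputs.

## Year-shifted direct age standardization

The cohort can be followed longitudinally; the general population cannot.
When a window lies X years before/after initiation, the GP comparison
shifts both dispensing year and age by X: windows −4…−1 shift by −4…−1,
window +1 by 0 (the first post-index year *is* the initiation year) and
window +2 by +1. For reference ages 81–88 and initiation years 2008–2013
this yields exactly ages 77–84 in 2004–2009 for window −4 and ages 82–89
in 2009–2014 for window +2; `gp_comparison_cells()` exposes the index
sets and the test suite checks them cell by cell. The +1/+2 mapping is
the one consistent with the 82–89/2009–2014 convention; mapping the first
post-index year to shift 0 is the only choice that keeps the six shifts
consecutive.

For each initiation year $y$, `age_adjust_one_year()` computes the
age-adjusted user count $u_y = \sum_a w_y(a)\,\mathrm{rate}(y+s, a+s)$
with reference weights $w_y(a)$ = initiators of age $a$ in year $y$ (of
the same sex and age group — each stratum is standardized to its own age
distribution), and $N_y = \sum_a w_y(a)$. The window's adjusted
prevalence is $\sum_y u_y / \sum_y N_y$ and the prevalence ratio is the
study proportion divided by it. Reference ages whose shifted age exceeds
89 are dropped from both sums (a renormalization) with a warning; with
the 88-year cap and a +1 maximum shift this affects no mass in the
default setting. No CIs are attached to GP quantities — at population
denominators they are negligibly narrow — and none are attached to the
ratios. A ratio against a zero GP prevalence is reported as missing.

## The synthetic registry generator

Real nationwide prescription databases are access-restricted, so the
package ships a generator (`simulate_registry()`,
`simulate_population_counts()`) whose defaults encode the study
conditions the pipeline is meant for:

* registry coverage 2004–2016, initiation years 2008–2013;
* every simulated patient is an AChEI initiator (an extract of AChEI-ever
  persons, which is what an individual-level registry delivery looks
  like), 63% female, age at initiation truncated-normal
  (mean 79, sd 6.5) on 45–92 — deliberately crossing the 88-year cap so
  the age exclusion is exercised;
* AChEI streams are renewal processes: refill intervals uniform on 25–95
  days, each dispensing supplying its following gap plus 10 days, for a
  treatment duration uniform on 270–1800 days. This guarantees streams of
  intended-persistent patients satisfy the rules; intended-non-persistent
  patients receive 1–2 short supplies that provably violate all three.
  The configured `persistent_fraction` (default 0.8) is therefore
  realized exactly, which the tests exploit;
* co-medication is generated per 365-day window with configurable
  per-group probabilities (defaults: betablockers 0.28,
  citalopram/escitalopram 0.15, digitalis 0.035, verapamil 0.014,
  haloperidol 0.012 — magnitudes typical of an elderly Nordic cohort),
  plus a background analgesic (probability 0.98/window) that keeps living
  community-dwelling patients visible in the registry;
* an age-dependent Gompertz-type death hazard
  ($\min(0.5,\,2\cdot10^{-5} e^{0.1\,\mathrm{age}})$, ≈ 6%/year at 80)
  acting from the initiation year, and an institutionalization-style
  dropout (default 5% of patients) that hard-stops all dispensings from a
  random day 241–729 after index. Both truncations start after day 240 by
  construction, so they exercise the death and registry-absence
  exclusions without ever flipping an intended-persistent stream — a
  generator design choice that keeps the persistent fraction exact;
* the aggregate GP table has every year × age (0–89) × sex cell populated
  (default 10,000 persons/cell) with `users = round(population ×
  target)`, the target being scalar, sex-specific or age-banded per drug
  group; `default_gp_prevalence()` encodes age-rising betablocker,
  verapamil and digitalis use and a female excess for
  citalopram/escitalopram.

What the generator does *not* emulate: dose trajectories and switching
between AChEIs (all `N06DA` codes are pooled, as the design pools them),
seasonality, prescriber or geographic structure, correlation between
co-medication groups (they are independent given sex and age), and
calendar trends in GP prevalence. Passing tests therefore demonstrate the
*bookkeeping* — episode splitting, rule evaluation, cascade order, window
attribution, standardization algebra — under known truth; they do not
validate clinical prevalence levels on real data.

## Numerical and testing choices

Supply rounding is `ceiling`; all rule intervals are closed as stated
above; dates are `Date` arithmetic in integer days with ISO-8601 I/O.
Analysis outputs carry no timestamps, so reruns on identical inputs are
byte-identical. Test problem sizes are chosen to make binomial noise
negligible relative to the asserted tolerances while keeping the default
suite fast: 800-patient registries for structural properties, 4,000 for
empirical probability recovery (3 binomial SEs), 20,000 for the
prevalence/ratio parameter-recovery check (target 0.30 within 3 SEs of
each window × sex estimate; ratio 2.0 within [1.8, 2.2] against a flat
0.15 GP target, where the GP side is exact by construction and only
study-side sampling noise remains), and 10,000 for the end-to-end run.
The parameter-recovery fixture switches death and dropout off so the
check isolates binomial sampling from the censoring mechanisms; identity
checks on the standardization (self-standardization to the GP's own
structure, constant-rate invariance, brute-force double-sum agreement)
are asserted to `1e-12` on randomized tables.

## Limitations

Dispensing is a proxy for consumption ("assumed that dispensed drugs were
consumed"); institutional (nursing-home) supply is invisible, which is
precisely why the second-year registry-presence rule exists; the index
date is a surrogate for diagnosis; prevalence ratios carry no interval
estimates; and the persistent-survivor design conditions on two years of
survival, so its estimates describe survivors, not all initiators.
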