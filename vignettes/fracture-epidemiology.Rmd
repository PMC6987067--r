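---
title: "Methods: fracture incidence, burden projection and competing-risk probability"
author: "fracepi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fracture incidence, burden projection and competing-risk probability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracepi)
```

# What the package computes

`fracepi` implements the calibration core of a country-specific fracture-risk
(FRAX-style) model from population-based survey data:

1. **Incidence estimation** — from line-listed low-energy fracture records and
   a catchment population, age/sex/site-specific incidence per 100,000
   person-years with exact Poisson confidence intervals.
2. **Reference-ratio imputation** — rates for sites the survey did not capture
   (or to cross-check the ones it did), scaled from hip rates via a reference
   population's site-to-hip pattern.
3. **Burden projection** — expected annual fracture counts under population
   projections, with an optional secular-trend drift.
4. **Probability engine** — 10-year and remaining-lifetime fracture
   probabilities under the competing risk of death, from a per-year-of-age
   hazard schedule.
5. **Synthetic data** — a generator with known ground truth so each stage can
   be validated by parameter recovery.

The package ships the published two-district Moldovan survey tables
(2011–2012, ages 40+) as worked inputs: `moldova_population()`,
`moldova_fracture_counts()`, `moldova_predicted_observed()` and
`moldova_burden_projection()`.

# Incidence estimation

## Records and inclusion rules

A record is one admission: person id, sex, age at event, event date, ICD-10
site code, an energy/mechanism flag and a residency flag. `filter_records()`
keeps low-energy fractures in people at or above the minimum age (boundary
inclusive, default 40) whose event date lies in the observation window and
whose code belongs to a declared site group — hip (S72.0–S72.2), distal
forearm (S52.5, S52.6), proximal humerus (S42.2) by default. Nothing is
silently dropped: excluded rows go to a rejected-records report with a reason
each.

Two flags reflect genuinely open survey choices:

* `include_unknown_energy` (default `FALSE`): registers sometimes omit the
  mechanism; surveys that retrieve radiographs may include verified cases.
  The default is strict exclusion.
* `residents_only` (default `FALSE`): where permanent residence is not an
  inclusion criterion, temporary residents in the catchment are counted; the
  flag restricts to residents.

`deduplicate()` reduces the records to *index* fractures: the earliest
admission per (person, site group). Later admissions for the same site are
repeat presentations of the same fracture episode, not new events. Ties on
date are broken by stable input order; records with missing ids cannot be
deduplicated, are kept, and are tallied in a warning.

## Rates and intervals

Person-years in a stratum are the mid-period population count times the
window length in years — the population is treated as constant over the
window, which is exactly the convention under which a 2-year count divided by
one census figure reproduces published annual rates. Age bands are closed-open
`[low, high)` with an open-ended terminal band; this is the reading of
"40–49 … 90+" labels that reproduces published counts.

The rate is `count / person_years × 100,000`. The interval is the exact
Poisson (Garwood) interval built from chi-square quantiles,

$$\left[\tfrac{1}{2}\chi^2_{\alpha/2}(2k),\;
        \tfrac{1}{2}\chi^2_{1-\alpha/2}(2k+2)\right] / \mathrm{PY}
        \times 10^5,$$

with lower bound 0 at `k = 0`. Exact intervals are conservative (coverage at
or above nominal); the test suite verifies both CDF-inversion equivalence for
counts 0–500 and 93–98% empirical coverage on 2,500 simulated strata. A
normal-approximation mode exists behind `method = "normal"` for comparison
but is never the default: it misbehaves at the small counts typical of
oldest-age strata.

Pooled "40+" rows aggregate counts and person-years *before* dividing —
a pooled rate, never a mean of band rates. Display rounding (integer at
≥1,000, otherwise 1 decimal for hip and integer for forearm/humerus) is a
formatting convention in `format_rate()`; stored values are never rounded.

Recomputing the bundled Moldovan tables reproduces the published rates and
the verified interval bounds; a handful of published cells differ by one unit
in the last digit (and one rate cell is inconsistent with its own printed
interval), which we report rather than force — the published interval method
is unstated and software rounding differs.

# Reference-ratio imputation

Where a target population has trustworthy hip rates but no (or thin) data for
another site, the indirect method assumes the age- and sex-specific
site-to-hip ratio of a reference population transfers:

$$\mathrm{rate}_{target}(site) = \mathrm{rate}_{target}(hip) \times
  \frac{\mathrm{rate}_{ref}(site)}{\mathrm{rate}_{ref}(hip)}.$$

`impute_site_rate()` is that expression; `impute_rates()` applies it across a
table. The classical reference is the Malmö pattern; its tables are not
redistributable here, so the package bundles no reference rates — tests and
the acceptance script build a clearly labelled *synthetic* reference with
smooth age gradients. Three properties pin the arithmetic down: imputing a
population from itself is the identity; scaling target hip rates scales
predictions linearly; and the expression inverts exactly.

When reference and target bandings differ, `aggregate_reference_bands()`
aggregates the finer banding to the coarser by person-year-weighted averaging
(equal weights if no reference population is supplied, declared in the
output). Bands straddling a coarse edge are refused rather than interpolated:
whether published comparisons used the fine bands directly or interpolated is
typically unstated, so both resolutions are left to the caller explicitly.

`compare_predicted_observed()` joins predictions to observed strata and flags
whether each prediction falls inside the observed exact interval (boundaries
inclusive). By convention the check runs in the sex with more fractures
(women); on the published Moldovan comparison rows it reproduces 14 of 16
strata inside the interval, with the two published exceptions (forearm 55–59
overestimated, humerus 60–64 underestimated) flagged.

# Burden projection

`project_counts()` applies fixed age/sex/site rates to projected populations:
`count(year, sex, site) = Σ_bands rate × persons / 100,000`. Unrounded
expected counts are stored. Burden tables default to ages 50+ (the usual
presentation); `min_age = 40` uses the survey's full range. Additivity and
homogeneity are tested invariants, and the implementation is checked cell by
cell against a brute-force stratum loop.

`secular_trend_adjust()` compounds an annual drift,
`rate(year) = rate(base) × (1 + drift)^(year-base)`, producing per-year rate
tables for sensitivity scenarios (e.g. +1%/yr, the magnitude discussed for
moderate secular increases).

On the published totals row (2015: 10,484 → 2050: 15,084) `percent_change()`
gives +43.9%. The text accompanying the published table quotes "41%" for the
same comparison; the package follows the stated algorithm and documents
rather than chases the discrepancy (the published table is also internally
inconsistent with two other totals quoted alongside it). Reproducing the published projections
exactly would require the specific UN demography revision, which is external
versioned data; the bundled `moldova_burden_projection()` is therefore a
documentation fixture, not a test target.

# Competing-risk probability engine

`build_hazard_schedule()` expands banded incidence and mortality into
piecewise-constant hazards on single years of age: each year gets its band's
rate converted to a per-person-year hazard; the terminal band's value is held
constant up to the closure age. Incidence is the hazard of a *first* (index)
fracture; no prior-fracture multiplier is applied — the clinical-risk-factor
layer of a full FRAX model is out of scope. Major-osteoporotic schedules can
be formed by summing site-specific hazards, accepting the known
approximation that one person can fracture at two sites.

`interval_probability()` computes, over years `u` with fracture hazard `h_f`,
death hazard `h_d`, `h = h_f + h_d` and event-free survival
`S(u) = exp(−Σ_{v<u} h(v))`:

$$p_{fracture\ first} = \sum_u S(u)\,\frac{h_f(u)}{h(u)}\,
  \bigl(1 - e^{-h(u)}\bigr),$$

and analogously for death-first. The within-year split `h_f/h` is the exact
allocation for competing constant hazards — not an end-of-year approximation,
which would bias fracture probability downward at old ages where annual death
hazards are large. Years with `h = 0` contribute nothing and leave `S`
unchanged. The three components sum to one by construction (tested to 1e−9);
constant-hazard cases match the closed form
`h_f/h × (1 − e^{−Th})` to 1e−12; and the engine agrees with an independent
event-time microsimulation (competing exponentials within each year) within
three Monte-Carlo standard errors at 10^6 replicates.

## Numerical choices

* **Annual steps.** Because hazards are constant within a year and the
  within-year split is exact, refining to monthly sub-steps
  (`steps_per_year = 12`) changes 10-year probabilities only at rounding
  level; the tested bound is <0.1% relative. The annual default is therefore
  adequate, and the sub-step option exists mainly to document that.
* **Closure age 110.** Hazards beyond the last band are held constant to
  110. At realistic old-age mortality, survival past 110 is negligible, so
  lifetime risks are insensitive to this choice.
* **Below the youngest band** fracture hazard would be undefined; schedules
  start at the incidence table's first band (40), and probability runs start
  at or above it.

`lifetime_probability()` is the interval probability run to the closure age —
the remaining-lifetime risk from, conventionally, age 50.
`probability_ratio_vs_reference()` compares like-for-like probabilities
across populations. Published lifetime figures for specific countries depend
on the specific national life table used (for Moldova, a UN 2009 revision not
printed in the source); the package treats them as plausibility anchors: on a
Gompertz life table tuned to Moldovan life expectancy, the bundled hip rates
give a women's remaining lifetime risk at 50 in the upper single digits of
percent and roughly 1.7 times the men's — the expected regime.

# The synthetic-data world

`simulation_spec()` fixes the stated world of the generator: true rates per
(sex, band, site), a catchment population, the window length (the population
table's `period_years`), and decoy fractions. Its defaults mirror the survey
design the package targets: a 24-month window on a fixed two-district
catchment, with the decoys *off* unless a test switches them on.

* Stratum counts are Poisson with mean `rate × persons × window / 10^5` —
  the sampling model under which the estimator's intervals are exact.
* Ages are uniform within band (no within-band distribution is asserted by
  survey tables; this is a declared limitation for fine-band re-aggregation
  experiments) and event dates uniform in the window (no seasonality).
* Decoys: repeat admissions (`duplicate_prob`; same person and site, later
  date — what deduplication must remove *exactly*), high-energy fractures
  (`high_energy_frac`; what the energy filter must exclude), and non-resident
  flags (`nonresident_frac`; genuine fractures that a residency filter could
  exclude — matching surveys that include temporary residents, these are kept
  by default).
* A fixed seed reproduces records byte for byte.

`make_demography()` stands in for external demographic sources: Gompertz
mortality, log-linear in age with a sex offset, defaults
`log h(a) = log(3×10^{-5}) + 0.10a` for women and ×1.8 for men, chosen once
to give remaining life expectancy at 50 of ≈27 years (women) and ≈22 (men) —
the published regime for the target population — and band-wise compounding
population growth for ageing scenarios.

What a green recovery test establishes: with decoys off, the full
`simulate → filter → deduplicate → estimate` pipeline is unbiased (|relative
bias| < 2% at 1,000 replicates for strata with expected count ≥ 20) with
interval coverage in [0.93, 0.98]. What it does not establish: robustness to
features real registers have and the generator omits — seasonality, secular
trends within the window, within-band age gradients, clustering, or
ascertainment that varies by source.

# Known limitations

* The exact method behind published intervals is rarely stated; last-digit
  disagreements with printed bounds are expected and reported, not forced.
* Imputation inherits the transferability assumption of the reference
  pattern; it is a cross-check, not a substitute for local data, and clinical
  spine rates imputed this way cannot be validated against the bundled survey
  (no observed spine data).
* Projections carry no uncertainty intervals (none are conventionally
  published for this design) and assume either stable rates or a single
  deterministic drift.
* The probability engine models first index fractures at the population
  level; individual risk stratification (clinical risk factors, BMD) is out
  of scope.
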