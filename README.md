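# fracepi

Population-based osteoporotic fracture epidemiology in R: from line-listed
low-energy fracture records to age/sex-specific incidence with exact Poisson
confidence intervals, reference-ratio imputation of non-hip fracture rates,
calendar-year burden projections, and a competing-mortality life-table engine
for 10-year and remaining-lifetime fracture probability — the calibration
core of a country-specific FRAX-style model.

It is written for epidemiologists and biostatisticians building or auditing
national fracture-risk models from regional survey data, where the raw
material is a fracture register (hip S72.0–S72.2, distal forearm S52.5–S52.6,
proximal humerus S42.2), a catchment population, and a life table.

## The statistics at the core

**Incidence.** For a stratum (sex *s*, age band *a*) with *k* index fractures
over PY person-years, the rate is *k*/PY × 10⁵ with the exact Poisson
(Garwood) interval [½χ²₍α/2₎(2k), ½χ²₍1−α/2₎(2k+2)]/PY × 10⁵. Index fractures
are first admissions per person and site; repeat admissions are removed.

**Imputation.** Missing-site rates follow the reference-ratio (Malmö) method:
rate_target(site) = rate_target(hip) × rate_ref(site)/rate_ref(hip), per sex
and age band.

**Burden.** count(year, s, site) = Σₐ rate(s, a, site) × persons(year, s, a)/10⁵,
optionally with a compounding secular drift on the rates.

**Probability.** With piecewise-constant annual fracture hazard h_f and death
hazard h_d (h = h_f + h_d), and S(u) the event-free survival from the start
age, the fracture-first probability over a horizon is
Σᵤ S(u) · h_f/h · (1 − e^(−h)) — the exact competing-risk allocation within
each year. Remaining lifetime risk is the same sum run to the closure age
(110).

## Worked example

The package bundles the published two-district Moldovan survey (2011–2012,
ages 40+) as data constructors, so the full pipeline runs out of the box:

```r
library(fracepi)

inc <- moldova_incidence()          # counts + populations -> rates and CIs
subset(inc, sex == "female" & site == "hip" & age_low >= 60 & !is_total)
#> incidence table: 4 strata (95% exact Poisson CIs)
#>     sex  band site count person_years   rate ci_low ci_high
#>  female 60-69  hip    41        17842  229.8  164.9   311.7
#>  female 70-79  hip    69        11578  596.0  463.7   754.2
#>  female 80-89  hip    48         3964 1210.9  892.8  1605.5
#>  female   90+  hip    11          316 3481.0 1737.7  6228.5

sex_count_ratio(inc, "hip")$rounded     # 1.5  (203 women / 137 men)
sex_count_ratio(inc, "forearm")$rounded # 3.5

# predicted-vs-observed check of the reference-ratio method on the
# published comparison rows (women, 5-year bands):
tab4 <- moldova_predicted_observed()
cmp <- compare_predicted_observed(tab4[, c("sex","age_low","site","predicted")], tab4)
attr(cmp, "summary")
#>  within outside
#>      14       2

# competing-risk probabilities on a synthetic Gompertz life table tuned to
# e50 ~ 27 y (women):
spec <- simulation_spec(inc[!inc$is_total, c("sex","age_low","age_high","site","rate")],
                        moldova_population(), seed = 1)
demo <- make_demography(spec, years = 2015:2050)
sch  <- build_hazard_schedule(subset(inc, site == "hip"), demo$mortality, "female")
interval_probability(sch, 70, 10)
#> from age 70 over 10 y: P(fracture first) = 0.0469, P(death first) = 0.4027, P(event-free) = 0.5504
lifetime_probability(sch, 50)
#> [1] 0.0985
```

Read: a 70-year-old woman has a 4.7% probability of a first hip fracture in
the next decade once the 40% probability of dying first is accounted for; her
remaining lifetime hip-fracture risk from age 50 is ~9.9% on this life table.
(Published lifetime figures depend on the specific national life table used,
so they are plausibility anchors, not test targets.)

Synthetic surveys with known truth validate every stage:

```r
sim  <- simulate_records(spec)
kept <- deduplicate(filter_records(sim$records,
          window = as.Date(c("2011-01-01", "2012-12-31"))))
est  <- estimate_incidence(kept, moldova_population())
```

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch against the
installed package — recomputing the bundled survey's incidence table, sex
ratios, the predicted-vs-observed comparison, a seeded synthetic survey with
filtering/deduplication recovery, a burden projection on synthetic demography,
and the 10-year and lifetime probabilities — and writes its JSON result file:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

* `R/` — implementation (records, incidence, imputation, projection,
  probability engine, synthetic data, bundled survey tables)
* `tests/testthat/` — unit, property and acceptance tests
* `vignettes/fracture-epidemiology.Rmd` — the methods vignette: models,
  assumptions, numerical choices, what the synthetic world does and does not
  establish
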