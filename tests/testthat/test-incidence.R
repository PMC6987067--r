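test_that("person_years multiplies population by the observation period", {
  pop <- moldova_population()
  expect_equal(person_years(pop, "female", 70), 11578)   # 5,789 x 2 y
  expect_equal(person_years(pop, "male", 60), 13654)     # 6,827 x 2 y
  pop1 <- population_table(as.data.frame(pop), period_years = 1)
  expect_equal(person_years(pop1, "female", 70), 5789)   # identity at 1 y
  expect_error(person_years(pop, "female", 45), "missing population stratum")
})

test_that("poisson_ci matches direct CDF inversion for counts 0-500", {
  # oracle: invert P(X >= k | mu) = a/2 and P(X <= k | mu) = a/2 by bisection
  invert <- function(target_fun, lo, hi, tol = 1e-10) {
    while (hi - lo > tol * max(1, hi)) {
      mid <- (lo + hi) / 2
      if (target_fun(mid)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  oracle_ci <- function(k, level = 0.95) {
    a <- 1 - level
    low <- if (k == 0) 0 else
      invert(function(mu) stats::ppois(k - 1, mu, lower.tail = FALSE) < a / 2,
             0, 3 * k + 10)
    high <- invert(function(mu) stats::ppois(k, mu) > a / 2, 0, 3 * k + 30)
    c(low, high)
  }
  py <- 1e5 # rate units equal mean-count units
  for (k in c(0L, 1L, 2L, 5L, 10L, 48L, 137L, 500L)) {
    got <- poisson_ci(k, py)
    want <- oracle_ci(k)
    expect_equal(got$low, want[1], tolerance = 1e-4)
    expect_equal(got$high, want[2], tolerance = 1e-4)
  }
  # spec'd example: count 10, PY 100,000
  got <- poisson_ci(10L, 1e5)
  want <- oracle_ci(10L)
  expect_equal(c(got$low, got$high), want, tolerance = 1e-4)
})

test_that("poisson_ci handles edge cases and bad input", {
  z <- poisson_ci(0, 5000)
  expect_identical(z$low, 0)
  expect_gt(z$high, 0)
  expect_error(poisson_ci(3, 0), "positive")
  expect_error(poisson_ci(-1, 10), "non-negative")
  expect_error(poisson_ci(3, 10, level = 1.2), "level")
  # normal approximation flag differs from exact but brackets the rate
  k <- 50; py <- 2e4
  ex <- poisson_ci(k, py); no <- poisson_ci(k, py, method = "normal")
  rate <- k / py * 1e5
  expect_true(no$low < rate && rate < no$high)
  expect_false(isTRUE(all.equal(ex$low, no$low)))
})

test_that("exact intervals cover the true rate 93-98% of the time", {
  set.seed(2024)
  n_strata <- 2500
  rate <- stats::runif(n_strata, 50, 1200)          # per 1e5/yr
  py <- stats::runif(n_strata, 4e3, 4e4)            # expected counts ~20-300
  k <- stats::rpois(n_strata, rate * py / 1e5)
  ci <- poisson_ci(k, py)
  coverage <- mean(ci$low <= rate & rate <= ci$high)
  expect_gte(coverage, 0.93)
  expect_lte(coverage, 0.98)
})

test_that("estimate_incidence tabulates counts, rates and CIs by stratum", {
  window <- as.Date(c("2011-01-01", "2012-12-31"))
  recs <- rbind(
    make_record("p1", age = 45), make_record("p2", age = 45),
    make_record("p3", age = 52), make_record("p4", age = 67, sex = "male"),
    make_record("p5", age = 44, icd10 = "S52.5"),
    make_record("p6", age = 96))  # above the top closed band? 60+ is open here
  pop <- tiny_population()
  banding <- age_banding(c(40, 50, 60))
  kept <- deduplicate(filter_records(recs, window = window))
  inc <- estimate_incidence(kept, pop, banding = banding)

  cell <- function(s, lo, site)
    inc[inc$sex == s & inc$age_low == lo & inc$site == site & !inc$is_total, ]
  expect_equal(cell("female", 40, "hip")$count, 2L)
  expect_equal(cell("female", 40, "hip")$person_years, 20000)
  expect_equal(cell("female", 40, "hip")$rate, 10)
  expect_equal(cell("female", 60, "hip")$count, 1L)  # age 96 in open band
  expect_equal(cell("male", 60, "hip")$count, 1L)
  expect_equal(cell("female", 40, "forearm")$count, 1L)
  z <- cell("male", 40, "forearm")
  expect_equal(z$rate, 0)
  expect_equal(z$ci_low, 0)

  # totals pool counts and person-years before computing the rate
  tot <- inc[inc$is_total & inc$sex == "female" & inc$site == "hip", ]
  expect_equal(tot$count, 4L)
  expect_equal(tot$person_years, 48000)
  expect_equal(tot$rate, 4 / 48000 * 1e5)
})

test_that("rate reconstruction and totals-consistency invariants hold", {
  set.seed(7)
  spec <- simulation_spec(
    rates = synthetic_reference()[, c("sex", "age_low", "age_high", "site",
                                      "rate")],
    population = moldova_population(), seed = 77)
  sim <- simulate_records(spec)
  kept <- deduplicate(filter_records(
    sim$records, window = as.Date(c("2011-01-01", "2012-12-31"))))
  inc <- estimate_incidence(kept, moldova_population())

  # rate x PY / 1e5 reconstructs the count for every cell
  expect_equal(inc$rate * inc$person_years / 1e5, as.numeric(inc$count))
  # totals equal pooled bands, not the mean of band rates
  for (s in c("female", "male")) for (site in c("hip", "forearm", "humerus")) {
    bands <- inc[!inc$is_total & inc$sex == s & inc$site == site, ]
    tot <- inc[inc$is_total & inc$sex == s & inc$site == site, ]
    expect_equal(tot$count, sum(bands$count))
    expect_equal(tot$person_years, sum(bands$person_years))
    expect_equal(tot$rate, sum(bands$count) / sum(bands$person_years) * 1e5)
  }
  # deterministic ordering by sex then band lower edge
  fem_hip <- inc[inc$sex == "female" & inc$site == "hip" & !inc$is_total, ]
  expect_equal(fem_hip$age_low, sort(fem_hip$age_low))
})

test_that("sex_count_ratio returns exact and 1-dp values, NA on zero male", {
  inc <- moldova_incidence()
  r <- sex_count_ratio(inc, "hip")
  expect_equal(r$ratio, 203 / 137)
  expect_equal(r$rounded, 1.5)
  # equal counts give exactly 1
  eq <- inc
  eq$count[eq$is_total & eq$site == "hip"] <- 100L
  expect_equal(sex_count_ratio(eq, "hip")$ratio, 1)
  zero <- inc
  zero$count[zero$is_total & zero$site == "hip" & zero$sex == "male"] <- 0L
  expect_warning(rz <- sex_count_ratio(zero, "hip"), "undefined")
  expect_true(is.na(rz$ratio))
})

test_that("incidence tables round-trip through CSV", {
  inc <- moldova_incidence()
  path <- tempfile(fileext = ".csv")
  write_incidence_csv(inc, path)
  back <- read_incidence_csv(path)
  bands <- inc[!inc$is_total, ]
  expect_equal(back$count, bands$count)
  expect_equal(back$rate, bands$rate, tolerance = 1e-9)
  expect_equal(back$age_high, bands$age_high)  # Inf survives as empty field
})

test_that("display rounding follows table conventions without touching data", {
  expect_equal(format_rate(c(1210.9, 596.04, 85.56), rep("hip", 3)),
               c("1211", "596.0", "85.6"))
  expect_equal(format_rate(c(672.57, 336.85), c("forearm", "humerus")),
               c("673", "337"))
})
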