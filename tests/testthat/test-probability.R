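flat_schedule <- function(hf, hd, start = 40, closure = 110) {
  ages <- start:(closure - 1)
  structure(list(sex = "female", site = "hip", ages = ages,
                 fracture_hazard = rep(hf, length(ages)),
                 death_hazard = rep(hd, length(ages))),
            class = "hazard_schedule")
}

test_that("build_hazard_schedule expands bands to piecewise-constant years", {
  inc <- moldova_incidence()
  mort <- mortality_table(data.frame(
    sex = rep(c("female", "male"), each = 2),
    age_low = rep(c(40, 70), 2), age_high = rep(c(70, Inf), 2),
    hazard = c(0.005, 0.04, 0.009, 0.06)))
  sch <- build_hazard_schedule(inc[inc$site == "hip", ], mort, "female")

  expect_equal(sch$ages, 40:109)
  # band 70-79 rate 596.0/1e5 lands on every single year in the band
  expect_equal(sch$fracture_hazard[sch$ages == 73], 69 / 11578, # = 0.00596
               tolerance = 1e-12)
  expect_equal(sch$fracture_hazard[sch$ages == 73], 0.00596, tolerance = 1e-3)
  # step edges: the two-band mortality is a step function at 70
  expect_equal(unique(sch$death_hazard[sch$ages < 70]), 0.005)
  expect_equal(unique(sch$death_hazard[sch$ages >= 70]), 0.04)
  # terminal open band's rate extends to the closure age
  expect_equal(sch$fracture_hazard[sch$ages == 109],
               11 / 316 * 1e5 / 1e5)
  # two-band fixture verified pointwise against a hand expansion
  inc2 <- data.frame(sex = "female", age_low = c(40, 60),
                     age_high = c(60, Inf), site = "hip",
                     rate = c(100, 400), is_total = FALSE)
  sch2 <- build_hazard_schedule(inc2, mort, "female", closure_age = 80)
  expect_equal(sch2$fracture_hazard,
               c(rep(0.001, 20), rep(0.004, 20)))
})

test_that("all-zero incidence gives all-zero fracture hazards", {
  inc <- data.frame(sex = "male", age_low = 40, age_high = Inf, site = "hip",
                    rate = 0, is_total = FALSE)
  mort <- mortality_table(data.frame(sex = "male", age_low = 40,
                                     age_high = Inf, hazard = 0.02))
  sch <- build_hazard_schedule(inc, mort, "male")
  expect_true(all(sch$fracture_hazard == 0))
  expect_equal(interval_probability(sch, 50, 10)$p_fracture_first, 0)
})

test_that("coverage gaps and bad horizons are refused", {
  mort <- mortality_table(data.frame(sex = "female", age_low = 40,
                                     age_high = Inf, hazard = 0.02))
  gappy <- data.frame(sex = "female", age_low = c(40, 60),
                      age_high = c(50, Inf), site = "hip",
                      rate = c(100, 200), is_total = FALSE)
  expect_error(build_hazard_schedule(gappy, mort, "female"), "gap")
  sch <- flat_schedule(0.01, 0.02)
  expect_error(interval_probability(sch, 50, 0), "positive")
  expect_error(interval_probability(sch, 105, 10), "not covered")
})

test_that("constant-hazard cases match the analytic closed forms to 1e-12", {
  # no mortality: cumulative-hazard exponential
  p <- interval_probability(flat_schedule(0.01, 0), 50, 10)
  expect_equal(p$p_fracture_first, 1 - exp(-0.1), tolerance = 1e-12)
  # competing risk: hf/(hf+hd) x (1 - exp(-10(hf+hd)))
  p <- interval_probability(flat_schedule(0.01, 0.03), 50, 10)
  expect_equal(p$p_fracture_first, 0.25 * (1 - exp(-0.4)), tolerance = 1e-12)
  expect_equal(p$p_death_first, 0.75 * (1 - exp(-0.4)), tolerance = 1e-12)
  expect_equal(p$p_event_free, exp(-0.4), tolerance = 1e-12)
  # lifetime closed form with zero mortality: 1 - exp(-H)
  sch <- flat_schedule(0.004, 0)
  H <- 0.004 * (110 - 50)
  expect_equal(lifetime_probability(sch, 50), 1 - exp(-H), tolerance = 1e-12)
})

test_that("the three components conserve probability on random schedules", {
  for (s in 1:25) {
    sch <- random_schedule(s)
    p <- interval_probability(sch, 45, sample(1:60, 1))
    expect_equal(p$p_fracture_first + p$p_death_first + p$p_event_free, 1,
                 tolerance = 1e-9)
    expect_true(all(c(p$p_fracture_first, p$p_death_first, p$p_event_free)
                    >= 0))
  }
})

test_that("probabilities are monotone in horizon and in the hazards", {
  sch <- random_schedule(123)
  p5 <- interval_probability(sch, 50, 5)$p_fracture_first
  p10 <- interval_probability(sch, 50, 10)$p_fracture_first
  p30 <- interval_probability(sch, 50, 30)$p_fracture_first
  expect_true(p5 <= p10 && p10 <= p30)

  up <- sch; up$fracture_hazard <- up$fracture_hazard * 1.5
  expect_gte(interval_probability(up, 50, 10)$p_fracture_first, p10)
  dn <- sch; dn$death_hazard <- dn$death_hazard + 0.05
  expect_lte(interval_probability(dn, 50, 10)$p_fracture_first, p10)
})

test_that("single-year collapse and high-mortality limits behave", {
  # death hazard so large that survival collapses within the first year
  sch <- flat_schedule(0.01, 6)
  lt <- lifetime_probability(sch, 50)
  # later years contribute only ~S(1) = exp(-6.01) in relative terms
  expect_equal(lt, 0.01 / 6.01 * (1 - exp(-6.01)), tolerance = 0.005)
  # mortality scaled up strictly decreases lifetime fracture probability
  base <- flat_schedule(0.01, 0.02)
  worse <- flat_schedule(0.01, 0.2)
  expect_lt(lifetime_probability(worse, 50), lifetime_probability(base, 50))
})

test_that("engine agrees with an event-time microsimulation oracle", {
  # moderate n here; the full 1e6-replicate check runs in the acceptance suite
  n <- 2e5
  for (s in c(31:40, 101:120)) {  # 30 random step schedules
    sch <- random_schedule(s)
    p <- interval_probability(sch, 50, 10)
    sim <- microsim_competing(sch, 50, 10, n, seed = 1000 + s)
    se <- sqrt(p$p_fracture_first * (1 - p$p_fracture_first) / n)
    expect_lt(abs(p$p_fracture_first - sim$p_fracture), 3 * se + 1e-12)
  }
})

test_that("monthly sub-steps leave 10-year probabilities essentially unchanged", {
  for (s in c(7, 8, 9)) {
    sch <- random_schedule(s)
    annual <- interval_probability(sch, 50, 10)$p_fracture_first
    monthly <- interval_probability(sch, 50, 10,
                                    steps_per_year = 12L)$p_fracture_first
    expect_lt(abs(monthly - annual) / annual, 1e-3)
  }
})

test_that("probability ratios compare like-for-like populations", {
  a <- interval_probability(flat_schedule(0.01, 0.02), 50, 10)
  b <- interval_probability(flat_schedule(0.01, 0.02), 50, 10)
  expect_equal(probability_ratio_vs_reference(a, b), 1)
  # doubling small fracture hazards about doubles small probabilities
  a2 <- interval_probability(flat_schedule(0.004, 0.02), 60, 10)
  a1 <- interval_probability(flat_schedule(0.002, 0.02), 60, 10)
  r <- probability_ratio_vs_reference(a2, a1)
  expect_true(abs(r - 2) / 2 < 0.05)
  # pointwise-larger fracture hazard, same mortality: ratio above 1
  expect_gt(probability_ratio_vs_reference(a2, a1), 1)
  mism <- interval_probability(flat_schedule(0.01, 0.02), 55, 10)
  expect_error(probability_ratio_vs_reference(a, mism), "share")
  z <- interval_probability(flat_schedule(0, 0.02), 50, 10)
  expect_warning(rz <- probability_ratio_vs_reference(a, z), "zero")
  expect_true(is.na(rz))
})

test_that("mortality CSV reader converts rates to hazards", {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(sex = "female", age_low = c(50, 70),
                              age_high = c(70, ""),
                              death_rate_per_1e5 = c(800, 5000)),
                   path, row.names = FALSE, quote = FALSE)
  mt <- read_mortality_csv(path)
  expect_s3_class(mt, "mortality_table")
  expect_equal(mt$hazard, c(0.008, 0.05))
  expect_equal(mt$age_high, c(70, Inf))
})
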