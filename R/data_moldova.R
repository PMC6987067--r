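#' Moldova 2011-2012 catchment population (Anenii Noi + Orhei districts)
#'
#' Published census-style population of the two-district catchment by sex and
#' 10-year age band, ages 40+. The survey window was the 24 months
#' 2011-01-01 to 2012-12-31, so the returned [population_table()] carries
#' `period_years = 2`.
#'
#' @return a [population_table()]
#' @export
moldova_population <- function() {
  df <- data.frame(
    sex = rep(c("male", "female"), each = 6),
    age_low = rep(c(40, 50, 60, 70, 80, 90), 2),
    age_high = rep(c(50, 60, 70, 80, 90, Inf), 2),
    count = c(13312, 14353, 6827, 3445, 734, 71,
              14880, 16947, 8921, 5789, 1982, 158))
  population_table(df, period_years = 2)
}

#' Moldova 2011-2012 index fracture counts by sex, age band and site
#'
#' Two-year counts of radiograph-verified low-energy index fractures at the
#' hip (ICD-10 S72.0-S72.2), distal forearm (S52.5-S52.6) and proximal
#' humerus (S42.2) in the two-district catchment, ages 40+. Forearm and
#' humerus counts were not reported for the 90+ band (pooled totals imply
#' zero there).
#'
#' @return data.frame with columns `sex`, `age_low`, `age_high`, `site`,
#'   `count`, suitable for [incidence_from_counts()]
#' @export
moldova_fracture_counts <- function() {
  band <- function(sex, site, counts)
    data.frame(sex = sex, age_low = c(40, 50, 60, 70, 80, 90),
               age_high = c(50, 60, 70, 80, 90, Inf), site = site,
               count = counts)
  rbind(
    band("male",   "hip",     c(15, 47, 36, 30, 8, 1)),
    band("female", "hip",     c(5, 29, 41, 69, 48, 11)),
    band("male",   "forearm", c(24, 53, 25, 8, 1, 0)),
    band("female", "forearm", c(35, 151, 120, 61, 16, 0)),
    band("male",   "humerus", c(5, 22, 14, 9, 2, 0)),
    band("female", "humerus", c(7, 49, 39, 39, 11, 0)))
}

#' Moldova incidence table recomputed from the published counts
#'
#' Convenience wrapper: [incidence_from_counts()] on
#' [moldova_fracture_counts()] and [moldova_population()].
#'
#' @param level confidence level (default 0.95)
#' @return an `incidence_table`
#' @export
moldova_incidence <- function(level = 0.95) {
  incidence_from_counts(moldova_fracture_counts(), moldova_population(),
                        level = level)
}

#' Published predicted-vs-observed comparison for women (5-year bands)
#'
#' Forearm and humerus incidence in women aged 50-89, 5-year bands: the rate
#' predicted by scaling a reference (Malmo) site-to-hip pattern by the local
#' hip rate, next to the locally observed rate and its 95% CI. Rates per
#' 100,000/yr.
#'
#' @return data.frame with columns `sex`, `age_low`, `age_high`, `site`,
#'   `predicted`, `observed`, `ci_low`, `ci_high`
#' @export
moldova_predicted_observed <- function() {
  lo <- seq(50, 85, 5)
  data.frame(
    sex = "female",
    age_low = rep(lo, 2),
    age_high = rep(lo + 5, 2),
    site = rep(c("forearm", "humerus"), each = 8),
    predicted = c(447, 671, 590, 539, 606, 407, 468, 278,
                  133, 188, 132, 274, 257, 247, 220, 227),
    observed = c(412, 485, 705, 617, 560, 479, 407, 397,
                 99, 198, 250, 166, 324, 354, 296, 238),
    ci_low = c(324, 382, 558, 443, 397, 304, 203, 128,
               59, 134, 166, 83, 203, 206, 128, 49),
    ci_high = c(516, 607, 879, 838, 769, 720, 729, 925,
                156, 281, 361, 296, 491, 568, 584, 695))
}

#' Published national fracture burden projections, ages 50+ (2015-2050)
#'
#' Estimated annual counts of hip, forearm and humerus fractures in Moldova
#' obtained by applying the 2011-2012 regional rates to UN medium-variant
#' population projections, as printed. Kept as a documentation/check fixture:
#' reproducing it exactly needs the specific UN demography revision.
#'
#' @return data.frame with columns `year`, `sex`, `site`, `count`
#' @export
moldova_burden_projection <- function() {
  years <- c(2015, 2020, 2030, 2040, 2050)
  row <- function(sex, site, counts)
    data.frame(year = years, sex = sex, site = site, count = counts)
  rbind(
    row("male",   "hip",     c(1359, 1375, 1526, 1644, 1818)),
    row("female", "hip",     c(2381, 2617, 3177, 3813, 4359)),
    row("male",   "forearm", c(914, 875, 903, 1146, 1127)),
    row("female", "forearm", c(3789, 3986, 4258, 4772, 4953)),
    row("male",   "humerus", c(513, 513, 542, 651, 714)),
    row("female", "humerus", c(1528, 1571, 1806, 2041, 2113)))
}
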