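#' Read a population projection CSV
#'
#' Header `year,sex,age_low,age_high,persons,scenario`; empty `age_high` marks
#' the terminal open band. Each year must cover its full banding.
#'
#' @param path CSV path
#' @return data.frame of class `population_projection`
#' @export
read_projection_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$age_high <- suppressWarnings(as.numeric(df$age_high))
  population_projection(df)
}

#' Population projection constructor
#' @param df data.frame with columns `year`, `sex`, `age_low`, `age_high`,
#'   `persons`, and optionally `scenario`
#' @return data.frame of class `population_projection`
#' @export
population_projection <- function(df) {
  need <- c("year", "sex", "age_low", "age_high", "persons")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("projection missing columns: ",
                         paste(miss, collapse = ", "))
  df$age_high[is.na(df$age_high)] <- Inf
  if (any(df$persons < 0)) stop("persons must be >= 0")
  class(df) <- c("population_projection", "data.frame")
  df
}

#' Project annual fracture counts onto a population projection
#'
#' Applies fixed (or per-year, see [secular_trend_adjust()]) age/sex/site
#' incidence rates to projected population strata:
#' `count(year, sex, site) = sum over bands of rate x persons / 100,000`.
#' Unrounded expected counts are stored; rounding is for display only.
#'
#' Burden tables are conventionally restricted to ages 50 and older; lower
#' `min_age` to 40 to use the survey's full range.
#'
#' @param rates an `incidence_table` (band rows used; totals ignored). May
#'   carry a `year` column for time-varying rates, in which case each
#'   projection year uses its own rates.
#' @param projection a [population_projection()]
#' @param years calendar years to evaluate (default: all years present)
#' @param min_age drop strata below this age (default 50)
#' @return data.frame of class `burden_table` with columns `year`, `sex`,
#'   `site`, `expected_count`; attribute `"totals"` holds per-year grand
#'   totals.
#' @export
project_counts <- function(rates, projection, years = NULL, min_age = 50) {
  r <- as.data.frame(rates)
  if ("is_total" %in% names(r)) r <- r[!r$is_total, ]
  r <- r[r$age_low >= min_age, ]
  if (is.null(years)) years <- sort(unique(projection$year))
  p <- projection[projection$year %in% years & projection$age_low >= min_age, ]
  missing_years <- setdiff(years, unique(p$year))
  if (length(missing_years))
    stop("projection lacks years: ", paste(missing_years, collapse = ", "))

  time_varying <- "year" %in% names(r)
  out <- list()
  for (yr in years) {
    py <- p[p$year == yr, ]
    ry <- if (time_varying) r[r$year == yr, ] else r
    if (!nrow(ry)) stop("no rates available for year ", yr)
    for (site in unique(ry$site)) {
      for (s in unique(py$sex)) {
        ps <- py[py$sex == s, ]
        rs <- ry[ry$sex == s & ry$site == site, ]
        m <- match(ps$age_low, rs$age_low)
        if (any(is.na(m)))
          stop("projection strata without a rate: ",
               paste(paste(yr, s, ps$age_low[is.na(m)]), collapse = "; "))
        out[[length(out) + 1L]] <- data.frame(
          year = yr, sex = s, site = site,
          expected_count = sum(rs$rate[m] * ps$persons / 1e5))
      }
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$year, out$site, out$sex), ]
  rownames(out) <- NULL
  totals <- stats::aggregate(expected_count ~ year, data = out, FUN = sum)
  attr(out, "totals") <- totals
  class(out) <- c("burden_table", "data.frame")
  out
}

#' Percent change in projected burden between two calendar years
#'
#' `100 * (count(year1) - count(year0)) / count(year0)` over the strata picked
#' out by `selector` (all strata by default).
#'
#' @param burden a `burden_table` (or any data.frame with `year` and
#'   `expected_count`/`count`)
#' @param year0 baseline calendar year
#' @param year1 comparison calendar year
#' @param selector optional function taking the burden data.frame and
#'   returning a logical row mask (e.g. `function(b) b$site == "hip"`)
#' @return percentage change (positive = increase); `NA` with a warning when
#'   the baseline is zero
#' @export
percent_change <- function(burden, year0, year1, selector = NULL) {
  b <- as.data.frame(burden)
  cnt <- if ("expected_count" %in% names(b)) b$expected_count else b$count
  keep <- if (is.null(selector)) rep(TRUE, nrow(b)) else selector(b)
  c0 <- sum(cnt[keep & b$year == year0])
  c1 <- sum(cnt[keep & b$year == year1])
  if (!any(b$year == year0) || !any(b$year == year1))
    stop("both years must be present in the burden table")
  if (c0 == 0) {
    warning("baseline count is zero: percent change undefined")
    return(NA_real_)
  }
  100 * (c1 - c0) / c0
}

#' Apply a secular trend to age/sex-specific rates
#'
#' Compounds a constant annual drift onto every rate:
#' `rate(year) = rate(base_year) * (1 + drift)^(year - base_year)`. Returns a
#' stacked rates table with a `year` column, ready for [project_counts()]
#' sensitivity scenarios.
#'
#' @param rates an `incidence_table` (band rows used)
#' @param annual_drift fractional drift per year (e.g. 0.01); must be > -1
#' @param base_year year at which the input rates apply
#' @param years calendar years to generate
#' @return data.frame like `rates` with an added `year` column and drifted
#'   `rate`
#' @export
secular_trend_adjust <- function(rates, annual_drift, base_year, years) {
  if (annual_drift <= -1) stop("annual_drift must be > -1")
  r <- as.data.frame(rates)
  if ("is_total" %in% names(r)) r <- r[!r$is_total, ]
  out <- do.call(rbind, lapply(years, function(yr) {
    ri <- r
    ri$rate <- ri$rate * (1 + annual_drift)^(yr - base_year)
    ri$year <- yr
    ri
  }))
  rownames(out) <- NULL
  out
}
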