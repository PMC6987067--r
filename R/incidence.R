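#' Catchment population table
#'
#' Holds the population at risk per (sex, age band) together with the
#' observation period in years. Person-years for a stratum are
#' `count * period_years` — a mid-period population held constant over the
#' window, the usual convention when a multi-year count is divided by a single
#' census figure.
#'
#' @param df data.frame with columns `sex`, `age_low`, `age_high`, `count`
#'   (`age_high` may be `Inf`/`NA` for the terminal open band)
#' @param period_years positive observation duration in years
#' @return data.frame of class `population_table`
#' @export
population_table <- function(df, period_years) {
  need <- c("sex", "age_low", "age_high", "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("population table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!is.numeric(period_years) || period_years <= 0)
    stop("period_years must be positive")
  df$age_high[is.na(df$age_high)] <- Inf
  if (any(df$count < 0)) stop("population counts must be non-negative")
  if (anyDuplicated(df[, c("sex", "age_low")]))
    stop("one entry per (sex, band) required")
  attr(df, "period_years") <- period_years
  class(df) <- c("population_table", "data.frame")
  df
}

#' Read a population CSV
#'
#' Header `sex,age_low,age_high,count`; an empty `age_high` marks the
#' open-ended terminal band.
#'
#' @param path CSV path
#' @param period_years observation duration in years
#' @return a [population_table()]
#' @export
read_population_csv <- function(path, period_years) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$age_high <- suppressWarnings(as.numeric(df$age_high))
  population_table(df, period_years)
}

#' Person-years at risk in one stratum
#'
#' @param population a [population_table()]
#' @param sex "female" or "male"
#' @param age_low lower edge of the band
#' @return person-years = population count x period length
#' @export
person_years <- function(population, sex, age_low) {
  i <- which(population$sex == sex & population$age_low == age_low)
  if (length(i) != 1L)
    stop("missing population stratum: sex=", sex, ", band lower edge=", age_low)
  population$count[i] * attr(population, "period_years")
}

#' Exact Poisson (Garwood) confidence interval for an incidence rate
#'
#' Bounds for the Poisson mean from chi-square quantiles,
#' `low = qchisq(a/2, 2k)/2`, `high = qchisq(1-a/2, 2k+2)/2` with
#' `a = 1 - level`, scaled to events per 100,000 person-years. A zero count
#' has lower bound 0 and the one-sided exact upper bound. Exact intervals are
#' conservative: realised coverage is at or above the nominal level.
#'
#' @param count non-negative event count (vectorised)
#' @param person_years positive person-years at risk (vectorised)
#' @param level confidence level in (0,1); default 0.95
#' @param method "exact" (default) or "normal" for the Wald approximation
#'   `rate +/- z * sqrt(count)/PY` (floored at 0), kept behind a flag for
#'   comparison only.
#' @return data.frame with columns `low`, `high` in events per 100,000
#'   person-years
#' @export
poisson_ci <- function(count, person_years, level = 0.95,
                       method = c("exact", "normal")) {
  method <- match.arg(method)
  if (any(person_years <= 0)) stop("person_years must be positive")
  if (any(count < 0) || any(count != round(count)))
    stop("count must be a non-negative integer")
  if (level <= 0 || level >= 1) stop("level must be in (0,1)")
  a <- 1 - level
  if (method == "exact") {
    low <- ifelse(count == 0, 0, stats::qchisq(a / 2, 2 * count) / 2)
    high <- stats::qchisq(1 - a / 2, 2 * count + 2) / 2
  } else {
    z <- stats::qnorm(1 - a / 2)
    low <- pmax(0, count - z * sqrt(count))
    high <- count + z * sqrt(count)
  }
  data.frame(low = low / person_years * 1e5,
             high = high / person_years * 1e5)
}

#' Estimate age/sex/site-specific incidence
#'
#' Counts index fractures per (sex, band, site) stratum, divides by stratum
#' person-years and scales to events per 100,000 person-years, with an exact
#' Poisson confidence interval per cell. A pooled "total" row per (sex, site)
#' aggregates counts and person-years over bands *before* computing the rate,
#' so the total is the pooled rate, never a mean of band rates. Strata are
#' ordered by (sex, band lower edge) with totals last within each sex.
#'
#' Records whose age falls outside every band are routed to the
#' rejected-records report (attribute `"rejected"`), never silently dropped.
#'
#' @param records filtered, deduplicated records with a `site` column
#' @param population a [population_table()] covering every (sex, band)
#' @param site_groups list of [site_group()]s to tabulate (or site names)
#' @param banding an [age_banding()]; must match the population table's bands
#' @param level confidence level for the intervals
#' @param include_totals add the pooled per-sex totals row per site?
#' @return data.frame of class `incidence_table` with columns `sex`,
#'   `age_low`, `age_high`, `site`, `count`, `person_years`, `rate`,
#'   `ci_low`, `ci_high`, `is_total`; attributes `ci_level`, `banding`.
#' @export
estimate_incidence <- function(records, population,
                               site_groups = default_site_groups(),
                               banding = default_banding(), level = 0.95,
                               include_totals = TRUE) {
  validate_banding(banding)
  site_names <- vapply(site_groups, function(g)
    if (inherits(g, "site_group")) g$name else as.character(g), character(1))
  if (!"site" %in% names(records))
    stop("records must carry a 'site' column; run filter_records() first")

  band_idx <- find_band(records$age, banding)
  rejected <- records[is.na(band_idx), , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- "age_outside_banding"
  recs <- records[!is.na(band_idx), , drop = FALSE]
  band_idx <- band_idx[!is.na(band_idx)]

  sexes <- intersect(c("female", "male"), unique(population$sex))
  rows <- list()
  for (s in sexes) {
    for (site in site_names) {
      sel <- recs$sex == s & recs$site == site
      counts <- tabulate(band_idx[sel], nbins = nrow(banding))
      py <- vapply(banding$age_low, function(lo)
        person_years(population, s, lo), numeric(1))
      block <- data.frame(sex = s,
                          age_low = banding$age_low,
                          age_high = banding$age_high,
                          site = site,
                          count = counts,
                          person_years = py,
                          is_total = FALSE)
      if (include_totals) {
        block <- rbind(block,
                       data.frame(sex = s, age_low = min(banding$age_low),
                                  age_high = Inf, site = site,
                                  count = sum(counts),
                                  person_years = sum(py), is_total = TRUE))
      }
      rows[[length(rows) + 1L]] <- block
    }
  }
  out <- do.call(rbind, rows)
  out$rate <- out$count / out$person_years * 1e5
  ci <- poisson_ci(out$count, out$person_years, level = level)
  out$ci_low <- ci$low
  out$ci_high <- ci$high
  out <- out[order(out$sex, out$site, out$is_total, out$age_low),
             c("sex", "age_low", "age_high", "site", "count", "person_years",
               "rate", "ci_low", "ci_high", "is_total")]
  rownames(out) <- NULL
  attr(out, "ci_level") <- level
  attr(out, "banding") <- banding
  attr(out, "rejected") <- rejected
  class(out) <- c("incidence_table", "data.frame")
  out
}

#' Assemble an incidence table directly from stratum counts
#'
#' For published tables one has counts and populations rather than
#' line-listed records: this constructor computes rates and exact intervals
#' from pre-tabulated counts, with the same pooled-totals convention as
#' [estimate_incidence()].
#'
#' @param counts data.frame with columns `sex`, `age_low`, `age_high`, `site`,
#'   `count`
#' @param population a [population_table()]
#' @param level confidence level
#' @param include_totals add pooled per-sex totals rows?
#' @return an `incidence_table`
#' @export
incidence_from_counts <- function(counts, population, level = 0.95,
                                  include_totals = TRUE) {
  counts$age_high[is.na(counts$age_high)] <- Inf
  counts$person_years <- mapply(function(s, lo) person_years(population, s, lo),
                                counts$sex, counts$age_low)
  counts$is_total <- FALSE
  if (include_totals) {
    tot <- stats::aggregate(cbind(count, person_years) ~ sex + site,
                            data = counts, FUN = sum)
    tot$age_low <- min(counts$age_low)
    tot$age_high <- Inf
    tot$is_total <- TRUE
    counts <- rbind(counts[, c("sex", "age_low", "age_high", "site", "count",
                               "person_years", "is_total")],
                    tot[, c("sex", "age_low", "age_high", "site", "count",
                            "person_years", "is_total")])
  }
  counts$rate <- counts$count / counts$person_years * 1e5
  ci <- poisson_ci(counts$count, counts$person_years, level = level)
  counts$ci_low <- ci$low
  counts$ci_high <- ci$high
  out <- counts[order(counts$sex, counts$site, counts$is_total, counts$age_low),
                c("sex", "age_low", "age_high", "site", "count",
                  "person_years", "rate", "ci_low", "ci_high", "is_total")]
  rownames(out) <- NULL
  attr(out, "ci_level") <- level
  class(out) <- c("incidence_table", "data.frame")
  out
}

#' @export
print.incidence_table <- function(x, ...) {
  cat("incidence table:", sum(!x$is_total), "strata",
      sprintf("(%d%% exact Poisson CIs)\n",
              round(100 * (attr(x, "ci_level") %||% 0.95))))
  y <- as.data.frame(x)
  y$band <- band_label(y)
  y$band[y$is_total] <- paste0(y$age_low[y$is_total], "+ (total)")
  y$rate <- round(y$rate, 1)
  y$ci_low <- round(y$ci_low, 1)
  y$ci_high <- round(y$ci_high, 1)
  print(y[, c("sex", "band", "site", "count", "person_years", "rate",
              "ci_low", "ci_high")], row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Female/male fracture-count ratio for a site
#'
#' Ratio of total female to total male index-fracture counts. Both the exact
#' value and the conventional 1-decimal display rounding (half away from
#' zero) are returned. A zero male count yields an undefined-ratio result
#' (`NA`) rather than infinity.
#'
#' @param table an `incidence_table` with totals rows
#' @param site site group name
#' @return list with `ratio` (exact), `rounded` (1 dp), `female`, `male`
#'   counts
#' @export
sex_count_ratio <- function(table, site) {
  tot <- table[table$is_total & table$site == site, ]
  f <- tot$count[tot$sex == "female"]
  m <- tot$count[tot$sex == "male"]
  if (length(f) != 1L || length(m) != 1L)
    stop("totals rows for both sexes required for site ", site)
  if (m == 0) {
    warning("male count is zero: ratio undefined for site ", site)
    return(list(ratio = NA_real_, rounded = NA_real_, female = f, male = m))
  }
  r <- f / m
  list(ratio = r, rounded = round_half_up(r, 1), female = f, male = m)
}

# round half away from zero, robust to binary representation of x*10^d
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Display rounding for rate tables
#'
#' Conventional table formatting: rates of 1,000 or more to the nearest
#' integer, smaller rates to 1 decimal for hip and nearest integer for other
#' sites. A formatting convenience only — stored values are never rounded.
#'
#' @param rate numeric rates per 100,000
#' @param site site names (hip gets 1 dp below 1,000)
#' @return character vector
#' @export
format_rate <- function(rate, site) {
  dp <- ifelse(rate >= 1000, 0, ifelse(site == "hip", 1, 0))
  mapply(function(r, d) formatC(round_half_up(r, d), format = "f", digits = d),
         rate, dp)
}

#' Write an incidence table to CSV
#'
#' Header `sex,age_low,age_high,site,count,person_years,rate_per_1e5,ci_low,
#' ci_high` (unrounded values; open-ended upper edges written empty).
#'
#' @param table an `incidence_table`
#' @param path output path
#' @param include_totals write the pooled totals rows too?
#' @return `path`, invisibly
#' @export
write_incidence_csv <- function(table, path, include_totals = FALSE) {
  y <- as.data.frame(table)
  if (!include_totals) y <- y[!y$is_total, ]
  out <- data.frame(sex = y$sex, age_low = y$age_low,
                    age_high = ifelse(is.infinite(y$age_high), "", y$age_high),
                    site = y$site, count = y$count,
                    person_years = y$person_years, rate_per_1e5 = y$rate,
                    ci_low = y$ci_low, ci_high = y$ci_high)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an incidence table written by [write_incidence_csv()]
#' @param path CSV path
#' @return an `incidence_table` (band rows only, `is_total = FALSE`)
#' @export
read_incidence_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$age_high <- suppressWarnings(as.numeric(df$age_high))
  df$age_high[is.na(df$age_high)] <- Inf
  names(df)[names(df) == "rate_per_1e5"] <- "rate"
  df$is_total <- FALSE
  class(df) <- c("incidence_table", "data.frame")
  df
}
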