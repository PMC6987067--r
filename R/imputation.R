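#' Impute a non-hip fracture rate from a reference site-to-hip ratio
#'
#' The indirect ("Malmo ratio") method: where a target population has reliable
#' hip fracture rates but no data for another site, assume the age- and
#' sex-specific site-to-hip ratio of a well-characterised reference
#' population transfers, so
#' `rate_target(site) = rate_target(hip) * rate_ref(site) / rate_ref(hip)`.
#'
#' @param hip_target target-population hip rate (per 100,000/yr); vectorised
#' @param hip_ref reference-population hip rate, same stratum; must be > 0
#' @param site_ref reference-population rate at the site being imputed
#' @return imputed target-population site rate, same units
#' @export
impute_site_rate <- function(hip_target, hip_ref, site_ref) {
  if (any(hip_ref <= 0))
    stop("reference hip rate must be positive in every stratum")
  if (any(hip_target < 0) || any(site_ref < 0)) stop("rates must be >= 0")
  hip_target * site_ref / hip_ref
}

#' Read a reference rates CSV
#'
#' Header `sex,age_low,age_high,site,rate_per_1e5,source`; empty `age_high`
#' marks an open-ended band. A hip entry must be present in every (sex, band)
#' stratum that carries any other-site entry.
#'
#' @param path CSV path
#' @return data.frame of class `reference_rates`
#' @export
read_reference_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "rate_per_1e5"] <- "rate"
  reference_rates(df)
}

#' Reference rate table constructor
#' @param df data.frame with columns `sex`, `age_low`, `age_high`, `site`,
#'   `rate` (per 100,000/yr) and optionally `source`
#' @return data.frame of class `reference_rates`
#' @export
reference_rates <- function(df) {
  need <- c("sex", "age_low", "age_high", "site", "rate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("reference rates missing columns: ",
                         paste(miss, collapse = ", "))
  df$age_high[is.na(df$age_high)] <- Inf
  if (any(df$rate < 0)) stop("reference rates must be >= 0")
  nonhip <- df[df$site != "hip", c("sex", "age_low")]
  hip <- df[df$site == "hip", c("sex", "age_low")]
  key <- function(x) paste(x$sex, x$age_low)
  orphan <- setdiff(unique(key(nonhip)), key(hip))
  if (length(orphan))
    stop("reference strata lacking a hip entry: ",
         paste(orphan, collapse = "; "))
  class(df) <- c("reference_rates", "data.frame")
  df
}

#' Impute site-specific rates for a whole incidence table
#'
#' Applies [impute_site_rate()] stratum by stratum: for each (sex, band) of
#' the target hip table, the reference hip and site rates of the matching
#' stratum scale the target hip rate. If the reference uses a finer banding
#' than the target (say 5-year vs 10-year), aggregate it first with
#' [aggregate_reference_bands()]; matching here is by identical
#' (sex, age_low).
#'
#' @param hip_rates an `incidence_table` restricted to hip (band rows used)
#' @param reference a [reference_rates()] table
#' @param sites character vector of site names to impute
#' @return data.frame with columns `sex`, `age_low`, `age_high`, `site`,
#'   `predicted` (per 100,000/yr)
#' @export
impute_rates <- function(hip_rates, reference, sites = c("forearm", "humerus")) {
  hip <- hip_rates[hip_rates$site == "hip" & !hip_rates$is_total, ]
  if (!nrow(hip)) stop("no hip band rows in hip_rates")
  out <- list()
  for (site in sites) {
    for (i in seq_len(nrow(hip))) {
      s <- hip$sex[i]; lo <- hip$age_low[i]
      rh <- reference$rate[reference$sex == s & reference$age_low == lo &
                             reference$site == "hip"]
      rs <- reference$rate[reference$sex == s & reference$age_low == lo &
                             reference$site == site]
      if (length(rh) != 1L || length(rs) != 1L)
        stop("reference stratum missing for sex=", s, ", band ", lo,
             ", site ", site)
      out[[length(out) + 1L]] <- data.frame(
        sex = s, age_low = lo, age_high = hip$age_high[i], site = site,
        predicted = impute_site_rate(hip$rate[i], rh, rs))
    }
  }
  do.call(rbind, out)
}

#' Aggregate reference rates from a finer to a coarser banding
#'
#' Person-year-weighted mean of the finer-band rates within each coarse band:
#' equivalent to pooling the implied counts and person-years. Weights come
#' from a population table on the finer banding; with `weights = NULL` the
#' bands are weighted equally (a declared approximation when no reference
#' population is available).
#'
#' @param reference a [reference_rates()] on the finer banding
#' @param banding the target (coarser) [age_banding()]
#' @param weights optional [population_table()] on the finer banding
#' @return a [reference_rates()] on the coarser banding
#' @export
aggregate_reference_bands <- function(reference, banding, weights = NULL) {
  validate_banding(banding)
  idx <- find_band(reference$age_low, banding)
  if (any(is.na(idx)))
    stop("reference bands outside the target banding: ",
         paste(unique(reference$age_low[is.na(idx)]), collapse = ", "))
  # a fine band must not straddle a coarse edge
  idx_hi <- find_band(pmin(reference$age_high, banding$age_low[nrow(banding)] +
                             1) - 1e-9, banding)
  if (any(idx != idx_hi, na.rm = TRUE))
    stop("a reference band straddles a target band edge")
  w <- if (is.null(weights)) rep(1, nrow(reference)) else {
    mapply(function(s, lo) person_years(weights, s, lo),
           reference$sex, reference$age_low)
  }
  key <- data.frame(sex = reference$sex, band = idx, site = reference$site)
  agg <- stats::aggregate(cbind(wr = reference$rate * w, w = w),
                          by = key, FUN = sum)
  out <- data.frame(sex = agg$sex,
                    age_low = banding$age_low[agg$band],
                    age_high = banding$age_high[agg$band],
                    site = agg$site,
                    rate = agg$wr / agg$w)
  out <- out[order(out$sex, out$site, out$age_low), ]
  rownames(out) <- NULL
  reference_rates(out)
}

#' Compare predicted with observed incidence, stratum by stratum
#'
#' Joins a predicted-rate table to an observed `incidence_table` on
#' (sex, age_low, site) and flags whether each predicted rate falls inside the
#' observed exact Poisson confidence interval (boundaries inclusive).
#' Unmatched strata on either side are reported in the `"unmatched"`
#' attribute, and in/out summary counts in the `"summary"` attribute.
#'
#' By convention the check is run in the sex with the larger fracture counts
#' (usually women); pass both sexes' tables to widen it.
#'
#' @param predicted data.frame with `sex`, `age_low`, `site`, `predicted`
#' @param observed an `incidence_table` (band rows are used)
#' @return data.frame with columns `sex`, `age_low`, `age_high`, `site`,
#'   `predicted`, `observed`, `ci_low`, `ci_high`, `within_ci`
#' @export
compare_predicted_observed <- function(predicted, observed) {
  obs <- as.data.frame(observed)
  if ("is_total" %in% names(obs)) obs <- obs[!obs$is_total, ]
  if (!"observed" %in% names(obs)) {
    names(obs)[names(obs) == "rate"] <- "observed"
  }
  pk <- paste(predicted$sex, predicted$age_low, predicted$site)
  ok <- paste(obs$sex, obs$age_low, obs$site)
  m <- match(pk, ok)
  rows <- data.frame(sex = predicted$sex,
                     age_low = predicted$age_low,
                     age_high = obs$age_high[m],
                     site = predicted$site,
                     predicted = predicted$predicted,
                     observed = obs$observed[m],
                     ci_low = obs$ci_low[m],
                     ci_high = obs$ci_high[m])
  unmatched <- c(pk[is.na(m)], setdiff(ok, pk))
  rows <- rows[!is.na(m), , drop = FALSE]
  rows$within_ci <- rows$ci_low <= rows$predicted &
    rows$predicted <= rows$ci_high
  attr(rows, "unmatched") <- unmatched
  attr(rows, "summary") <- c(within = sum(rows$within_ci),
                             outside = sum(!rows$within_ci))
  rows
}
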