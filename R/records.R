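#' Read line-listed fracture records
#'
#' Expects a CSV with header
#' `person_id,sex,age,event_date,icd10,energy,resident` — one row per
#' admission. `event_date` must be ISO-8601 (`YYYY-MM-DD`); `sex` is
#' "female"/"male"; `energy` is "low"/"high"/"unknown"; `resident` is
#' TRUE/FALSE.
#'
#' @param path path to the CSV file
#' @return data.frame of fracture records
#' @export
read_records_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("person_id", "sex", "age", "event_date", "icd10", "energy",
            "resident")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("records CSV missing columns: ",
                         paste(miss, collapse = ", "))
  df$event_date <- as.Date(df$event_date)
  df$resident <- as.logical(df$resident)
  validate_records(df)
  df
}

validate_records <- function(records) {
  need <- c("person_id", "sex", "age", "event_date", "icd10", "energy")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(!is.na(records$age) & records$age < 0)) stop("negative ages in records")
  bad_sex <- setdiff(unique(records$sex), c("female", "male"))
  if (length(bad_sex)) stop("sex must be 'female' or 'male'; found: ",
                            paste(bad_sex, collapse = ", "))
  bad_en <- setdiff(unique(records$energy), c("low", "high", "unknown"))
  if (length(bad_en)) stop("energy must be low/high/unknown; found: ",
                           paste(bad_en, collapse = ", "))
  invisible(records)
}

#' Apply survey inclusion rules to fracture records
#'
#' Retains records that (i) carry a low-energy mechanism (optionally also
#' `unknown`, mirroring radiograph-verified fallback inclusion), (ii) are aged
#' `min_age` or older at the event (boundary inclusive), (iii) fall inside the
#' observation window, and (iv) carry an ICD-10 code belonging to one of the
#' requested site groups. Input order is preserved, the input is not modified,
#' and nothing is silently dropped: excluded rows are returned in a
#' rejected-records report attached as an attribute, each with its exclusion
#' reason, retrievable with [rejected_records()]. Filter tallies are attached
#' as attribute `"tallies"`.
#'
#' Non-residents are included by default, as is usual when permanent residence
#' is not an inclusion criterion; set `residents_only = TRUE` to restrict.
#'
#' @param records data.frame of fracture records (see [read_records_csv()])
#' @param site_groups list of [site_group()] objects
#' @param min_age minimum age in whole years, inclusive
#' @param window length-2 Date vector: first and last admissible event date
#'   (both inclusive)
#' @param include_unknown_energy retain records with `energy == "unknown"`?
#' @param residents_only drop non-resident records?
#' @return the retained records, with an added `site` column naming the
#'   matched site group; attributes `"rejected"` (data.frame with a `reason`
#'   column) and `"tallies"` (named integer vector).
#' @export
filter_records <- function(records, site_groups = default_site_groups(),
                           min_age = 40, window,
                           include_unknown_energy = FALSE,
                           residents_only = FALSE) {
  validate_records(records)
  validate_site_groups(site_groups)
  if (missing(window) || length(window) != 2L)
    stop("window must be two dates: c(first, last)")
  window <- as.Date(window)
  if (is.na(window[1L]) || is.na(window[2L]) || window[1L] > window[2L])
    stop("window is not a well-formed date interval")
  if (min_age < 0) stop("min_age must be >= 0")

  site <- classify_site(records$icd10, site_groups)
  ok_energy <- records$energy == "low" |
    (include_unknown_energy & records$energy == "unknown")
  ok_age <- !is.na(records$age) & records$age >= min_age
  ok_window <- !is.na(records$event_date) &
    records$event_date >= window[1L] & records$event_date <= window[2L]
  ok_site <- !is.na(site)
  ok_resident <- if (residents_only) {
    !is.na(records$resident) & records$resident
  } else rep(TRUE, nrow(records))

  keep <- ok_energy & ok_age & ok_window & ok_site & ok_resident
  reason <- rep(NA_character_, nrow(records))
  reason[!ok_site]     <- "site_code_unclassified"
  reason[!ok_window]   <- "outside_window"
  reason[!ok_age]      <- "below_min_age"
  reason[!ok_energy]   <- "not_low_energy"
  reason[!ok_resident] <- "non_resident"

  kept <- records[keep, , drop = FALSE]
  kept$site <- site[keep]
  rejected <- records[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]

  tallies <- c(input = nrow(records), retained = nrow(kept),
               not_low_energy = sum(!ok_energy),
               below_min_age = sum(!ok_age),
               outside_window = sum(!ok_window),
               site_code_unclassified = sum(!ok_site),
               non_resident_excluded = sum(!ok_resident))
  attr(kept, "rejected") <- rejected
  attr(kept, "tallies") <- tallies
  kept
}

#' Rejected-records report from a filtering step
#' @param records the value returned by [filter_records()] or
#'   [estimate_incidence()]
#' @return data.frame of excluded records with a `reason` column
#' @export
rejected_records <- function(records) attr(records, "rejected")

#' Drop repeat admissions for the same person and site
#'
#' A person's first admission for a given site group is their index fracture;
#' later admissions for the same site within the window are duplicates and are
#' removed. Records at different sites for the same person are all kept. Ties
#' on date are broken by stable input order. Records with a missing
#' `person_id` cannot be deduplicated and are kept; their number is attached
#' as attribute `"n_missing_id"` and reported in a warning.
#'
#' @param records filtered records carrying a `site` column (see
#'   [filter_records()])
#' @return deduplicated records, input order preserved; attribute
#'   `"n_duplicates_removed"` gives the count removed.
#' @export
deduplicate <- function(records) {
  if (!"site" %in% names(records))
    stop("records must carry a 'site' column; run filter_records() first")
  n <- nrow(records)
  if (n == 0L) {
    attr(records, "n_duplicates_removed") <- 0L
    attr(records, "n_missing_id") <- 0L
    return(records)
  }
  missing_id <- is.na(records$person_id) | records$person_id == ""
  keep <- rep(TRUE, n)
  idx <- which(!missing_id)
  if (length(idx)) {
    key <- paste(records$person_id[idx], records$site[idx], sep = "\r")
    # earliest date wins; stable order breaks date ties
    o <- idx[order(key, records$event_date[idx], idx)]
    okey <- paste(records$person_id[o], records$site[o], sep = "\r")
    keep[o[duplicated(okey)]] <- FALSE
  }
  out <- records[keep, , drop = FALSE]
  attr(out, "n_duplicates_removed") <- n - nrow(out)
  attr(out, "n_missing_id") <- sum(missing_id)
  if (any(missing_id))
    warning(sum(missing_id), " record(s) with missing person_id kept undeduplicated")
  out
}
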