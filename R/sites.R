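#' Fracture site groups (ICD-10 code sets)
#'
#' A site group names a skeletal site and the set of ICD-10 codes that map to
#' it. Code sets must be disjoint across the groups in use. Codes are
#' normalised (upper case, internal whitespace stripped) so that variants such
#' as "S 42.2" and "s42.2" match.
#'
#' @param name site name, e.g. "hip"
#' @param codes character vector of ICD-10 codes
#' @return a list of class `site_group` with elements `name` and `codes`
#' @export
site_group <- function(name, codes) {
  structure(list(name = as.character(name), codes = normalise_icd10(codes)),
            class = "site_group")
}

#' @export
print.site_group <- function(x, ...) {
  cat("site group '", x$name, "': ", paste(x$codes, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

normalise_icd10 <- function(codes) {
  toupper(gsub("[[:space:]]+", "", as.character(codes)))
}

#' Standard low-energy fracture site groups
#'
#' The conventional ICD-10 sets for osteoporotic fracture surveillance:
#' hip (S72.0, S72.1, S72.2), distal forearm (S52.5, S52.6) and proximal
#' humerus (S42.2).
#'
#' @return named list of `site_group` objects
#' @export
default_site_groups <- function() {
  list(hip     = site_group("hip",     c("S72.0", "S72.1", "S72.2")),
       forearm = site_group("forearm", c("S52.5", "S52.6")),
       humerus = site_group("humerus", c("S42.2")))
}

#' Classify ICD-10 codes into site groups
#'
#' @param codes character vector of ICD-10 codes (any spacing/case)
#' @param site_groups list of `site_group` objects
#' @return character vector of group names; `NA` for codes matching no group
#' @export
classify_site <- function(codes, site_groups = default_site_groups()) {
  validate_site_groups(site_groups)
  codes <- normalise_icd10(codes)
  out <- rep(NA_character_, length(codes))
  for (g in site_groups) out[codes %in% g$codes] <- g$name
  out
}

validate_site_groups <- function(site_groups) {
  all_codes <- unlist(lapply(site_groups, `[[`, "codes"))
  if (anyDuplicated(all_codes))
    stop("site group code sets must be disjoint; duplicated: ",
         paste(unique(all_codes[duplicated(all_codes)]), collapse = ", "))
  invisible(site_groups)
}
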