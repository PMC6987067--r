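#' Age banding schemes
#'
#' An age banding is a data frame with columns `age_low` (inclusive) and
#' `age_high` (exclusive); `Inf` in `age_high` marks the terminal open-ended
#' band. Bands must be non-overlapping and contiguous. The conventional
#' scheme for adult fracture surveys is 10-year bands from 40 with an
#' open-ended 90+ band.
#'
#' @param breaks integer vector of band lower edges, increasing.
#' @param open_end if `TRUE` (default) the last break opens an unbounded
#'   terminal band; otherwise the last break is the exclusive upper limit of
#'   the previous band.
#' @return a data.frame of class `age_banding` with columns `age_low`,
#'   `age_high`.
#' @examples
#' age_banding(seq(40, 90, 10))           # 40-49 ... 80-89, 90+
#' age_banding(seq(50, 90, 5))            # 5-year bands from 50
#' @export
age_banding <- function(breaks, open_end = TRUE) {
  breaks <- as.numeric(breaks)
  if (length(breaks) < 1L || is.unsorted(breaks, strictly = TRUE))
    stop("breaks must be strictly increasing")
  if (open_end) {
    lows <- breaks
    highs <- c(breaks[-1L], Inf)
  } else {
    if (length(breaks) < 2L) stop("need at least two breaks when open_end = FALSE")
    lows <- breaks[-length(breaks)]
    highs <- breaks[-1L]
  }
  out <- data.frame(age_low = lows, age_high = highs)
  class(out) <- c("age_banding", "data.frame")
  out
}

#' Default 10-year adult banding (40-49 ... 80-89, 90+)
#' @return an `age_banding`
#' @export
default_banding <- function() age_banding(seq(40, 90, 10))

#' Human-readable band labels ("40-49", "90+")
#' @param banding an `age_banding` or data frame with age_low/age_high
#' @return character vector
#' @export
band_label <- function(banding) {
  ifelse(is.infinite(banding$age_high),
         paste0(banding$age_low, "+"),
         paste0(banding$age_low, "-", banding$age_high - 1))
}

#' Locate the band containing each age
#'
#' Bands are closed-open `[age_low, age_high)`.
#'
#' @param age numeric vector of ages in years
#' @param banding an `age_banding`
#' @return integer vector of row indices into `banding`; `NA` where an age
#'   falls outside all bands.
#' @export
find_band <- function(age, banding) {
  idx <- rep(NA_integer_, length(age))
  for (i in seq_len(nrow(banding))) {
    hit <- !is.na(age) & age >= banding$age_low[i] & age < banding$age_high[i]
    idx[hit] <- i
  }
  idx
}

validate_banding <- function(banding) {
  if (!all(c("age_low", "age_high") %in% names(banding)))
    stop("banding needs columns age_low, age_high")
  if (any(banding$age_low >= banding$age_high))
    stop("each band needs age_low < age_high")
  o <- order(banding$age_low)
  b <- banding[o, , drop = FALSE]
  if (nrow(b) > 1L && any(b$age_high[-nrow(b)] != b$age_low[-1L]))
    stop("bands must be contiguous and non-overlapping")
  invisible(banding)
}
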