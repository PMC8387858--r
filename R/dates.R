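# Calendar conventions used throughout:
#   * date intervals are half-open [start, end): a same-day interval is empty
#   * person-years use the 365.25-day year
#   * "2 years" of look-back/coverage is 730 days
#   * calendar-year arithmetic is calendrical; 29 Feb maps to 28 Feb in
#     non-leap target years

DAYS_PER_YEAR <- 365.25
TWO_YEARS_DAYS <- 730L
MIN_FOLLOW_UP_DAYS <- 30.5

#' Five childhood age bands
#'
#' Band boundaries at ages 1, 5, 10, 14 and 18; bands are half-open
#' `[lower, upper)` in age so no day of follow-up is counted twice.
#'
#' @return data.frame with columns `age_band`, `lower`, `upper` (years).
#' @export
age_bands <- function() {
  data.frame(
    age_band = c("<1", "1-4", "5-9", "10-13", "14-17"),
    lower = c(0L, 1L, 5L, 10L, 14L),
    upper = c(1L, 5L, 10L, 14L, 18L),
    stringsAsFactors = FALSE
  )
}

#' @rdname age_bands
#' @export
age_band_levels <- function() age_bands()$age_band

# proleptic-Gregorian civil-date arithmetic (era-based integer algorithms),
# vectorised and much faster than POSIXlt round trips
days_from_civil <- function(y, m, d) {
  y <- y - (m <= 2L)
  era <- ifelse(y >= 0L, y, y - 399L) %/% 400L
  yoe <- y - era * 400L
  doy <- (153L * (m + ifelse(m > 2L, -3L, 9L)) + 2L) %/% 5L + d - 1L
  doe <- yoe * 365L + yoe %/% 4L - yoe %/% 100L + doy
  era * 146097L + doe - 719468L
}

civil_from_days <- function(z) {
  z <- z + 719468L
  era <- ifelse(z >= 0L, z, z - 146096L) %/% 146097L
  doe <- z - era * 146097L
  yoe <- (doe - doe %/% 1460L + doe %/% 36524L - doe %/% 146096L) %/% 365L
  y <- yoe + era * 400L
  doy <- doe - (365L * yoe + yoe %/% 4L - yoe %/% 100L)
  mp <- (5L * doy + 2L) %/% 153L
  d <- doy - (153L * mp + 2L) %/% 5L + 1L
  m <- mp + ifelse(mp < 10L, 3L, -9L)
  list(year = as.integer(y + (m <= 2L)), month = as.integer(m),
       day = as.integer(d))
}

is_leap <- function(y) (y %% 4L == 0L & y %% 100L != 0L) | y %% 400L == 0L

#' Add whole calendar years to dates
#'
#' Calendrical addition: the month and day are kept; a 29 February source date
#' maps to 28 February when the target year is not a leap year. Vectorised in
#' both arguments.
#'
#' @param date a `Date` vector.
#' @param n integer vector of years to add (recycled).
#' @return a `Date` vector.
#' @export
add_years <- function(date, n) {
  cv <- civil_from_days(as.integer(as_date(date)))
  y <- cv$year + as.integer(n)
  d <- ifelse(cv$month == 2L & cv$day == 29L & !is_leap(y), 28L, cv$day)
  as.Date(days_from_civil(y, cv$month, d), origin = "1970-01-01")
}

#' Calendar year of dates
#' @param date a `Date` vector.
#' @return integer year.
#' @export
year_of <- function(date) civil_from_days(as.integer(as_date(date)))$year

#' Convert a day count to person-years
#' @param days numeric vector of day counts.
#' @return numeric person-years (`days / 365.25`).
#' @export
days_to_years <- function(days) as.numeric(days) / DAYS_PER_YEAR

as_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  # an all-missing column (e.g. read from a header-only CSV) arrives logical
  if (is.logical(x) && all(is.na(x))) {
    return(as.Date(rep(NA_real_, length(x)), origin = "1970-01-01"))
  }
  as.Date(x)
}

# max/min over date columns ignoring NA, preserving Date class
pmax_date <- function(...) {
  args <- lapply(list(...), function(x) as.numeric(as_date(x)))
  as.Date(do.call(pmax, c(args, list(na.rm = TRUE))), origin = "1970-01-01")
}

pmin_date <- function(...) {
  args <- lapply(list(...), function(x) as.numeric(as_date(x)))
  as.Date(do.call(pmin, c(args, list(na.rm = TRUE))), origin = "1970-01-01")
}
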