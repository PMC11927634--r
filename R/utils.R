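# Shared helpers: calendar indexing, barometric pressure, input checks.

#' Day-of-year on a fixed 365-slot calendar
#'
#' Maps dates onto day-of-year indices 1-365. In leap years Feb 29 shares
#' slot 59 with Feb 28 and all later days are shifted down by one, so every
#' calendar day occupies the same slot in every year. This keeps day-specific
#' climatology arrays a fixed length.
#'
#' @param dates a `Date` vector.
#' @return integer vector in 1..365.
#' @export
#' @examples
#' doy365(as.Date(c("2020-02-28", "2020-02-29", "2020-03-01")))
doy365 <- function(dates) {
  stopifnot(inherits(dates, "Date"))
  d <- lubridate::yday(dates)
  leap <- lubridate::leap_year(dates)
  d[leap & d >= 60] <- d[leap & d >= 60] - 1L
  as.integer(d)
}

#' Surface air pressure from elevation
#'
#' Standard-atmosphere barometric formula, returning pressure in atmospheres.
#' Used as a deterministic proxy when reanalysis surface pressure is absent.
#'
#' @param elevation_m elevation above sea level in metres.
#' @return pressure in atm.
#' @export
pressure_from_elevation <- function(elevation_m) {
  stopifnot(is.numeric(elevation_m), all(elevation_m >= -500), all(elevation_m < 11000))
  (1 - 2.25577e-5 * elevation_m)^5.25588
}

# internal: validate that a data frame has the named columns
check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(
      sprintf("%s is missing required column(s): %s", what, paste(missing, collapse = ", ")),
      class = "lakedo_error_columns"
    )
  }
  invisible(df)
}

# internal: derive a per-lake RNG substream seed (kept < 2^31)
lake_seed <- function(seed, lake_index, salt = 0L) {
  (as.integer(seed) + 104729L * as.integer(lake_index) + 9973L * as.integer(salt)) %% 2147483647L
}

# internal: numeric index encoded in a lake id like "L0042"
lake_index_of <- function(lake_id) {
  idx <- suppressWarnings(as.integer(gsub("[^0-9]", "", lake_id)))
  ifelse(is.na(idx), abs(vapply(lake_id, function(x) sum(utf8ToInt(x)), 1)) %% 10000L, idx)
}
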