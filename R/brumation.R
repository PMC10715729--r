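#' Brumation days in one calendar year
#'
#' Implements the activity-period rule used to turn a daily temperature
#' series and a species' activity threshold into an annual brumation
#' estimate. The active period starts on the first day of the first run of
#' at least `persistence` consecutive days with mean temperature strictly
#' above the threshold, and ends on the last day before the terminal run of
#' days at or below the threshold that persists to the end of the calendar
#' year. Brumation days = days in the year minus the active-period length.
#' If no qualifying run exists the species is considered inactive all year.
#'
#' A day exactly at the threshold counts as inactive (below); see
#' `above_strict` to flip that convention.
#'
#' @param series Data frame with columns `date` (Date) and `temp_c`.
#' @param entry_temp Threshold (deg C) at which brumation begins; ends the
#'   active period.
#' @param emergence_temp Threshold at which activity resumes; starts the
#'   active period. Defaults to `entry_temp`.
#' @param year Calendar year to evaluate.
#' @param persistence Minimum run length (days) above threshold that opens
#'   the active period; default 5.
#' @param buffer Deg C subtracted from both thresholds (0, 2 or 4 in the
#'   study design) to emulate thermal buffering in burrows.
#' @param above_strict If `TRUE` (default) a day is active when
#'   `temp > threshold`; days at the threshold are inactive.
#' @return Integer number of brumation days in `year`.
#' @export
annual_brumation_days <- function(series, entry_temp, emergence_temp = entry_temp,
                                  year, persistence = 5L, buffer = 0,
                                  above_strict = TRUE) {
  if (!is.numeric(persistence) || persistence < 1) {
    stop("persistence must be a positive integer")
  }
  persistence <- as.integer(persistence)
  stopifnot(is.data.frame(series), all(c("date", "temp_c") %in% names(series)))
  dates <- as.Date(series$date)
  keep <- as.integer(format(dates, "%Y")) == year
  d <- dates[keep]
  temps <- series$temp_c[keep]
  o <- order(d)
  d <- d[o]; temps <- temps[o]
  n_days <- days_in_year(year)
  expected <- seq(as.Date(sprintf("%d-01-01", year)),
                  as.Date(sprintf("%d-12-31", year)), by = "day")
  if (length(d) != n_days || any(d != expected)) {
    gaps <- expected[!expected %in% d]
    stop("temperature series has missing days in ", year, ": ",
         paste(utils::head(format(gaps, "%Y-%m-%d"), 5), collapse = ", "),
         if (length(gaps) > 5) " ..." else "")
  }
  if (anyNA(temps)) stop("temperature series contains NA values in ", year)
  thr_start <- emergence_temp - buffer
  thr_end <- entry_temp - buffer
  active_len <- active_period_length(temps, thr_start, thr_end,
                                     persistence, above_strict)
  n_days - active_len
}

days_in_year <- function(year) {
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  ifelse(leap, 366L, 365L)
}

active_period_length <- function(temps, thr_start, thr_end, persistence,
                                 above_strict = TRUE) {
  n <- length(temps)
  above_start <- if (above_strict) temps > thr_start else temps >= thr_start
  above_end <- if (above_strict) temps > thr_end else temps >= thr_end
  # first run of >= persistence active days (emergence threshold)
  r <- rle(above_start)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= persistence)
  if (length(ok) == 0) return(0L)
  first_day <- starts[ok[1]]
  # terminal run of inactive days (entry threshold) persisting to year end
  last_day <- n
  if (!above_end[n]) {
    r2 <- rle(above_end)
    tail_len <- r2$lengths[length(r2$lengths)]
    last_day <- n - tail_len
  }
  if (last_day < first_day) return(0L)
  last_day - first_day + 1L
}

#' Brumation days with a buffered threshold
#'
#' Convenience wrapper around [annual_brumation_days()] subtracting a 2 or
#' 4 deg C buffer from the activity thresholds, emulating the thermal
#' shelter of underground burrows relative to air temperature.
#'
#' @inheritParams annual_brumation_days
#' @export
buffered_days <- function(series, entry_temp, emergence_temp = entry_temp,
                          year, buffer, persistence = 5L) {
  if (!buffer %in% c(2, 4)) stop("buffer must be 2 or 4")
  annual_brumation_days(series, entry_temp, emergence_temp, year,
                        persistence = persistence, buffer = buffer)
}

#' Species-level brumation estimate over several years
#'
#' @inheritParams annual_brumation_days
#' @param years Integer vector of calendar years (the study used 2012-2016).
#' @return List with `per_year_days`, `mean_days` and `status`
#'   (from [classify_brumation()]).
#' @export
brumation_estimate <- function(series, entry_temp, emergence_temp = entry_temp,
                               years, persistence = 5L, buffer = 0) {
  per_year <- vapply(years, function(y) {
    annual_brumation_days(series, entry_temp, emergence_temp, y,
                          persistence = persistence, buffer = buffer)
  }, numeric(1))
  names(per_year) <- years
  m <- mean(per_year)
  list(per_year_days = per_year, mean_days = m,
       status = classify_brumation(m))
}

#' Classify a species as brumating or not
#'
#' Species with a mean of 27 or fewer days below their activity threshold
#' are conservatively classified as non-brumating: ground microclimates
#' buffer air-temperature fluctuations and frogs tolerate short cold spells
#' without sustained dormancy.
#'
#' @param mean_days Mean annual days below threshold.
#' @return `"brumating"` or `"non-brumating"`.
#' @export
classify_brumation <- function(mean_days) {
  ifelse(mean_days <= 27, "non-brumating", "brumating")
}

#' Coefficient of variation
#'
#' Sample standard deviation over the mean, used to summarise annual
#' fluctuation in monthly climate normals. For temperature in deg C the CV
#' is ill-defined when the mean is at or below zero, so a warning is issued
#' there. The temperature CV is log-transformed downstream at the analysis
#' stage, not here.
#'
#' @param values Numeric vector (e.g. 12 monthly means).
#' @return The CV.
#' @export
climate_cv <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 values for a CV")
  m <- mean(values)
  if (m <= 0) warning("mean <= 0: CV is ill-defined across zero")
  stats::sd(values) / m
}

#' Dry-season length (P2T rule)
#'
#' Number of months in which total precipitation (mm) is strictly less than
#' twice the mean temperature (deg C).
#'
#' @param monthly_precip 12 monthly precipitation totals (mm).
#' @param monthly_temp 12 monthly mean temperatures (deg C).
#' @return Integer count of dry months (0-12).
#' @export
dry_season_p2t <- function(monthly_precip, monthly_temp) {
  if (length(monthly_precip) != 12 || length(monthly_temp) != 12) {
    stop("need exactly 12 monthly values for precipitation and temperature")
  }
  sum(monthly_precip < 2 * monthly_temp)
}
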