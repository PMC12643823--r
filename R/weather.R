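#' Wet-bulb temperature from the Stull (2011) empirical formula
#'
#' Approximates wet-bulb temperature at standard sea-level pressure from air
#' temperature and relative humidity. The fit is accurate to a few tenths of
#' a degree for temperatures of roughly -20 to 50 C and humidities of about
#' 5%-99%; a warning is issued outside that envelope. The wet-bulb value is
#' below the dry-bulb temperature whenever the air is unsaturated.
#'
#' @param t_c air (dry-bulb) temperature, degrees C.
#' @param rh relative humidity, percent, in (0, 100].
#' @return wet-bulb temperature, degrees C (vectorised).
#' @export
stull_wet_bulb <- function(t_c, rh) {
  if (any(rh <= 0)) stop("relative humidity must be > 0 (percent)")
  if (any(rh > 100)) stop("relative humidity must be <= 100 (percent)")
  if (any(t_c < -20 | t_c > 50) || any(rh < 5)) {
    warning("inputs outside the formula's empirical validity range ",
            "(-20..50 C, rh >= 5%)")
  }
  t_c * atan(0.151977 * sqrt(rh + 8.313659)) +
    atan(t_c + rh) - atan(rh - 1.676331) +
    0.00391838 * rh^1.5 * atan(0.023101 * rh) - 4.686035
}

# May 1 .. Aug 31 of a given year, as Dates
breeding_season_days <- function(year) {
  seq(as.Date(sprintf("%d-05-01", year)),
      as.Date(sprintf("%d-08-31", year)), by = "day")
}

#' Breeding-season mean daily-high wet-bulb temperature
#'
#' Mean over May 1 - August 31 of the wet-bulb temperature computed from
#' each day's maximum temperature and maximum relative humidity.
#'
#' @param daily data.frame with columns `date` (Date or ISO 8601 string),
#'   `tmax_c`, `rhmax_pct`.
#' @param year breeding season year.
#' @return scalar mean wet-bulb temperature, degrees C.
#' @export
season_mean_wetbulb <- function(daily, year) {
  days <- breeding_season_days(year)
  d <- daily[as.Date(daily$date) %in% days, , drop = FALSE]
  missing_days <- setdiff(as.character(days), as.character(as.Date(d$date)))
  if (length(missing_days) > 0) {
    stop("season ", year, " is missing ", length(missing_days),
         " day(s), e.g. ", paste(utils::head(missing_days, 5),
                                 collapse = ", "))
  }
  mean(stull_wet_bulb(d$tmax_c, d$rhmax_pct))
}

#' Count breeding-season storms
#'
#' A storm is a day whose rainfall strictly exceeds the threshold. The
#' default threshold, 18.21 mm, is the site's operative storm definition
#' (one standard deviation above the mean rain-day rainfall);
#' [storm_threshold_from_data()] recomputes mean + 1 SD from supplied data
#' instead.
#'
#' @param daily data.frame with `date` and `precip_mm`.
#' @param year breeding season year (May-Aug window).
#' @param threshold_mm storm threshold, mm.
#' @return integer number of storm days.
#' @export
count_storms <- function(daily, year, threshold_mm = 18.21) {
  days <- breeding_season_days(year)
  d <- daily[as.Date(daily$date) %in% days, , drop = FALSE]
  if (any(d$precip_mm < 0)) stop("negative precipitation")
  sum(d$precip_mm > threshold_mm)
}

#' Storm threshold recomputed from data
#'
#' Mean plus one standard deviation of rainfall on rain days (days with
#' `precip_mm > 0`) across the supplied daily table.
#'
#' @param daily data.frame with `precip_mm`.
#' @return threshold in mm.
#' @export
storm_threshold_from_data <- function(daily) {
  rain <- daily$precip_mm[daily$precip_mm > 0]
  if (length(rain) < 2) stop("need at least 2 rain days")
  mean(rain) + stats::sd(rain)
}

#' Seasonal ESPI
#'
#' Sums the May-August monthly values of the El Nino-Southern Oscillation
#' Precipitation Index for one year.
#'
#' @param espi_monthly data.frame with `year`, `month`, `espi`.
#' @param year focal year.
#' @return scalar seasonal index.
#' @export
seasonal_espi <- function(espi_monthly, year) {
  m <- espi_monthly[espi_monthly$year == year &
                      espi_monthly$month %in% 5:8, , drop = FALSE]
  if (nrow(m) != 4) {
    stop("year ", year, " does not have exactly the four May-August ",
         "monthly ESPI values (found ", nrow(m), ")")
  }
  sum(m$espi)
}

#' Lag a yearly series
#'
#' The value for year `y` becomes the predictor attached to year `y + lag`;
#' the first `lag` positions are `NA` (never imputed).
#'
#' @param x yearly values in year order.
#' @param lag nonnegative integer lag.
#' @return vector of the same length.
#' @export
lag_series <- function(x, lag = 2) {
  if (lag < 0) stop("lag must be >= 0")
  if (lag == 0) return(x)
  c(rep(NA_real_, min(lag, length(x))),
    x[seq_len(max(0, length(x) - lag))])
}

#' Annual weather covariate table
#'
#' Computes, per study year, the three weather metrics used as demographic
#' covariates — breeding-season mean daily-high wet-bulb temperature, storm
#' count, and 2-year-lagged seasonal ESPI — plus total May-August
#' precipitation and its 2-year lag (the ESPI proxy used for projection).
#'
#' @param daily daily weather data.frame (`date`, `tmax_c`, `rhmax_pct`,
#'   `precip_mm`).
#' @param espi_monthly monthly ESPI data.frame (`year`, `month`, `espi`).
#' @param years integer vector of study years.
#' @param storm_threshold_mm storm threshold (default 18.21).
#' @param lag ESPI/precipitation lag in years (default 2).
#' @return data.frame `year`, `wetbulb_mean`, `n_storms`, `espi`,
#'   `espi_lag2`, `precip_total`, `precip_lag2`. Lagged columns are `NA`
#'   for the first `lag` years.
#' @export
weather_series <- function(daily, espi_monthly, years,
                           storm_threshold_mm = 18.21, lag = 2) {
  years <- sort(as.integer(years))
  wb <- vapply(years, function(y) season_mean_wetbulb(daily, y), numeric(1))
  st <- vapply(years, function(y)
    count_storms(daily, y, storm_threshold_mm), numeric(1))
  espi <- vapply(years, function(y) seasonal_espi(espi_monthly, y),
                 numeric(1))
  pr <- vapply(years, function(y) {
    days <- breeding_season_days(y)
    sum(daily$precip_mm[as.Date(daily$date) %in% days])
  }, numeric(1))
  data.frame(year = years, wetbulb_mean = wb, n_storms = as.integer(st),
             espi = espi, espi_lag2 = lag_series(espi, lag),
             precip_total = pr, precip_lag2 = lag_series(pr, lag))
}
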