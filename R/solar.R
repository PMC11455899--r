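# Solar position after the NOAA general calculations: fractional-year
# Fourier series for the equation of time and solar declination, hour angle
# at zenith 90.833 deg (top of disc, standard atmospheric refraction).

#' @keywords internal
.solar_terms <- function(date) {
  date <- as.Date(date)
  doy <- as.integer(format(date, "%j"))
  yr <- as.integer(format(date, "%Y"))
  leap <- (yr %% 4 == 0 & yr %% 100 != 0) | yr %% 400 == 0
  ndays <- ifelse(leap, 366, 365)
  # evaluated at UTC noon; sub-minute accuracy suffices for day/night labels
  g <- 2 * pi / ndays * (doy - 1 + 0.5)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  list(eqtime_min = eqtime, decl_rad = decl)
}

#' Sunrise and sunset times
#'
#' Computes UTC sunrise and sunset for one or more dates at a fixed location,
#' using the NOAA solar-position formulation with a refraction-corrected
#' zenith of 90.833 degrees (top edge of the solar disc). Polar day or night
#' (no sunrise/sunset) is reported explicitly as `NA` times with the
#' `polar` column set, never silently defaulted.
#'
#' @param date Date vector (UTC calendar dates).
#' @param lon,lat location in decimal degrees (east and north positive).
#'   Latitudes poleward of the polar circles give polar flags on the
#'   affected dates.
#' @return A data frame with columns `date`, `sunrise_utc`, `sunset_utc`
#'   (POSIXct, UTC), `day_length_h`, and `polar` (`"none"`, `"polar_day"`,
#'   `"polar_night"`).
#' @examples
#' sun_times(as.Date("2019-03-01"), lon = 5.149636, lat = 60.080593)
#' @export
sun_times <- function(date, lon, lat) {
  date <- as.Date(date)
  st <- .solar_terms(date)
  lat_r <- lat * pi / 180
  cos_ha <- (cos(90.833 * pi / 180) - sin(lat_r) * sin(st$decl_rad)) /
    (cos(lat_r) * cos(st$decl_rad))
  polar <- ifelse(cos_ha < -1, "polar_day",
                  ifelse(cos_ha > 1, "polar_night", "none"))
  ha_deg <- acos(pmin(1, pmax(-1, cos_ha))) * 180 / pi
  rise_min <- 720 - 4 * (lon + ha_deg) - st$eqtime_min
  set_min <- 720 - 4 * (lon - ha_deg) - st$eqtime_min
  midnight <- .as_utc(date)
  sunrise <- midnight + rise_min * 60
  sunset <- midnight + set_min * 60
  sunrise[polar != "none"] <- NA
  sunset[polar != "none"] <- NA
  day_len <- ifelse(polar == "polar_day", 24,
                    ifelse(polar == "polar_night", 0, 2 * ha_deg * 4 / 60))
  data.frame(date = date, sunrise_utc = sunrise, sunset_utc = sunset,
             day_length_h = day_len, polar = polar,
             stringsAsFactors = FALSE)
}

#' Label timestamps as day or night
#'
#' Day is the interval from sunrise (inclusive) to sunset (exclusive);
#' night is the complement, so every second of a date belongs to exactly
#' one class.
#'
#' @param t POSIXct vector, UTC.
#' @param lon,lat location in decimal degrees.
#' @return Character vector, `"day"` or `"night"`.
#' @export
label_day_night <- function(t, lon, lat) {
  t <- .as_utc(t)
  d <- .utc_date(t)
  ud <- sort(unique(d))
  st <- sun_times(ud, lon, lat)
  .check(all(st$polar == "none"),
         "polar day/night encountered; day/night labels undefined")
  i <- match(d, st$date)
  ifelse(t >= st$sunrise_utc[i] & t < st$sunset_utc[i], "day", "night")
}

#' Expected day/night split of randomly timed events
#'
#' If `n_events` events were timed uniformly at random through the 24 h of
#' a reference date, the expected number in daylight is `n_events` times the
#' day-length fraction of that date; the night expectation is the
#' complement. Used to contrast observed descent timing with a
#' random-timing null.
#'
#' @param n_events non-negative event count.
#' @param date reference date (e.g. the median spawning date).
#' @param lon,lat location in decimal degrees.
#' @return Named numeric vector with elements `expected_day` and
#'   `expected_night`, summing to `n_events`.
#' @export
expected_day_night_counts <- function(n_events, date, lon, lat) {
  .check(n_events >= 0, "n_events must be >= 0")
  st <- sun_times(as.Date(date), lon, lat)
  frac <- st$day_length_h / 24
  c(expected_day = n_events * frac, expected_night = n_events * (1 - frac))
}
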