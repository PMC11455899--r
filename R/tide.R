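# Tide series: simulation, IO, 1-s linear interpolation, depth correction.
# A tide series is a data.frame (class "tide_series") with POSIXct UTC
# `timestamp` at 10-min cadence and numeric `sea_level_m`; the series mean
# is carried as attribute "mean_level_m".

#' @keywords internal
.new_tide_series <- function(timestamp, sea_level_m) {
  .check(!is.unsorted(as.numeric(timestamp), strictly = TRUE),
         "tide timestamps must be strictly increasing")
  out <- data.frame(timestamp = .as_utc(timestamp), sea_level_m = sea_level_m)
  attr(out, "mean_level_m") <- mean(sea_level_m)
  class(out) <- c("tide_series", "data.frame")
  out
}

#' Simulate a harmonic tide gauge series
#'
#' Generates sea level sampled every 10 minutes over the study window as
#' `mean + amplitude * sin(2 * pi * t / period)`, emulating a dominant
#' semidiurnal constituent (default period 12.42 h, the M2 tide).
#'
#' @param params a [sim_params()] object.
#' @return A `tide_series` data frame (`timestamp`, `sea_level_m`) with the
#'   series mean as attribute `mean_level_m`.
#' @export
simulate_tide <- function(params) {
  validate_sim_params(params)
  t0 <- .as_utc(params$study_start)
  t1 <- .as_utc(params$study_end)
  ts <- seq(t0, t1, by = 600)
  tt <- as.numeric(ts) - as.numeric(t0)
  level <- params$tide_mean_m +
    params$tide_amplitude_m * sin(2 * pi * tt / (params$tide_period_h * 3600))
  .new_tide_series(ts, level)
}

#' Read a tide-gauge CSV
#'
#' Expects columns `timestamp` (ISO-8601 UTC) and `sea_level_m`.
#'
#' @param path CSV path.
#' @return A `tide_series` data frame.
#' @export
read_tide <- function(path) {
  .check(file.exists(path), paste("file not found:", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check(all(c("timestamp", "sea_level_m") %in% names(d)),
         "tide CSV must have columns timestamp, sea_level_m")
  .new_tide_series(.parse_utc(d$timestamp), as.numeric(d$sea_level_m))
}

#' @keywords internal
write_tide <- function(tide, path) {
  utils::write.csv(
    data.frame(timestamp = .fmt_utc(tide$timestamp),
               sea_level_m = tide$sea_level_m),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Interpolate sea level at arbitrary times
#'
#' Linear interpolation between the bracketing 10-min gauge samples,
#' evaluated at 1-s resolution to match the telemetry clock. Times outside
#' the gauge span are refused (no extrapolation).
#'
#' @param tide a `tide_series`.
#' @param t POSIXct vector, UTC.
#' @return Sea level in metres at each `t`.
#' @export
interpolate_sea_level <- function(tide, t) {
  t <- .as_utc(t)
  tt <- round(as.numeric(t))          # 1-s resolution
  t0 <- as.numeric(tide$timestamp[1L])
  t1 <- as.numeric(tide$timestamp[nrow(tide)])
  .check(all(tt >= t0 & tt <= t1),
         "time outside tide series span; extrapolation refused")
  stats::approx(as.numeric(tide$timestamp), tide$sea_level_m, xout = tt,
                method = "linear", ties = "ordered")$y
}

#' Tidal correction of pressure-derived depth
#'
#' Removes the tidal signal from depth-sensor data by subtracting the
#' deviation of the current sea level from the series-mean sea level:
#' `corrected = depth - (level(t) - mean_level)`.
#'
#' @param depth_m recorded depths, metres (positive down).
#' @param t POSIXct detection times, UTC.
#' @param tide a `tide_series`.
#' @return Corrected depths, metres.
#' @export
correct_tide <- function(depth_m, t, tide) {
  level <- interpolate_sea_level(tide, t)
  depth_m - (level - attr(tide, "mean_level_m"))
}
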