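# Inter-descent interval statistics, descent photoperiod analysis,
# cohort summaries and export of analysis-ready model tables.

#' Inter-descent intervals
#'
#' For every valid sequence of k descent events, the k-1 intervals in
#' hours between successive times of maximum depth -- the putative proxy
#' for successive spawning events. Intervals are computed only within
#' sequences, never across sequence breaks.
#'
#' @param fit a [periodic_descents()] object (or the `events` data frame
#'   from [build_sequences()]).
#' @return Data frame `fish_id`, `sequence_id`, `interval_h`.
#' @export
descent_intervals <- function(fit) {
  ev <- if (inherits(fit, "periodic_descents")) fit$events else fit
  ev <- ev[ev$valid, , drop = FALSE]
  if (nrow(ev) == 0L)
    return(data.frame(fish_id = character(0), sequence_id = character(0),
                      interval_h = numeric(0)))
  ev <- ev[order(ev$sequence_id, ev$date), , drop = FALSE]
  same <- ev$sequence_id[-1] == ev$sequence_id[-nrow(ev)]
  dt <- as.numeric(diff(as.numeric(ev$time_of_max))) / 3600
  data.frame(fish_id = ev$fish_id[-1][same],
             sequence_id = ev$sequence_id[-1][same],
             interval_h = dt[same], stringsAsFactors = FALSE)
}

#' Histogram of descent intervals
#'
#' Counts intervals in half-open bins `[k*bin_h, (k+1)*bin_h)`.
#'
#' @param intervals_h numeric vector of intervals (hours), or the output
#'   of [descent_intervals()].
#' @param bin_h bin width, hours.
#' @return Data frame `bin_low_h`, `bin_high_h`, `count` (empty input
#'   gives an empty histogram).
#' @export
interval_histogram <- function(intervals_h, bin_h = 10) {
  if (is.data.frame(intervals_h)) intervals_h <- intervals_h$interval_h
  if (length(intervals_h) == 0L)
    return(data.frame(bin_low_h = numeric(0), bin_high_h = numeric(0),
                      count = integer(0)))
  k <- floor(intervals_h / bin_h)
  tab <- table(k)
  ks <- as.integer(names(tab))
  data.frame(bin_low_h = ks * bin_h, bin_high_h = (ks + 1) * bin_h,
             count = as.integer(tab))
}

#' Median descent interval
#'
#' Standard mid-ordering median (mean of the two central order statistics
#' for even n). An empty input is an explicit error, never a silent NA.
#'
#' @param intervals_h as in [interval_histogram()].
#' @return Median interval, hours.
#' @export
median_interval <- function(intervals_h) {
  if (is.data.frame(intervals_h)) intervals_h <- intervals_h$interval_h
  .check(length(intervals_h) > 0, "median undefined: no intervals")
  stats::median(intervals_h)
}

#' Photoperiod of descent events
#'
#' Labels each descent event day/night at its time of maximum depth and
#' contrasts the observed split with the expectation under random timing
#' (event count times the day-length fraction of a reference date,
#' typically the median spawning date).
#'
#' @param events descent events (need `time_of_max`), e.g. the `events`
#'   of a [periodic_descents()] fit, usually restricted to valid
#'   sequences.
#' @param lon,lat location for solar times, decimal degrees.
#' @param reference_date date used for the random-timing expectation.
#' @return A list: `events` (input plus `photoperiod`) and `table`
#'   (observed and expected day/night counts).
#' @export
descent_photoperiod <- function(events, lon, lat,
                                reference_date = as.Date("2019-03-01")) {
  n <- nrow(events)
  if (n == 0L) {
    events$photoperiod <- character(0)
    tab <- data.frame(photoperiod = c("day", "night"),
                      observed = c(0L, 0L), expected = c(0, 0))
    return(list(events = events, table = tab))
  }
  events$photoperiod <- label_day_night(events$time_of_max, lon, lat)
  exp_dn <- expected_day_night_counts(n, reference_date, lon, lat)
  tab <- data.frame(photoperiod = c("day", "night"),
                    observed = c(sum(events$photoperiod == "day"),
                                 sum(events$photoperiod == "night")),
                    expected = as.numeric(exp_dn))
  list(events = events, table = tab)
}

#' Distribution of valid sequence lengths
#'
#' Histogram of descent counts per valid sequence, split by sex when
#' metadata are available.
#'
#' @param sequences the `sequences` of a [periodic_descents()] fit.
#' @param fish optional fish metadata (for the sex split).
#' @return Data frame `n_events`, `sex` (or `"all"`), `count`.
#' @export
sequence_length_distribution <- function(sequences, fish = NULL) {
  sq <- sequences[sequences$valid, , drop = FALSE]
  if (nrow(sq) == 0L)
    return(data.frame(n_events = integer(0), sex = character(0),
                      count = integer(0)))
  sex <- if (is.null(fish)) rep("all", nrow(sq))
         else fish$sex[match(sq$fish_id, fish$fish_id)]
  agg <- as.data.frame(table(n_events = sq$n_events, sex = sex),
                       stringsAsFactors = FALSE)
  agg <- agg[agg$Freq > 0, , drop = FALSE]
  data.frame(n_events = as.integer(agg$n_events), sex = agg$sex,
             count = agg$Freq, row.names = NULL)
}

#' Cohort descriptive summary
#'
#' Per ground x sex x period: number of fish and detections, mean depth
#' (mean of per-fish mean depths) with standard error, mean detection
#' days and bursts per fish with standard errors, and -- when flags are
#' supplied -- the count and proportion of periodic-descent fish.
#' Standard errors are `sd/sqrt(n)` and reported as `NA` for groups of
#' fewer than two fish.
#'
#' @param stream filtered, period-labelled detections with `fish_id`,
#'   `timestamp`, `value`, `ground`, `sex`, `period`.
#' @param flags optional named logical vector from [classify_fish()].
#' @param period which period to summarise.
#' @return A data frame, one row per ground x sex.
#' @export
cohort_summary <- function(stream, flags = NULL, period = "spawning") {
  s <- stream[stream$period == period, , drop = FALSE]
  if (nrow(s) == 0L)
    return(data.frame(ground = character(0), sex = character(0)))
  bursts <- count_bursts(s)
  per_fish <- do.call(rbind, lapply(split(s, s$fish_id), function(d) {
    data.frame(fish_id = d$fish_id[1L], ground = d$ground[1L],
               sex = d$sex[1L], n_detections = nrow(d),
               mean_depth_m = mean(d$value),
               n_days = length(unique(.utc_date(d$timestamp))),
               stringsAsFactors = FALSE)
  }))
  per_fish$bursts <- as.integer(bursts[per_fish$fish_id])
  if (!is.null(flags))
    per_fish$flagged <- unname(flags[per_fish$fish_id])
  groups <- split(per_fish, paste(per_fish$ground, per_fish$sex))
  out <- do.call(rbind, lapply(groups, function(g) {
    r <- data.frame(ground = g$ground[1L], sex = g$sex[1L],
                    n_fish = nrow(g),
                    n_detections = sum(g$n_detections),
                    mean_depth_m = mean(g$mean_depth_m),
                    se_depth_m = .se(g$mean_depth_m),
                    mean_detection_days = mean(g$n_days),
                    se_detection_days = .se(g$n_days),
                    mean_bursts = mean(g$bursts),
                    se_bursts = .se(g$bursts),
                    stringsAsFactors = FALSE)
    if (!is.null(flags)) {
      r$n_flagged <- sum(g$flagged, na.rm = TRUE)
      r$prop_flagged <- r$n_flagged / r$n_fish
    }
    r
  }))
  rownames(out) <- NULL
  out$period <- period
  out
}

#' Export analysis-ready model tables
#'
#' Builds the two long-format tables consumed by external mixed-model
#' software: a detection-level depth table (tide-corrected depth, sex,
#' day/night, length centred at the cohort mean, fish id, Julian day,
#' year, ground) and a per-fish binomial table of the periodic-descent
#' flag with sex, length and ground.
#'
#' @param stream filtered, labelled detections with `value`, `sex`,
#'   `length_cm`, `fish_id`, `ground`, `region`, `timestamp` and a
#'   `day_night` column (add one with [label_day_night()]).
#' @param flags named logical vector from [classify_fish()] (fish absent
#'   from it are omitted from the binomial table).
#' @return A list: `depth_table` (one row per detection) and
#'   `binomial_table` (one row per flagged-or-not fish).
#' @export
export_model_tables <- function(stream, flags = NULL) {
  len_mean <- mean(stream$length_cm[!duplicated(stream$fish_id)])
  depth_table <- data.frame(
    depth = stream$value,
    sex = stream$sex,
    day_night = stream$day_night,
    length_centred = stream$length_cm - len_mean,
    fish_id = stream$fish_id,
    julian_day = as.integer(format(stream$timestamp, "%j", tz = "UTC")),
    year = as.integer(format(stream$timestamp, "%Y", tz = "UTC")),
    ground = stream$ground,
    stringsAsFactors = FALSE)
  binomial_table <- NULL
  if (!is.null(flags)) {
    per_fish <- stream[!duplicated(stream$fish_id), , drop = FALSE]
    per_fish <- per_fish[per_fish$fish_id %in% names(flags), , drop = FALSE]
    binomial_table <- data.frame(
      fish_id = per_fish$fish_id,
      periodic_descent = as.integer(flags[per_fish$fish_id]),
      sex = per_fish$sex,
      length_cm = per_fish$length_cm,
      ground = per_fish$ground,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  list(depth_table = depth_table, binomial_table = binomial_table)
}
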