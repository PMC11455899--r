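# Detection quality control: dead-fish removal, cross-receiver
# deduplication, single-day stray removal, period assignment, tagging-year
# restriction, data-rich selection and burst counting, with attrition
# bookkeeping at every stage.

#' Regional study configuration
#'
#' Month sets defining the spawning, feeding and transitional periods per
#' region, plus the coordinates used for tide reference and solar times.
#' Defaults encode the two Norwegian coastal study regions: western Norway
#' (WN, spawning February--March) and mid Norway (MN, spawning
#' February--April); the feeding period is June--August in both, and the
#' transitional months flanking the spawning period are omitted from all
#' analyses.
#'
#' @param region `"WN"` or `"MN"` (vectorised access via the returned list).
#' @return A named list per region with elements `spawning_months`,
#'   `feeding_months`, `transitional_months` (integer month numbers),
#'   `solar_lon`, `solar_lat`, `median_spawning_date` (the reference date
#'   for the random-timing day/night expectation: 1 March WN,
#'   15 March MN; the year is supplied when used).
#' @export
study_config <- function(region = c("WN", "MN")) {
  cfg <- list(
    WN = list(spawning_months = c(2L, 3L),
              feeding_months = c(6L, 7L, 8L),
              transitional_months = c(1L, 4L),
              solar_lon = 5.149636, solar_lat = 60.080593,
              median_spawning_md = c(3L, 1L)),
    MN = list(spawning_months = c(2L, 3L, 4L),
              feeding_months = c(6L, 7L, 8L),
              transitional_months = c(1L, 5L),
              solar_lon = 8.343865, solar_lat = 63.382649,
              median_spawning_md = c(3L, 15L)))
  for (r in names(cfg)) {
    s <- cfg[[r]]
    stopifnot(!anyDuplicated(c(s$spawning_months, s$feeding_months,
                               s$transitional_months)))
  }
  if (missing(region)) return(cfg)
  cfg[[match.arg(region)]]
}

#' Remove fish assumed dead from flat depth records
#'
#' A fish showing no vertical movement over a day is assumed dead. Per
#' fish, the earliest `window_h`-hour span containing at least two
#' detections whose depth range is below `movement_epsilon_m` marks the
#' onset of flatness; all of that fish's detections from the span start
#' onward are removed. Fish whose whole record is removed are listed dead;
#' fish with fewer than two detections pass through untouched (the
#' single-day filter handles strays).
#'
#' @param stream time-sorted detection data frame with `fish_id`,
#'   `timestamp`, `value`.
#' @param window_h flatness window, hours.
#' @param movement_epsilon_m depth range below which a window counts as no
#'   vertical movement, metres.
#' @return A list: `stream` (surviving detections), `removed` (count),
#'   `dead_fish` (ids with all detections removed), `flat_onset` (named
#'   POSIXct of flatness onset per affected fish).
#' @export
filter_dead_fish <- function(stream, window_h = 24, movement_epsilon_m = 0.5) {
  if (nrow(stream) == 0L)
    return(list(stream = stream, removed = 0L, dead_fish = character(0),
                flat_onset = .as_utc(numeric(0))))
  keep <- rep(TRUE, nrow(stream))
  onset <- c()
  idx_by_fish <- split(seq_len(nrow(stream)), stream$fish_id)
  for (fid in names(idx_by_fish)) {
    idx <- idx_by_fish[[fid]]
    if (length(idx) < 2L) next
    tt <- as.numeric(stream$timestamp[idx])
    o <- order(tt)
    idx <- idx[o]; tt <- tt[o]
    wr <- .window_range(tt, stream$value[idx], window_h * 3600)
    hit <- which(wr$n >= 2L & (wr$hi - wr$lo) < movement_epsilon_m)
    if (length(hit)) {
      first <- hit[1L]
      keep[idx[first:length(idx)]] <- FALSE
      onset[fid] <- tt[first]
    }
  }
  out <- stream[keep, , drop = FALSE]
  dead <- setdiff(names(onset), unique(out$fish_id))
  list(stream = out, removed = sum(!keep), dead_fish = dead,
       flat_onset = .as_utc(onset))
}

#' Deduplicate cross-receiver detections
#'
#' A tag transmission can be logged by several receivers; only the first
#' detection is kept. Scanning each fish in time order, a detection is
#' dropped iff it occurs less than `window_s` seconds after the last
#' retained detection of that fish *and* at a different station.
#' Same-station successors are retained: given the 200 s minimum tag
#' delay they are necessarily distinct transmissions.
#'
#' @param stream time-sorted detection data frame with `fish_id`,
#'   `timestamp`, `station_id`.
#' @param window_s duplicate window, seconds.
#' @return A list: `stream` (deduplicated) and `removed` (count).
#' @export
deduplicate <- function(stream, window_s = 200) {
  if (nrow(stream) == 0L) return(list(stream = stream, removed = 0L))
  keep <- rep(TRUE, nrow(stream))
  for (idx in split(seq_len(nrow(stream)), stream$fish_id)) {
    o <- order(stream$timestamp[idx], stream$station_id[idx])
    idx <- idx[o]
    tt <- as.numeric(stream$timestamp[idx])
    st <- stream$station_id[idx]
    last_t <- tt[1L]; last_s <- st[1L]
    if (length(idx) < 2L) next
    for (k in 2:length(idx)) {
      if (tt[k] - last_t < window_s && st[k] != last_s) {
        keep[idx[k]] <- FALSE
      } else {
        last_t <- tt[k]; last_s <- st[k]
      }
    }
  }
  list(stream = stream[keep, , drop = FALSE], removed = sum(!keep))
}

#' Remove single-day stray detections
#'
#' A single daily detection of a fish within the receiver grid is treated
#' as dubious/erroneous: any (fish, UTC calendar day) cell holding exactly
#' one detection has that detection removed. Applied once, not iterated.
#'
#' @param stream deduplicated detection data frame with `fish_id`,
#'   `timestamp`.
#' @return A list: `stream` and `removed` (count).
#' @export
remove_single_day_detections <- function(stream) {
  if (nrow(stream) == 0L) return(list(stream = stream, removed = 0L))
  cell <- paste(stream$fish_id, .utc_date(stream$timestamp))
  n_in_cell <- ave(seq_along(cell), cell, FUN = length)
  keep <- n_in_cell > 1L
  list(stream = stream[keep, , drop = FALSE], removed = sum(!keep))
}

#' Label detections by study period
#'
#' Labels each detection `spawning`, `feeding`, `transitional` or `other`
#' by its UTC calendar month against the fish's regional month sets, and
#' drops the transitional and other classes (they are omitted from all
#' analyses).
#'
#' @param stream detection data frame with `timestamp` and `region`
#'   columns (as after [join_metadata()]).
#' @param config regional configuration list, as [study_config()].
#' @return A list: `stream` (surviving detections with a `period` column)
#'   and `removed` (count).
#' @export
assign_period <- function(stream, config = study_config()) {
  if (nrow(stream) == 0L) {
    stream$period <- character(0)
    return(list(stream = stream, removed = 0L))
  }
  .check(all(stream$region %in% names(config)),
         paste("unknown region(s):",
               paste(setdiff(unique(stream$region), names(config)), collapse = ", ")))
  mon <- as.integer(format(stream$timestamp, "%m", tz = "UTC"))
  period <- rep("other", nrow(stream))
  for (r in unique(stream$region)) {
    sel <- stream$region == r
    period[sel & mon %in% config[[r]]$spawning_months] <- "spawning"
    period[sel & mon %in% config[[r]]$feeding_months] <- "feeding"
    period[sel & mon %in% config[[r]]$transitional_months] <- "transitional"
  }
  keep <- period %in% c("spawning", "feeding")
  out <- stream[keep, , drop = FALSE]
  out$period <- period[keep]
  list(stream = out, removed = sum(!keep))
}

#' Restrict detections to the tagging year
#'
#' Keeps only detections from the calendar year each fish was tagged, so
#' length-at-tagging remains a valid covariate.
#'
#' @param stream detection data frame with `timestamp` and `tagging_date`.
#' @return A list: `stream` and `removed`.
#' @export
restrict_to_tagging_year <- function(stream) {
  if (nrow(stream) == 0L) return(list(stream = stream, removed = 0L))
  yr <- as.integer(format(stream$timestamp, "%Y", tz = "UTC"))
  tag_yr <- as.integer(format(stream$tagging_date, "%Y"))
  keep <- yr == tag_yr
  list(stream = stream[keep, , drop = FALSE], removed = sum(!keep))
}

#' Select data-rich fish
#'
#' Within one period, fish qualify as data-rich with at least `min_days`
#' distinct detection days and at least `min_detections` depth detections.
#'
#' @param stream filtered, period-labelled detection data frame.
#' @param min_days minimum distinct UTC detection days.
#' @param min_detections minimum detection count.
#' @param period period to evaluate (`"spawning"` or `"feeding"`).
#' @return Character vector of qualifying `fish_id`s.
#' @export
select_data_rich <- function(stream, min_days = 21L, min_detections = 2000L,
                             period = "spawning") {
  s <- stream[stream$period == period, , drop = FALSE]
  if (nrow(s) == 0L) return(character(0))
  n_det <- table(s$fish_id)
  days <- tapply(.utc_date(s$timestamp), s$fish_id,
                 function(d) length(unique(d)))
  ids <- names(n_det)
  sort(ids[as.integer(n_det) >= min_detections &
             as.integer(days[ids]) >= min_days])
}

#' Count detection bursts per fish
#'
#' A burst is a maximal run of detections of one fish with no
#' inter-detection gap exceeding `gap_h` hours; a fish going undetected
#' for longer starts a new burst.
#'
#' @param stream time-sorted detection data frame with `fish_id`,
#'   `timestamp`.
#' @param gap_h gap defining a new burst, hours.
#' @return Named integer vector of burst counts per fish.
#' @export
count_bursts <- function(stream, gap_h = 24) {
  if (nrow(stream) == 0L) return(integer(0))
  out <- tapply(as.numeric(stream$timestamp), stream$fish_id, function(tt) {
    tt <- sort(tt)
    if (length(tt) == 1L) return(1L)
    1L + sum(diff(tt) > gap_h * 3600)
  })
  res <- as.integer(out)
  names(res) <- names(out)
  res
}

#' Run the full QC filter pipeline
#'
#' Applies, in order: dead-fish removal, cross-receiver deduplication,
#' single-day stray removal, period assignment (dropping transitional and
#' out-of-period months), and the tagging-year restriction, recording
#' detection and fish counts before and after every stage.
#'
#' @param stream joined detection data frame (after [join_metadata()]).
#' @param config regional configuration, as [study_config()].
#' @param movement_epsilon_m dead-fish flatness threshold, metres.
#' @return A list: `stream` (the filtered detections) and `attrition`
#'   (data frame of per-stage detection/fish counts, class
#'   `attrition_report`).
#' @export
run_qc <- function(stream, config = study_config(), movement_epsilon_m = 0.5) {
  stages <- list()
  note <- function(name, s) {
    stages[[length(stages) + 1L]] <<- data.frame(
      stage = name, detections = nrow(s),
      fish = length(unique(s$fish_id)), stringsAsFactors = FALSE)
  }
  note("input", stream)
  r1 <- filter_dead_fish(stream, movement_epsilon_m = movement_epsilon_m)
  note("dead_fish_removed", r1$stream)
  r2 <- deduplicate(r1$stream)
  note("deduplicated", r2$stream)
  r3 <- remove_single_day_detections(r2$stream)
  note("single_day_removed", r3$stream)
  r4 <- assign_period(r3$stream, config)
  note("period_restricted", r4$stream)
  r5 <- restrict_to_tagging_year(r4$stream)
  note("tagging_year", r5$stream)
  att <- do.call(rbind, stages)
  class(att) <- c("attrition_report", "data.frame")
  list(stream = r5$stream, attrition = att, dead_fish = r1$dead_fish)
}

#' @export
print.attrition_report <- function(x, ...) {
  cat("QC attrition\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-20s %9d detections  %4d fish\n",
                x$stage[i], x$detections[i], x$fish[i]))
  invisible(x)
}

#' Serialize an attrition report to JSON
#'
#' @param report an `attrition_report` from [run_qc()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_attrition <- function(report, path) {
  jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
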