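# The core algorithm: rule-based detection of periodic spawning descents
# from daily maximum depths, gap-limited sequence building, per-fish
# classification, and the 2x2x2 sensitivity-scenario grid.

#' Descent-detection criteria
#'
#' The three tunable rules of the detector: (i) a descent day's maximum
#' depth must be at least `depth_ratio` times the mean of the adjacent
#' days' maxima (1.5 reads "50% deeper", 2.0 "100% deeper"); (ii) at most
#' `max_gap_days` calendar days may separate consecutive descents of one
#' sequence; (iii) a sequence is valid -- and the fish classified a
#' periodic-descent fish -- only with at least `min_descents` descents.
#'
#' @param depth_ratio multiplier on the neighbour-day mean maximum, > 1.
#' @param max_gap_days maximum calendar-day gap within a sequence, >= 1.
#' @param min_descents minimum descents per valid sequence, >= 2.
#' @return An object of class `descent_criteria`.
#' @export
descent_criteria <- function(depth_ratio = 1.5, max_gap_days = 6L,
                             min_descents = 2L) {
  .check(depth_ratio > 1, "depth_ratio must be > 1")
  .check(max_gap_days >= 1, "max_gap_days must be >= 1")
  .check(min_descents >= 2, "min_descents must be >= 2")
  structure(list(depth_ratio = depth_ratio,
                 max_gap_days = as.integer(max_gap_days),
                 min_descents = as.integer(min_descents)),
            class = "descent_criteria")
}

#' @export
print.descent_criteria <- function(x, ...) {
  cat(sprintf("descent criteria: depth >= %.2f x neighbour mean, gap <= %d d, >= %d descents\n",
              x$depth_ratio, x$max_gap_days, x$min_descents))
  invisible(x)
}

#' Daily maximum depths
#'
#' Collapses a tide-corrected, period-restricted depth track to one record
#' per fish and UTC calendar day: the maximum corrected depth, the
#' timestamp of the first detection attaining it, and the day's detection
#' count.
#'
#' @param track detection data frame with `fish_id`, `timestamp` and the
#'   depth column.
#' @param depth_col name of the depth column (default `"value"`).
#' @return Data frame `fish_id`, `date`, `max_depth_m`, `time_of_max`,
#'   `n_detections`, ordered by fish then date.
#' @export
daily_maxima <- function(track, depth_col = "value") {
  if (nrow(track) == 0L)
    return(data.frame(fish_id = character(0), date = as.Date(character(0)),
                      max_depth_m = numeric(0),
                      time_of_max = .as_utc(numeric(0)),
                      n_detections = integer(0)))
  date <- .utc_date(track$timestamp)
  key <- paste(track$fish_id, date)
  depth <- track[[depth_col]]
  n <- ave(seq_along(key), key, FUN = length)
  # deepest first, earliest timestamp breaking ties
  o <- order(track$fish_id, date, -depth, track$timestamp)
  first <- !duplicated(key[o])
  sel <- o[first]
  out <- data.frame(fish_id = track$fish_id[sel], date = date[sel],
                    max_depth_m = depth[sel],
                    time_of_max = track$timestamp[sel],
                    n_detections = as.integer(n[sel]),
                    stringsAsFactors = FALSE)
  out[order(out$fish_id, out$date), , drop = FALSE]
}

#' Neighbour-day mean maximum depth
#'
#' For each daily-max record, the mean of the maximum depths on the
#' calendar day before and the calendar day after (a centred rolling
#' mean excluding the focal day). Days lacking either calendar neighbour
#' -- including the first and last day of every track -- are ineligible
#' and get `NA`. With `include_focal = TRUE` the focal day joins the mean
#' (a centred window of three), exposed for sensitivity checking only.
#'
#' @param daily output of [daily_maxima()].
#' @param include_focal include the focal day in the rolling mean.
#' @return Numeric vector aligned with `daily` rows; `NA` = ineligible.
#' @export
neighbor_mean <- function(daily, include_focal = FALSE) {
  key <- paste(daily$fish_id, daily$date)
  prev <- daily$max_depth_m[match(paste(daily$fish_id, daily$date - 1), key)]
  nxt <- daily$max_depth_m[match(paste(daily$fish_id, daily$date + 1), key)]
  if (include_focal) (prev + daily$max_depth_m + nxt) / 3
  else (prev + nxt) / 2
}

#' Detect periodic-descent days
#'
#' Flags every eligible day whose maximum depth is at least
#' `criteria$depth_ratio` times the neighbour-day mean maximum
#' (inclusive threshold).
#'
#' @param daily output of [daily_maxima()].
#' @param criteria a [descent_criteria()] object.
#' @param include_focal passed to [neighbor_mean()].
#' @return Data frame of descent events: `fish_id`, `date`,
#'   `max_depth_m`, `neighbor_mean_m`, `time_of_max`.
#' @export
detect_descent_days <- function(daily, criteria = descent_criteria(),
                                include_focal = FALSE) {
  nbr <- neighbor_mean(daily, include_focal)
  hit <- !is.na(nbr) & daily$max_depth_m >= criteria$depth_ratio * nbr
  data.frame(fish_id = daily$fish_id[hit], date = daily$date[hit],
             max_depth_m = daily$max_depth_m[hit],
             neighbor_mean_m = nbr[hit],
             time_of_max = daily$time_of_max[hit],
             stringsAsFactors = FALSE)
}

#' Chain descent events into gap-limited sequences
#'
#' Greedy chaining per fish in date order: consecutive events at most
#' `criteria$max_gap_days` calendar days apart join the same sequence; a
#' larger gap starts a new one. A sequence is valid iff it holds at least
#' `criteria$min_descents` events.
#'
#' @param events output of [detect_descent_days()].
#' @param criteria a [descent_criteria()] object.
#' @return A list: `events` (input plus `sequence_id`, `valid`) and
#'   `sequences` (one row per sequence: `fish_id`, `sequence_id`,
#'   `start_date`, `end_date`, `n_events`, `valid`).
#' @export
build_sequences <- function(events, criteria = descent_criteria()) {
  if (nrow(events) == 0L) {
    events$sequence_id <- character(0)
    events$valid <- logical(0)
    return(list(events = events,
                sequences = data.frame(fish_id = character(0),
                                       sequence_id = character(0),
                                       start_date = as.Date(character(0)),
                                       end_date = as.Date(character(0)),
                                       n_events = integer(0),
                                       valid = logical(0))))
  }
  ev <- events[order(events$fish_id, events$date), , drop = FALSE]
  new_fish <- c(TRUE, ev$fish_id[-1] != ev$fish_id[-nrow(ev)])
  gap <- c(0, as.integer(diff(ev$date)))
  new_seq <- new_fish | gap > criteria$max_gap_days
  seq_num <- cumsum(new_seq)
  within_fish <- ave(seq_num, ev$fish_id, FUN = function(s) s - s[1L] + 1L)
  ev$sequence_id <- sprintf("%s_seq%02d", ev$fish_id, within_fish)
  n_ev <- ave(seq_along(seq_num), seq_num, FUN = length)
  ev$valid <- n_ev >= criteria$min_descents
  seqs <- data.frame(
    fish_id = tapply(ev$fish_id, seq_num, `[`, 1L),
    sequence_id = tapply(ev$sequence_id, seq_num, `[`, 1L),
    start_date = as.Date(tapply(as.character(ev$date), seq_num, min)),
    end_date = as.Date(tapply(as.character(ev$date), seq_num, max)),
    n_events = as.integer(tapply(seq_along(seq_num), seq_num, length)),
    stringsAsFactors = FALSE, row.names = NULL)
  seqs$valid <- seqs$n_events >= criteria$min_descents
  list(events = ev, sequences = seqs)
}

#' Classify fish as periodic-descent fish
#'
#' A fish is flagged iff it owns at least one valid sequence.
#'
#' @param sequences the `sequences` element of [build_sequences()].
#' @param fish_ids optionally, the full set of fish to report (fish with
#'   no events get `FALSE`).
#' @return Named logical vector per fish.
#' @export
classify_fish <- function(sequences, fish_ids = NULL) {
  ids <- sort(unique(c(sequences$fish_id, fish_ids)))
  flag <- vapply(ids, function(f)
    any(sequences$valid[sequences$fish_id == f]), logical(1))
  flag
}

#' Detect periodic descents
#'
#' The front door of the detector: from daily maximum depths (or a raw
#' track, collapsed internally), finds descent days, chains them into
#' gap-limited sequences and classifies each fish, returning a single
#' object that the `print`, `summary` and `plot` methods understand.
#'
#' @param x a [daily_maxima()] data frame, or a detection track with
#'   `fish_id`, `timestamp` and a depth column (collapsed with
#'   [daily_maxima()] first).
#' @param criteria a [descent_criteria()] object.
#' @param fish optionally, the fish metadata table; enables sex/ground
#'   summaries and guarantees unflagged fish appear in the output.
#' @param include_focal include the focal day in the neighbour mean (see
#'   [neighbor_mean()]).
#' @param depth_col depth column name when `x` is a raw track.
#' @return An object of class `periodic_descents`: list with `daily`,
#'   `criteria`, `events`, `sequences`, `flags`, `fish`.
#' @examples
#' daily <- data.frame(fish_id = "f1",
#'                     date = as.Date("2019-03-01") + 0:6,
#'                     max_depth_m = c(30, 45, 30, 31, 48, 30, 30),
#'                     time_of_max = as.POSIXct("2019-03-01 12:00",
#'                                              tz = "UTC") + 0:6 * 86400,
#'                     n_detections = 100L)
#' fit <- periodic_descents(daily)
#' summary(fit)
#' @export
periodic_descents <- function(x, criteria = descent_criteria(), fish = NULL,
                              include_focal = FALSE, depth_col = "value") {
  daily <- if (all(c("date", "max_depth_m") %in% names(x))) x
           else daily_maxima(x, depth_col)
  events <- detect_descent_days(daily, criteria, include_focal)
  chain <- build_sequences(events, criteria)
  flags <- classify_fish(chain$sequences,
                         fish_ids = unique(c(daily$fish_id, fish$fish_id)))
  structure(list(daily = daily, criteria = criteria,
                 events = chain$events, sequences = chain$sequences,
                 flags = flags, fish = fish),
            class = "periodic_descents")
}

#' @export
print.periodic_descents <- function(x, ...) {
  cat("Periodic-descent classification\n")
  print(x$criteria)
  cat(sprintf("  %d fish, %d descent days, %d sequences (%d valid), %d fish flagged\n",
              length(x$flags), nrow(x$events), nrow(x$sequences),
              sum(x$sequences$valid), sum(x$flags)))
  invisible(x)
}

#' @export
summary.periodic_descents <- function(object, ...) {
  x <- object
  out <- list(criteria = x$criteria,
              n_fish = length(x$flags),
              n_events = nrow(x$events),
              n_sequences_valid = sum(x$sequences$valid),
              n_flagged = sum(x$flags),
              prop_flagged = mean(x$flags),
              seq_length_table = table(x$sequences$n_events[x$sequences$valid]))
  if (!is.null(x$fish)) {
    sex <- x$fish$sex[match(names(x$flags), x$fish$fish_id)]
    out$by_sex <- data.frame(
      sex = c("F", "M"),
      n = c(sum(sex == "F", na.rm = TRUE), sum(sex == "M", na.rm = TRUE)),
      n_flagged = c(sum(x$flags & sex == "F", na.rm = TRUE),
                    sum(x$flags & sex == "M", na.rm = TRUE)))
    out$by_sex$prop_flagged <- ifelse(out$by_sex$n > 0,
                                      out$by_sex$n_flagged / out$by_sex$n, NA)
  }
  class(out) <- "summary.periodic_descents"
  out
}

#' @export
print.summary.periodic_descents <- function(x, ...) {
  print(x$criteria)
  cat(sprintf("fish: %d   descent days: %d   valid sequences: %d   flagged: %d (%.1f%%)\n",
              x$n_fish, x$n_events, x$n_sequences_valid, x$n_flagged,
              100 * x$prop_flagged))
  if (!is.null(x$by_sex)) {
    cat("by sex:\n")
    print(x$by_sex, row.names = FALSE)
  }
  if (length(x$seq_length_table)) {
    cat("valid sequence lengths:\n")
    print(x$seq_length_table)
  }
  invisible(x)
}

#' Plot a fish's daily maxima with detected descents
#'
#' Daily maximum depth (depth axis reversed, surface on top) with descent
#' days marked and valid sequences shaded.
#'
#' @param x a `periodic_descents` object.
#' @param fish_id which fish to draw (default: the first flagged fish,
#'   else the first fish).
#' @param ... passed to [graphics::plot()].
#' @export
plot.periodic_descents <- function(x, fish_id = NULL, ...) {
  if (is.null(fish_id))
    fish_id <- if (any(x$flags)) names(x$flags)[which(x$flags)[1L]]
               else names(x$flags)[1L]
  d <- x$daily[x$daily$fish_id == fish_id, , drop = FALSE]
  .check(nrow(d) > 0, paste("no daily maxima for fish", fish_id))
  graphics::plot(d$date, d$max_depth_m, type = "b", pch = 16,
                 ylim = rev(range(d$max_depth_m)),
                 xlab = "date", ylab = "daily max depth (m)",
                 main = paste("periodic descents:", fish_id), ...)
  sq <- x$sequences[x$sequences$fish_id == fish_id & x$sequences$valid, ,
                    drop = FALSE]
  if (nrow(sq)) {
    usr <- graphics::par("usr")
    for (i in seq_len(nrow(sq)))
      graphics::rect(as.numeric(sq$start_date[i]) - 0.5, usr[3],
                     as.numeric(sq$end_date[i]) + 0.5, usr[4],
                     col = grDevices::adjustcolor("steelblue", 0.15),
                     border = NA)
  }
  ev <- x$events[x$events$fish_id == fish_id, , drop = FALSE]
  if (nrow(ev))
    graphics::points(ev$date, ev$max_depth_m, pch = 21, cex = 1.6,
                     bg = "orange")
  invisible(x)
}

#' Sweep the sensitivity-scenario grid
#'
#' Reruns the classifier over all combinations of the three criteria --
#' by default the 2x2x2 grid depth ratio {1.5, 2}, gap {6, 10} days,
#' minimum descents {2, 3}, i.e. eight scenarios -- and tabulates per-fish
#' flags and, when metadata are supplied, flag counts and proportions per
#' ground and sex.
#'
#' @param daily a [daily_maxima()] data frame.
#' @param fish optional fish metadata table.
#' @param ratios,gaps,mins criterion values to cross.
#' @return A list: `summary` (one row per scenario: criteria, `n_flagged`,
#'   and per-sex counts if available), `flags` (fish x scenario logical
#'   matrix), `by_group` (per scenario x ground x sex counts/proportions,
#'   when `fish` given).
#' @export
run_scenarios <- function(daily, fish = NULL, ratios = c(1.5, 2),
                          gaps = c(6L, 10L), mins = c(2L, 3L)) {
  grid <- expand.grid(depth_ratio = ratios, max_gap_days = gaps,
                      min_descents = mins, KEEP.OUT.ATTRS = FALSE)
  flags <- NULL
  by_group <- list()
  summ <- grid
  summ$n_flagged <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    cr <- descent_criteria(grid$depth_ratio[i], grid$max_gap_days[i],
                           grid$min_descents[i])
    fit <- periodic_descents(daily, cr, fish = fish)
    if (is.null(flags))
      flags <- matrix(FALSE, nrow = length(fit$flags), ncol = nrow(grid),
                      dimnames = list(names(fit$flags),
                                      sprintf("r%.1f_g%d_m%d",
                                              grid$depth_ratio,
                                              grid$max_gap_days,
                                              grid$min_descents)))
    flags[names(fit$flags), i] <- fit$flags
    summ$n_flagged[i] <- sum(fit$flags)
    if (!is.null(fish)) {
      m <- match(names(fit$flags), fish$fish_id)
      g <- data.frame(scenario = colnames(flags)[i],
                      ground = fish$ground[m], sex = fish$sex[m],
                      flagged = fit$flags, stringsAsFactors = FALSE)
      agg <- stats::aggregate(flagged ~ scenario + ground + sex, g,
                              function(z) c(n = length(z), n_flagged = sum(z)))
      agg <- cbind(agg[, 1:3],
                   n = agg$flagged[, "n"],
                   n_flagged = agg$flagged[, "n_flagged"])
      agg$prop_flagged <- agg$n_flagged / agg$n
      by_group[[i]] <- agg
    }
  }
  if (!is.null(fish)) {
    m <- match(rownames(flags), fish$fish_id)
    sexv <- fish$sex[m]
    summ$n_female_flagged <- colSums(flags & !is.na(sexv) & sexv == "F")
    summ$n_male_flagged <- colSums(flags & !is.na(sexv) & sexv == "M")
  }
  list(summary = summ, flags = flags,
       by_group = if (length(by_group)) do.call(rbind, by_group) else NULL)
}
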