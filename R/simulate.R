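# Synthetic acoustic-telemetry generator. Emulates the statistical
# structure the downstream analysis assumes -- sex-specific baseline
# depths, diel shoaling, female spawning descents recurring at ~68 h,
# imperfect detection, cross-receiver duplicates, dead and stray fish,
# receiver clock drift and a harmonic tide riding on the depth sensor --
# and emits a ground-truth log so every pipeline stage can be checked
# against what was planted.

#' Simulate the tagged-fish cohort and its ground truth
#'
#' Draws the cohort (sexes per `n_females`/`n_males`, lengths uniform on
#' 45--90 cm) and plants the hidden structure: which females are batch
#' spawners (with descent peak times following a truncated-Normal renewal
#' process), which fish die mid-study, and which are strays contributing
#' only isolated single-day detections. Everything is reproducible from
#' `params$seed`.
#'
#' @param params a [sim_params()] object.
#' @return A `sim_truth` list with elements `fish` (one row per fish:
#'   `fish_id`, `tag_id`, `sex`, `length_cm`, `tagging_date`, `ground`,
#'   `region`, `is_spawner`, `is_dead`, `death_time`, `frozen_depth_m`,
#'   `is_stray`) and `descents` (one row per planted descent: `fish_id`,
#'   `t_start`, `t_peak`, `t_end`, `peak_depth_m`).
#' @export
simulate_fish_cohort <- function(params) {
  validate_sim_params(params)
  set.seed(params$seed)
  n <- params$n_females + params$n_males
  t0 <- .as_utc(params$study_start)
  t1 <- .as_utc(params$study_end)

  fish <- data.frame(
    fish_id = sprintf("FISH%03d", seq_len(max(n, 0L))),
    tag_id = sprintf("TAG%03d", seq_len(max(n, 0L))),
    sex = rep(c("F", "M"), c(params$n_females, params$n_males)),
    length_cm = round(stats::runif(n, 45, 90), 1),
    tagging_date = rep(params$study_start, n),
    ground = if (n > 0) sample(c("WN_1", "WN_2"), n, replace = TRUE) else character(0),
    region = rep("WN", n),
    stringsAsFactors = FALSE)
  if (n == 0L) {
    fish <- fish[0, ]
    truth <- list(fish = cbind(fish, is_spawner = logical(0),
                               is_dead = logical(0),
                               death_time = .as_utc(numeric(0)),
                               frozen_depth_m = numeric(0),
                               is_stray = logical(0)),
                  descents = data.frame(fish_id = character(0),
                                        t_start = .as_utc(numeric(0)),
                                        t_peak = .as_utc(numeric(0)),
                                        t_end = .as_utc(numeric(0)),
                                        peak_depth_m = numeric(0)))
    class(truth) <- "sim_truth"
    return(truth)
  }

  females <- which(fish$sex == "F")
  n_sp <- round(params$prop_spawning_females * length(females))
  spawners <- if (n_sp > 0) sort(sample(females, n_sp)) else integer(0)
  fish$is_spawner <- seq_len(n) %in% spawners

  # dead and stray flags drawn from non-spawners first, so planted descent
  # structure is never destroyed by the planted artefacts
  pool <- setdiff(seq_len(n), spawners)
  .check(length(pool) >= params$n_dead_fish + params$n_stray_fish,
         "not enough non-spawner fish for the requested dead+stray flags")
  picks <- if (length(pool)) sample(pool, params$n_dead_fish + params$n_stray_fish)
           else integer(0)
  dead <- picks[seq_len(params$n_dead_fish)]
  stray <- setdiff(picks, dead)
  fish$is_dead <- seq_len(n) %in% dead
  fish$is_stray <- seq_len(n) %in% stray
  span_s <- as.numeric(t1) - as.numeric(t0)
  fish$death_time <- .as_utc(rep(NA_real_, n))
  fish$death_time[dead] <- t0 + stats::runif(length(dead), 0.35, 0.55) * span_s
  base <- ifelse(fish$sex == "F", params$female_baseline_depth_m,
                 params$male_baseline_depth_m)
  fish$frozen_depth_m <- ifelse(fish$is_dead,
                                base + stats::rnorm(n, 0, params$depth_noise_sd_m),
                                NA_real_)

  # planted descents: first peak 1-3 days after release, then a renewal
  # process with Normal(mean, sd) increments truncated below at 12 h
  desc <- vector("list", length(spawners))
  half_s <- params$descent_duration_h * 3600 / 2
  for (k in seq_along(spawners)) {
    i <- spawners[k]
    peaks <- numeric(0)
    p <- as.numeric(t0) + stats::runif(1, 24, 72) * 3600
    while (p + half_s < as.numeric(t1)) {
      peaks <- c(peaks, p)
      p <- p + max(12, stats::rnorm(1, params$batch_interval_mean_h,
                                    params$batch_interval_sd_h)) * 3600
    }
    if (length(peaks))
      desc[[k]] <- data.frame(fish_id = fish$fish_id[i],
                              t_peak = peaks, stringsAsFactors = FALSE)
  }
  desc <- do.call(rbind, desc)
  if (is.null(desc))
    desc <- data.frame(fish_id = character(0), t_peak = numeric(0))
  descents <- data.frame(
    fish_id = desc$fish_id,
    t_start = .as_utc(desc$t_peak - half_s),
    t_peak = .as_utc(desc$t_peak),
    t_end = .as_utc(desc$t_peak + half_s),
    peak_depth_m = rep(params$descent_target_depth_m, nrow(desc)),
    stringsAsFactors = FALSE)

  truth <- list(fish = fish, descents = descents)
  class(truth) <- "sim_truth"
  truth
}

#' True swimming depth of a simulated fish
#'
#' Evaluates the planted depth model at arbitrary times: sex-specific
#' baseline, diel term (shallower by `diel_amplitude_m` between sunset and
#' sunrise), Gaussian noise, a symmetric linear ramp to
#' `descent_target_depth_m` around each planted descent peak for spawner
#' females, and a frozen constant depth after death for dead fish. Depths
#' are clipped at 0 (the surface).
#'
#' @param fish_id a single fish id present in `truth`.
#' @param truth a `sim_truth` from [simulate_fish_cohort()].
#' @param params the [sim_params()] used to build `truth`.
#' @param t POSIXct vector of evaluation times within the study window.
#' @return Depths in metres, positive down.
#' @export
simulate_depth <- function(fish_id, truth, params, t) {
  i <- match(fish_id, truth$fish$fish_id)
  .check(!is.na(i), paste("unknown fish id:", fish_id))
  t <- .as_utc(t)
  fr <- truth$fish[i, ]
  base <- if (fr$sex == "F") params$female_baseline_depth_m else params$male_baseline_depth_m
  ambient <- rep(base, length(t))
  if (params$diel_amplitude_m != 0) {
    night <- label_day_night(t, params$solar_lon, params$solar_lat) == "night"
    ambient <- ambient - params$diel_amplitude_m * night
  }
  depth <- ambient
  if (isTRUE(fr$is_spawner)) {
    dsc <- truth$descents[truth$descents$fish_id == fr$fish_id, ]
    if (nrow(dsc)) {
      half_s <- params$descent_duration_h * 3600 / 2
      pk <- as.numeric(dsc$t_peak)
      tt <- as.numeric(t)
      j <- if (length(pk) == 1L) rep(1L, length(tt))
      else pmax(1L, pmin(length(pk), round(stats::approx(
        pk, seq_along(pk), xout = tt, rule = 2, ties = "ordered")$y)))
      w <- pmax(0, 1 - abs(tt - pk[j]) / half_s)
      depth <- ambient + (dsc$peak_depth_m[j] - ambient) * w
    }
  }
  if (params$depth_noise_sd_m > 0)
    depth <- depth + stats::rnorm(length(t), 0, params$depth_noise_sd_m)
  if (isTRUE(fr$is_dead)) {
    dead_at <- t >= fr$death_time
    depth[dead_at] <- fr$frozen_depth_m
  }
  pmax(depth, 0)
}

#' Simulate the receiver detection log
#'
#' Per fish, transmission times follow a renewal process with
#' uniform(`transmit_delay_min_s`, `transmit_delay_max_s`) gaps. Each
#' transmission is independently detected with `detection_prob` at a random
#' station; with probability `duplicate_prob` a detected transmission is
#' additionally logged at a second station within 200 s. The sensor value
#' is the tide-displaced depth (true depth plus the current sea-level
#' deviation from the mean), so downstream tidal correction is meaningful,
#' and recorded timestamps carry each receiver's linear clock drift, so
#' drift correction is meaningful too. Stray fish contribute exactly one
#' detection on each of two isolated days more than 7 days apart.
#'
#' @param truth a `sim_truth` from [simulate_fish_cohort()].
#' @param params the matching [sim_params()].
#' @param tide optionally, a precomputed [simulate_tide()] series.
#' @return A list: `detections` (data frame `timestamp`, `station_id`,
#'   `tag_id`, `sensor`, `value`, time-sorted recorded timestamps),
#'   `clocks` (per-station `ReceiverClock` rows: `station_id`,
#'   `deploy_time`, `download_time`, `offset_deploy_s`,
#'   `offset_download_s`), and `true_times` (POSIXct true arrival time of
#'   every logged row, for round-trip checks).
#' @export
simulate_detections <- function(truth, params, tide = simulate_tide(params)) {
  validate_sim_params(params)
  .check(nrow(truth$fish) > 0, "cohort is empty")
  set.seed(params$seed + 1L)
  t0 <- .as_utc(params$study_start)
  t1 <- .as_utc(params$study_end)
  span_s <- as.numeric(t1) - as.numeric(t0)
  stations <- sprintf("ST%02d", seq_len(params$n_stations))

  rows <- vector("list", nrow(truth$fish))
  for (i in seq_len(nrow(truth$fish))) {
    fr <- truth$fish[i, ]
    if (fr$is_stray) {
      # two isolated single-detection days, > 7 days apart
      d1 <- stats::runif(1, 1, span_s / 86400 / 3)
      d2 <- d1 + stats::runif(1, 8, 14)
      tt <- as.numeric(t0) + floor(c(d1, d2)) * 86400 +
        stats::runif(2, 0, 86399)
      tt <- tt[tt < as.numeric(t1)]
      if (!length(tt)) next
      det_t <- tt
    } else {
      n_est <- ceiling(span_s / params$transmit_delay_min_s) + 2L
      gaps <- stats::runif(n_est, params$transmit_delay_min_s,
                           params$transmit_delay_max_s)
      tt <- as.numeric(t0) + stats::runif(1, 0, params$transmit_delay_max_s) +
        cumsum(gaps)
      tt <- tt[tt < as.numeric(t1)]
      keep <- stats::runif(length(tt)) < params$detection_prob
      det_t <- tt[keep]
      if (!length(det_t)) next
    }
    st <- sample(stations, length(det_t), replace = TRUE)
    depth <- simulate_depth(fr$fish_id, truth, params, .as_utc(det_t))
    frozen <- if (isTRUE(fr$is_dead)) det_t >= as.numeric(fr$death_time)
              else rep(FALSE, length(det_t))
    # the tide displacement rides on the pressure reading encoded in the
    # transmission, so it is added before any cross-receiver duplication
    # (every receiver logs the same sensor value); a dead tag lying on the
    # seabed is planted as a genuinely flat record, so frozen rows keep
    # their constant value
    live <- !frozen
    depth[live] <- pmax(0, depth[live] +
                          interpolate_sea_level(tide, .as_utc(det_t[live])) -
                          attr(tide, "mean_level_m"))
    out <- data.frame(true_time = det_t, station_id = st,
                      tag_id = fr$tag_id, value = depth, frozen = frozen,
                      stringsAsFactors = FALSE)
    if (params$duplicate_prob > 0 && !fr$is_stray && nrow(out) > 0) {
      dup <- stats::runif(nrow(out)) < params$duplicate_prob
      if (any(dup)) {
        second <- vapply(st[dup], function(s)
          sample(setdiff(stations, s), 1L), character(1))
        extra <- data.frame(
          true_time = out$true_time[dup] + stats::runif(sum(dup), 1, 198),
          station_id = second, tag_id = fr$tag_id,
          value = out$value[dup], frozen = out$frozen[dup],
          stringsAsFactors = FALSE)
        extra <- extra[extra$true_time < as.numeric(t1), , drop = FALSE]
        out <- rbind(out, extra)
      }
    }
    rows[[i]] <- out
  }
  det <- do.call(rbind, rows)
  .check(!is.null(det) && nrow(det) > 0 || params$detection_prob == 0,
         "simulation produced no detections")
  if (is.null(det))
    det <- data.frame(true_time = numeric(0), station_id = character(0),
                      tag_id = character(0), value = numeric(0),
                      frozen = logical(0))

  # linear receiver clock drift, identical rate at every station; the
  # download happens after the last (drifted) record so corrections are
  # never clamped
  dl_margin <- abs(params$clock_drift_s_per_day) * span_s / 86400 + 60
  download <- .as_utc(round(as.numeric(t1) + dl_margin))
  drift_total <- params$clock_drift_s_per_day *
    (as.numeric(download) - as.numeric(t0)) / 86400
  rec <- det$true_time +
    params$clock_drift_s_per_day * (det$true_time - as.numeric(t0)) / 86400
  det$timestamp <- .as_utc(round(rec))
  o <- order(det$timestamp, det$station_id)
  det <- det[o, ]
  detections <- data.frame(timestamp = det$timestamp,
                           station_id = det$station_id,
                           tag_id = det$tag_id,
                           sensor = rep("depth", nrow(det)),
                           value = det$value,
                           stringsAsFactors = FALSE)
  clocks <- data.frame(station_id = stations,
                       deploy_time = t0, download_time = download,
                       offset_deploy_s = 0,
                       offset_download_s = drift_total,
                       stringsAsFactors = FALSE)
  list(detections = detections, clocks = clocks,
       true_times = .as_utc(det$true_time))
}

#' Run the full synthetic-telemetry generator
#'
#' Convenience wrapper: builds the cohort and ground truth, the tide
#' series, and the detection log from one parameter set.
#'
#' @param params a [sim_params()] object.
#' @return A list with `params`, `truth`, `fish` (metadata table),
#'   `tide`, `detections`, `clocks`, `true_times`.
#' @examples
#' sim <- simulate_telemetry(sim_params(n_females = 2, n_males = 2,
#'                                      study_end = as.Date("2019-02-08")))
#' head(sim$detections)
#' @export
simulate_telemetry <- function(params = sim_params()) {
  truth <- simulate_fish_cohort(params)
  tide <- simulate_tide(params)
  dets <- simulate_detections(truth, params, tide)
  list(params = params, truth = truth,
       fish = truth$fish[, c("tag_id", "fish_id", "sex", "length_cm",
                             "tagging_date", "ground", "region")],
       tide = tide, detections = dets$detections, clocks = dets$clocks,
       true_times = dets$true_times)
}

#' Write a simulated dataset to disk
#'
#' Emits the standard CSV schemas (detections, tide, fish metadata,
#' receiver clocks) plus the ground-truth log as JSON.
#'
#' @param sim output of [simulate_telemetry()].
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(
    data.frame(timestamp = .fmt_utc(sim$detections$timestamp),
               station_id = sim$detections$station_id,
               tag_id = sim$detections$tag_id,
               sensor = sim$detections$sensor,
               value = sim$detections$value),
    file.path(dir, "detections.csv"), row.names = FALSE, quote = FALSE)
  write_tide(sim$tide, file.path(dir, "tide.csv"))
  utils::write.csv(sim$fish, file.path(dir, "fish.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(station_id = sim$clocks$station_id,
               deploy_time = .fmt_utc(sim$clocks$deploy_time),
               download_time = .fmt_utc(sim$clocks$download_time),
               offset_deploy_s = sim$clocks$offset_deploy_s,
               offset_download_s = sim$clocks$offset_download_s),
    file.path(dir, "clocks.csv"), row.names = FALSE, quote = FALSE)
  tr <- sim$truth
  truth_json <- list(
    fish = data.frame(tr$fish[, c("fish_id", "sex", "length_cm")],
                      is_spawner = tr$fish$is_spawner,
                      is_dead = tr$fish$is_dead,
                      death_time = ifelse(tr$fish$is_dead,
                                          .fmt_utc(tr$fish$death_time), NA),
                      is_stray = tr$fish$is_stray),
    descents = data.frame(fish_id = tr$descents$fish_id,
                          t_start = .fmt_utc(tr$descents$t_start),
                          t_peak = .fmt_utc(tr$descents$t_peak),
                          t_end = .fmt_utc(tr$descents$t_end),
                          peak_depth_m = tr$descents$peak_depth_m))
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
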