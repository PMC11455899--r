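# Builders for hand-constructed detection streams and the planted-artefact
# QC fixture used across tests.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# a detection stream row block for one fish
det_block <- function(fish_id, times, depths, station = "ST01",
                      tag_id = fish_id) {
  data.frame(timestamp = utc(times), station_id = station, tag_id = tag_id,
             sensor = "depth", value = depths, fish_id = fish_id,
             sex = "F", length_cm = 60, tagging_date = as.Date("2019-01-20"),
             ground = "WN_1", region = "WN", stringsAsFactors = FALSE)
}

# Ten-fish fixture with a manifest of planted artefacts:
#   * 2 dead fish: live oscillating for 2 days, then flat (identical depth)
#     for 48 h -> the flat-segment detections are the planted removals
#   * 5 cross-station duplicates: extra station-B records 100 s after
#     genuine station-A records of one fish
#   * 3 single-day strays: three fish whose only record is one detection
#     on one day
#   * 5 clean fish oscillating hourly
qc_fixture <- function() {
  t0 <- utc("2019-03-01 00:00:00")
  hours <- function(h) t0 + h * 3600
  blocks <- list()
  manifest <- list(dead = 0L, duplicates = 0L, single_day = 0L)

  # clean fish C1..C5: hourly detections, +-5 m oscillation, 4 days
  for (k in 1:5) {
    h <- 0:95
    blocks[[paste0("C", k)]] <-
      det_block(paste0("C", k), hours(h), 25 + 5 * (-1)^h,
                station = c("ST01", "ST02")[1 + k %% 2])
  }

  # dead fish D1, D2: 48 h live (hourly, oscillating, ending shallow),
  # then 48 h flat at 30.0 m
  for (k in 1:2) {
    h_live <- 0:47
    h_flat <- 48:95
    b <- rbind(det_block(paste0("D", k), hours(h_live), 20 + 5 * (-1)^h_live),
               det_block(paste0("D", k), hours(h_flat), rep(30.0, 48)))
    blocks[[paste0("D", k)]] <- b
    manifest$dead <- manifest$dead + length(h_flat)
  }

  # duplicate fish P1: station ST01 every 300 s for 2 days, plus 5 planted
  # echoes at ST02 100 s after the first five records of each day 1
  tt <- seq(0, 2 * 86400 - 1, by = 300)
  p1_depth <- 28 + 3 * (-1)^seq_along(tt)
  base <- det_block("P1", t0 + tt, p1_depth, station = "ST01")
  dup_idx <- 1:5
  dups <- det_block("P1", t0 + tt[dup_idx] + 100, p1_depth[dup_idx],
                    station = "ST02")
  blocks[["P1"]] <- rbind(base, dups)
  manifest$duplicates <- 5L

  # strays S1..S3: a single detection on one day each
  for (k in 1:3) {
    blocks[[paste0("S", k)]] <-
      det_block(paste0("S", k), hours(10 + k), 22 + k)
    manifest$single_day <- manifest$single_day + 1L
  }

  stream <- do.call(rbind, blocks)
  stream <- stream[order(stream$timestamp), ]
  rownames(stream) <- NULL
  list(stream = stream, manifest = manifest)
}

# random small daily-max track for oracle-equivalence checks
random_daily_track <- function(fish_id = "fx", n_days_max = 40) {
  span <- sample(5:n_days_max, 1)
  offs <- sort(sample(0:(span - 1), max(2, rbinom(1, span, 0.8))))
  dates <- as.Date("2019-02-01") + offs
  depth <- round(runif(length(dates), 10, 35), 1)
  # sprinkle spikes so descents actually occur
  spikes <- runif(length(dates)) < 0.25
  depth[spikes] <- depth[spikes] + runif(sum(spikes), 10, 40)
  data.frame(fish_id = fish_id, date = dates, max_depth_m = depth,
             time_of_max = utc(paste(dates, "12:00:00")) +
               round(runif(length(dates), -6, 6) * 3600),
             n_detections = 50L, stringsAsFactors = FALSE)
}
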