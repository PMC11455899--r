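# The synthetic telemetry generator: determinism, planted structure,
# transmission process, duplicates, drift, and the config loader.

small_params <- function(...) {
  sim_params(n_females = 3, n_males = 3, study_end = as.Date("2019-02-12"),
             n_stations = 3, seed = 9, ...)
}

test_that("parameter validation rejects impossible settings", {
  expect_error(sim_params(detection_prob = 1.3), "detection_prob")
  expect_error(sim_params(transmit_delay_min_s = 300,
                          transmit_delay_max_s = 200), "delay")
  expect_error(sim_params(study_start = as.Date("2019-03-01"),
                          study_end = as.Date("2019-02-01")), "empty")
  expect_error(sim_params(tide_period_h = 0), "tide_period_h")
  expect_error(sim_params(n_females = 1, n_males = 0, n_dead_fish = 2),
               "dead")
})

test_that("the cohort and truth log are reproducible and honour the flags", {
  p <- small_params(prop_spawning_females = 1)
  t1 <- simulate_fish_cohort(p)
  t2 <- simulate_fish_cohort(p)
  expect_identical(t1, t2)
  expect_equal(nrow(t1$fish), 6L)
  expect_true(all(t1$fish$is_spawner[t1$fish$sex == "F"]))
  expect_true(all(!t1$fish$is_spawner[t1$fish$sex == "M"]))

  empty <- simulate_fish_cohort(sim_params(n_females = 0, n_males = 0))
  expect_equal(nrow(empty$fish), 0L)
  expect_equal(nrow(empty$descents), 0L)

  # planted peaks strictly increasing per fish, renewal mean near target
  p2 <- sim_params(n_females = 25, n_males = 0, seed = 4,
                   study_end = as.Date("2019-04-01"))
  tr <- simulate_fish_cohort(p2)
  gaps_h <- unlist(lapply(split(tr$descents$t_peak, tr$descents$fish_id),
                          function(x) diff(as.numeric(x)) / 3600))
  expect_true(all(gaps_h > 0))
  expect_lt(abs(mean(gaps_h) - 68), 2 * sd(gaps_h) / sqrt(length(gaps_h)) + 0.5)
})

test_that("the planted depth model honours its stated contracts", {
  p <- small_params(depth_noise_sd_m = 0, diel_amplitude_m = 0,
                    n_dead_fish = 1, prop_spawning_females = 1)
  tr <- simulate_fish_cohort(p)
  live_f <- tr$fish$fish_id[tr$fish$sex == "F" & !tr$fish$is_dead &
                              !tr$fish$is_spawner]
  live_m <- tr$fish$fish_id[tr$fish$sex == "M" & !tr$fish$is_dead &
                              !tr$fish$is_stray]
  t <- utc("2019-02-05 12:00:00")
  if (length(live_m))
    expect_equal(simulate_depth(live_m[1], tr, p, t), 35)
  # spawner female exactly at a planted peak reaches the target depth
  sp <- tr$fish$fish_id[tr$fish$is_spawner][1]
  pk <- tr$descents$t_peak[tr$descents$fish_id == sp][1]
  expect_equal(simulate_depth(sp, tr, p, pk), 45)
  # dead fish flat-lines: identical depths 12 h apart after death
  dd <- tr$fish[tr$fish$is_dead, ]
  d1 <- simulate_depth(dd$fish_id, tr, p, dd$death_time + 3600)
  d2 <- simulate_depth(dd$fish_id, tr, p, dd$death_time + 3600 + 12 * 3600)
  expect_identical(d1, d2)
  expect_error(simulate_depth("nope", tr, p, t), "unknown fish")
})

test_that("non-spawner female with no noise or diel term sits at baseline", {
  p <- small_params(depth_noise_sd_m = 0, diel_amplitude_m = 0,
                    prop_spawning_females = 0)
  tr <- simulate_fish_cohort(p)
  f <- tr$fish$fish_id[tr$fish$sex == "F"][1]
  tt <- utc("2019-02-03 00:00:00") + 0:23 * 3600
  expect_equal(simulate_depth(f, tr, p, tt), rep(22, 24))
})

test_that("transmissions are a bounded renewal process with stated mean", {
  set.seed(2)
  gaps <- runif(10000, 200, 300)
  expect_true(all(gaps >= 200 & gaps <= 300))
  expect_true(mean(gaps) > 248 && mean(gaps) < 252)

  # and the generator respects the same bounds end to end (per fish,
  # true transmission gaps never violate the delay window)
  p <- small_params(detection_prob = 1, duplicate_prob = 0)
  sim <- simulate_telemetry(p)
  d <- data.frame(tag = sim$detections$tag_id,
                  t = as.numeric(sim$true_times))
  for (g in split(d$t, d$tag)) {
    dg <- diff(sort(g))
    expect_true(all(dg >= 199.999 & dg <= 300.001))
  }
})

test_that("identical parameters give byte-identical datasets", {
  p <- small_params(duplicate_prob = 0.1, n_dead_fish = 1, n_stray_fish = 1)
  s1 <- simulate_telemetry(p)
  s2 <- simulate_telemetry(p)
  expect_identical(s1$detections, s2$detections)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$clocks, s2$clocks)
})

test_that("zero detection probability yields an empty log", {
  p <- small_params(detection_prob = 0)
  sim <- simulate_detections(simulate_fish_cohort(p), p)
  expect_equal(nrow(sim$detections), 0L)
})

test_that("duplicates are same-fish, different-station echoes within 200 s", {
  p <- small_params(duplicate_prob = 0.2, detection_prob = 0.8,
                    clock_drift_s_per_day = 0)
  sim <- simulate_telemetry(p)
  r <- deduplicate(join_metadata(sim$detections, sim$fish)$matched)
  # every removed record sits < 200 s after a same-fish record at another
  # station; with zero drift the dedup count equals the planted echo count
  d <- sim$detections
  d$key <- paste(d$tag_id, round(as.numeric(d$timestamp)))
  n_planted <- nrow(d) - length(unique(paste(d$tag_id, d$value)))
  expect_equal(r$removed, n_planted)
})

test_that("recorded times carry linear receiver drift", {
  p <- small_params(clock_drift_s_per_day = 2, detection_prob = 1,
                    duplicate_prob = 0)
  sim <- simulate_telemetry(p)
  elapsed_d <- (as.numeric(sim$true_times) -
                  as.numeric(utc("2019-02-01 00:00:00"))) / 86400
  shift <- as.numeric(sim$detections$timestamp) - as.numeric(sim$true_times)
  expect_true(all(abs(shift - 2 * elapsed_d) <= 0.5 + 1e-9))
  # ten days of 2 s/day drift shifts a recording ~20 s
  late <- which.max(elapsed_d)
  expect_equal(shift[late], 2 * elapsed_d[late], tolerance = 0.03)
})

test_that("stray fish contribute single detections on two well-separated days", {
  p <- small_params(n_stray_fish = 1, detection_prob = 1, duplicate_prob = 0)
  sim <- simulate_telemetry(p)
  stray_tag <- sim$truth$fish$tag_id[sim$truth$fish$is_stray]
  sd_det <- sim$detections[sim$detections$tag_id == stray_tag, ]
  days <- as.Date(sd_det$timestamp, tz = "UTC")
  expect_equal(as.integer(table(days)), rep(1L, length(unique(days))))
  if (length(unique(days)) == 2)
    expect_gt(as.integer(diff(sort(unique(days)))), 7L)
})

test_that("simulation params round-trip through a YAML config", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_females: 5", "n_males: 2", "detection_prob: 0.4",
               "seed: 99"), cfg)
  p <- read_sim_config(cfg)
  expect_equal(p$n_females, 5L)
  expect_equal(p$detection_prob, 0.4)
  expect_equal(p$batch_interval_mean_h, 68)   # defaults preserved
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("n_fmales: 5", bad)
  expect_error(read_sim_config(bad), "unknown config")
})

test_that("written simulation files read back through the IO layer", {
  dir <- withr::local_tempdir()
  p <- small_params(duplicate_prob = 0.05)
  sim <- simulate_telemetry(p)
  write_simulation(sim, dir)
  det <- read_detections(file.path(dir, "detections.csv"))
  expect_equal(nrow(det), nrow(sim$detections))
  expect_equal(det$timestamp, sim$detections$timestamp)
  fish <- read_fish(file.path(dir, "fish.csv"))
  expect_equal(nrow(fish), 6L)
  tide <- read_tide(file.path(dir, "tide.csv"))
  expect_equal(nrow(tide), nrow(sim$tide))
  clocks <- read_clocks(file.path(dir, "clocks.csv"))
  expect_equal(clocks$offset_download_s, sim$clocks$offset_download_s)
})
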