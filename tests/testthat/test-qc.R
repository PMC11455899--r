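# The three detection filters, period logic, data-rich selection and bursts.

test_that("dead-fish filter removes flat segments from onset onward", {
  t0 <- utc("2019-03-01 00:00:00")
  flat <- det_block("d1", t0 + 0:47 * 3600, rep(30, 48))
  r <- filter_dead_fish(flat)
  expect_equal(nrow(r$stream), 0L)
  expect_equal(r$dead_fish, "d1")

  live <- det_block("l1", t0 + 0:47 * 3600, 25 + 3 * (-1)^(0:47))
  r2 <- filter_dead_fish(live)
  expect_equal(nrow(r2$stream), 48L)
  expect_equal(r2$removed, 0L)

  # 5 live days (10 m daily range) then 3 flat days: exactly the flat
  # segment goes, verified against a brute-force sliding-window scan
  h_live <- 0:(5 * 24 - 1); h_flat <- (5 * 24):(8 * 24 - 1)
  depths <- c(20 + 5 * (-1)^h_live, rep(27, length(h_flat)))
  mixed <- det_block("m1", t0 + c(h_live, h_flat) * 3600, depths)
  r3 <- filter_dead_fish(mixed)
  tt <- as.numeric(mixed$timestamp)
  brute_onset <- NA
  for (i in seq_along(tt)) {
    w <- which(tt >= tt[i] & tt <= tt[i] + 24 * 3600)
    if (length(w) >= 2 && diff(range(mixed$value[w])) < 0.5) {
      brute_onset <- i; break
    }
  }
  expect_equal(brute_onset, 5 * 24 + 1)
  expect_equal(nrow(r3$stream), 5 * 24)
  expect_equal(r3$removed, length(h_flat))
  expect_true(all(r3$stream$timestamp < t0 + 5 * 24 * 3600))
})

test_that("dedup drops cross-station echoes and spares same-station successors", {
  t0 <- utc("2019-03-01 12:00:00")
  ab <- rbind(det_block("f1", t0, 20, station = "ST01"),
              det_block("f1", t0 + 150, 20, station = "ST02"))
  r <- deduplicate(ab)
  expect_equal(r$removed, 1L)
  expect_equal(r$stream$station_id, "ST01")

  aa <- rbind(det_block("f1", t0, 20, station = "ST01"),
              det_block("f1", t0 + 150, 21, station = "ST01"))
  expect_equal(deduplicate(aa)$removed, 0L)

  # chain A(0), B(150), C(340): B dropped; C is 340 s after retained A
  chain <- rbind(det_block("f1", t0, 20, station = "ST01"),
                 det_block("f1", t0 + 150, 20, station = "ST02"),
                 det_block("f1", t0 + 340, 20, station = "ST03"))
  r3 <- deduplicate(chain)
  expect_equal(r3$stream$station_id, c("ST01", "ST03"))

  # idempotence of the scan rule
  again <- deduplicate(r3$stream)
  expect_equal(again$removed, 0L)
  expect_equal(again$stream, r3$stream)
})

test_that("single-day stray detections are removed exactly once", {
  t0 <- utc("2019-03-03 09:00:00")
  s <- rbind(det_block("f1", t0, 20),                      # lone day-3 record
             det_block("f1", t0 + 86400 + 0:49 * 600, runif(50, 18, 25)))
  r <- remove_single_day_detections(s)
  expect_equal(r$removed, 1L)
  expect_equal(nrow(r$stream), 50L)

  paired <- det_block("f2", t0 + rep(0:3, each = 2) * 86400 + c(0, 3600),
                      rep(20:23, each = 2))
  expect_equal(remove_single_day_detections(paired)$removed, 0L)

  only_strays <- det_block("f3", t0 + c(0, 5, 11) * 86400, c(20, 21, 22))
  r3 <- remove_single_day_detections(only_strays)
  expect_equal(nrow(r3$stream), 0L)

  # idempotence: one pass leaves a fixed point
  r4 <- remove_single_day_detections(r$stream)
  expect_equal(r4$removed, 0L)
})

test_that("period assignment follows the regional month sets", {
  mk <- function(ts, region) {
    b <- det_block("f1", utc(ts), 20)
    b$region <- region
    b
  }
  r <- assign_period(mk("2019-03-10 12:00:00", "WN"))
  expect_equal(r$stream$period, "spawning")
  expect_equal(assign_period(mk("2019-04-10 12:00:00", "MN"))$stream$period,
               "spawning")   # April is spawning in mid Norway
  expect_equal(nrow(assign_period(mk("2019-04-10 12:00:00", "WN"))$stream),
               0L)           # ... but transitional in western Norway
  expect_equal(nrow(assign_period(mk("2019-05-10 12:00:00", "MN"))$stream),
               0L)
  expect_equal(assign_period(mk("2019-07-01 12:00:00", "WN"))$stream$period,
               "feeding")
  expect_equal(nrow(assign_period(mk("2019-10-10 12:00:00", "WN"))$stream),
               0L)
  expect_error(assign_period(mk("2019-03-10 12:00:00", "XX")),
               "unknown region")
})

test_that("tagging-year restriction drops other calendar years", {
  b <- det_block("f1", utc(c("2019-12-31 23:00:00", "2020-02-01 10:00:00")),
                 c(20, 21))
  r <- restrict_to_tagging_year(b)
  expect_equal(nrow(r$stream), 1L)
  expect_equal(format(r$stream$timestamp, "%Y"), "2019")
  empty <- restrict_to_tagging_year(b[0, ])
  expect_equal(nrow(empty$stream), 0L)
})

test_that("data-rich selection applies both thresholds inclusively", {
  mk_fish <- function(id, n_days, n_det) {
    per_day <- ceiling(n_det / n_days)
    times <- utc("2019-02-01 00:00:00") +
      rep(0:(n_days - 1), each = per_day) * 86400 +
      seq_len(n_days * per_day) %% 86400
    b <- det_block(id, times[seq_len(n_det)], 20)
    b$period <- "spawning"
    b
  }
  s <- rbind(mk_fish("rich", 25, 2500), mk_fish("few_det", 21, 1999),
             mk_fish("few_days", 20, 5000))
  expect_equal(select_data_rich(s), "rich")
  expect_equal(select_data_rich(s, min_days = 20, min_detections = 1999),
               c("few_days", "few_det", "rich"))
})

test_that("burst counting splits on > 24 h silences", {
  t0 <- utc("2019-02-01 00:00:00")
  dense <- det_block("f1", t0 + 0:99 * 600, 20)
  expect_equal(unname(count_bursts(dense)), 1L)
  gappy <- det_block("f2", c(t0 + 0:9 * 3600, t0 + 10 * 3600 + 30 * 3600 +
                               0:9 * 3600), 20)
  expect_equal(unname(count_bursts(gappy)), 2L)
  single <- det_block("f3", t0, 20)
  expect_equal(unname(count_bursts(single)), 1L)
})

test_that("the QC pipeline logs non-increasing attrition in the paper's order", {
  fx <- qc_fixture()
  qc <- run_qc(fx$stream)
  att <- qc$attrition
  expect_equal(att$stage,
               c("input", "dead_fish_removed", "deduplicated",
                 "single_day_removed", "period_restricted", "tagging_year"))
  expect_true(all(diff(att$detections) <= 0))
  expect_true(all(diff(att$fish) <= 0))
})
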