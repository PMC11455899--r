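# Daily maxima, the three descent criteria, sequence chaining,
# classification, and the sensitivity-scenario grid.

mk_daily <- function(fish_id, dates, depths, times = NULL) {
  dates <- as.Date("2019-03-01") + dates
  if (is.null(times)) times <- utc(paste(dates, "12:00:00"))
  data.frame(fish_id = fish_id, date = dates, max_depth_m = depths,
             time_of_max = times, n_detections = 10L,
             stringsAsFactors = FALSE)
}

test_that("daily maxima take the deepest record, earliest on ties", {
  t0 <- utc("2019-03-05 00:00:00")
  tr <- det_block("f1", t0 + c(1, 2, 3) * 3600, c(10, 42, 30))
  d <- daily_maxima(tr)
  expect_equal(nrow(d), 1L)
  expect_equal(d$max_depth_m, 42)
  expect_equal(d$time_of_max, t0 + 2 * 3600)
  expect_equal(d$n_detections, 3L)

  tie <- det_block("f1", t0 + c(1, 5) * 3600, c(42, 42))
  expect_equal(daily_maxima(tie)$time_of_max, t0 + 1 * 3600)

  many <- det_block("f1", t0 + rep(0:20, each = 3) * 86400 +
                      rep(c(0, 3600, 7200), 21), runif(63, 10, 30))
  expect_equal(nrow(daily_maxima(many)), 21L)
})

test_that("neighbour mean needs both calendar neighbours", {
  d <- mk_daily("f1", c(0, 1, 2), c(30, 60, 34))
  nb <- neighbor_mean(d)
  expect_equal(nb, c(NA, 32, NA))
  # a calendar gap makes flanking days ineligible
  gap <- mk_daily("f1", c(0, 1, 3, 4), c(30, 40, 40, 30))
  expect_true(all(is.na(neighbor_mean(gap))))
  eq <- mk_daily("f1", c(0, 1, 2), c(25, 50, 25))
  expect_equal(neighbor_mean(eq)[2], 25)
  # optional focal-day variant: centred window of three
  expect_equal(neighbor_mean(d, include_focal = TRUE)[2], (30 + 60 + 34) / 3)
})

test_that("descent days follow the inclusive ratio rule", {
  d <- mk_daily("f1", c(0, 1, 2), c(30, 60, 34))
  expect_equal(nrow(detect_descent_days(d, descent_criteria(1.5))), 1L)
  d2 <- mk_daily("f1", c(0, 1, 2), c(30, 45, 34))   # 45 < 1.5 * 32
  expect_equal(nrow(detect_descent_days(d2, descent_criteria(1.5))), 0L)
  # same day fails under the stricter 100%-deeper scenario: 60 < 2 * 32
  expect_equal(nrow(detect_descent_days(d, descent_criteria(2.0))), 0L)
  # threshold is inclusive: exactly 1.5 x neighbour mean qualifies
  d3 <- mk_daily("f1", c(0, 1, 2), c(30, 48, 34))
  expect_equal(nrow(detect_descent_days(d3, descent_criteria(1.5))), 1L)
})

test_that("sequences chain greedily under the calendar-day gap rule", {
  ev <- data.frame(fish_id = "f1", date = as.Date("2019-03-01") + c(0, 3, 11),
                   max_depth_m = 50, neighbor_mean_m = 30,
                   time_of_max = utc("2019-03-01 12:00:00") + c(0, 3, 11) * 86400)
  r <- build_sequences(ev, descent_criteria(max_gap_days = 6))
  expect_equal(r$sequences$n_events, c(2L, 1L))
  expect_equal(r$sequences$valid, c(TRUE, FALSE))

  ev2 <- ev[1:2, ]
  ev2$date <- as.Date("2019-03-01") + c(0, 7)   # 7-day gap
  r2 <- build_sequences(ev2, descent_criteria(max_gap_days = 6))
  expect_equal(r2$sequences$valid, c(FALSE, FALSE))
  r3 <- build_sequences(ev2, descent_criteria(max_gap_days = 10))
  expect_equal(r3$sequences$n_events, 2L)
  expect_true(r3$sequences$valid)
})

test_that("fish classification needs one valid sequence", {
  sq <- data.frame(fish_id = c("a", "b", "b"), sequence_id = c("s1", "s2", "s3"),
                   n_events = c(2L, 1L, 1L), valid = c(TRUE, FALSE, FALSE))
  fl <- classify_fish(sq, fish_ids = c("a", "b", "c"))
  expect_equal(unname(fl), c(TRUE, FALSE, FALSE))
  expect_equal(names(fl), c("a", "b", "c"))
})

test_that("a constant daily max is never a descent for any ratio > 1", {
  d <- mk_daily("f1", 0:14, rep(28, 15))
  for (r in c(1.01, 1.5, 2, 3))
    expect_equal(nrow(detect_descent_days(d, descent_criteria(r))), 0L)
})

test_that("detector matches the brute-force oracle on random small tracks", {
  set.seed(101)
  for (rep in 1:200) {
    daily <- random_daily_track()
    cr <- descent_criteria(sample(c(1.5, 2), 1), sample(c(2:10), 1),
                           sample(2:3, 1))
    fit <- periodic_descents(daily, cr)
    oracle <- oracle_descents(daily, cr$depth_ratio, cr$max_gap_days,
                              cr$min_descents)
    expect_equal(paste(fit$events$fish_id, fit$events$date),
                 paste(oracle$events$fish_id, oracle$events$date))
    expect_equal(fit$events$neighbor_mean_m, oracle$events$neighbor_mean_m)
    expect_equal(unname(fit$flags[names(oracle$flags)]),
                 unname(oracle$flags))
    got_valid <- fit$events[fit$events$valid, ]
    expect_equal(sort(paste(got_valid$fish_id, got_valid$date)),
                 oracle$valid_event_keys)
    expect_equal(sort(fit$sequences$n_events[fit$sequences$valid]),
                 oracle$seq_sizes)
  }
})

test_that("the scenario grid has eight rows and honours relaxation monotonicity", {
  set.seed(7)
  daily <- do.call(rbind, lapply(1:25, function(i)
    random_daily_track(sprintf("f%02d", i))))
  sc <- run_scenarios(daily)
  expect_equal(nrow(sc$summary), 8L)
  expect_equal(ncol(sc$flags), 8L)
  g <- sc$summary
  for (i in seq_len(nrow(g))) for (j in seq_len(nrow(g))) {
    stricter_ratio <- g$depth_ratio[i] >= g$depth_ratio[j]
    stricter_gap <- g$max_gap_days[i] <= g$max_gap_days[j]
    stricter_min <- g$min_descents[i] >= g$min_descents[j]
    differs_one <- sum(g$depth_ratio[i] != g$depth_ratio[j],
                       g$max_gap_days[i] != g$max_gap_days[j],
                       g$min_descents[i] != g$min_descents[j]) == 1
    if (differs_one && stricter_ratio && stricter_gap && stricter_min)
      expect_true(all(sc$flags[, j][sc$flags[, i]]),
                  label = sprintf("containment %s in %s",
                                  colnames(sc$flags)[i], colnames(sc$flags)[j]))
  }
})

test_that("the periodic_descents object prints, summarises and plots", {
  daily <- mk_daily("f1", 0:6, c(30, 45, 30, 31, 48, 30, 30))
  fit <- periodic_descents(daily)
  expect_s3_class(fit, "periodic_descents")
  expect_output(print(fit), "flagged")
  s <- summary(fit)
  expect_equal(s$n_flagged, 1L)
  expect_output(print(s), "valid sequence")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
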