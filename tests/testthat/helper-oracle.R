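# Independent brute-force reimplementation of the periodic-descent rules,
# written with plain loops and no shared code with the package internals.
# Serves as the oracle for equivalence tests.

oracle_descents <- function(daily, depth_ratio, max_gap_days, min_descents) {
  events <- list()
  for (i in seq_len(nrow(daily))) {
    f <- daily$fish_id[i]; d <- daily$date[i]
    prev <- which(daily$fish_id == f & daily$date == d - 1)
    nxt <- which(daily$fish_id == f & daily$date == d + 1)
    if (length(prev) == 1 && length(nxt) == 1) {
      nb <- (daily$max_depth_m[prev] + daily$max_depth_m[nxt]) / 2
      if (daily$max_depth_m[i] >= depth_ratio * nb)
        events[[length(events) + 1]] <-
          data.frame(fish_id = f, date = d, max_depth_m = daily$max_depth_m[i],
                     neighbor_mean_m = nb, stringsAsFactors = FALSE)
    }
  }
  events <- if (length(events)) do.call(rbind, events)
            else data.frame(fish_id = character(0),
                            date = as.Date(character(0)),
                            max_depth_m = numeric(0),
                            neighbor_mean_m = numeric(0))
  # gap-limited chaining, one fish at a time, plain loop
  flags <- setNames(rep(FALSE, length(unique(daily$fish_id))),
                    sort(unique(daily$fish_id)))
  valid_event_keys <- character(0)
  seq_sizes <- integer(0)
  for (f in unique(events$fish_id)) {
    dts <- sort(events$date[events$fish_id == f])
    groups <- list(dts[1])
    if (length(dts) > 1) {
      for (k in 2:length(dts)) {
        g <- groups[[length(groups)]]
        if (as.integer(dts[k] - g[length(g)]) <= max_gap_days)
          groups[[length(groups)]] <- c(g, dts[k])
        else groups[[length(groups) + 1]] <- dts[k]
      }
    }
    for (g in groups) {
      if (length(g) >= min_descents) {
        flags[f] <- TRUE
        valid_event_keys <- c(valid_event_keys, paste(f, g))
        seq_sizes <- c(seq_sizes, length(g))
      }
    }
  }
  list(events = events, flags = flags,
       valid_event_keys = sort(valid_event_keys),
       seq_sizes = sort(seq_sizes))
}

# The end-to-end recovery simulation under the generator's default study
# conditions (40 spawner females vs 40 males, detection prob 0.5), run
# once per test session and shared across tests.
recovery_cache <- new.env(parent = emptyenv())

recovery_run <- function() {
  if (!is.null(recovery_cache$run)) return(recovery_cache$run)
  params <- sim_params(seed = 42L)
  sim <- simulate_telemetry(params)
  corrected <- correct_clock_drift(sim$detections, sim$clocks)
  joined <- join_metadata(corrected, sim$fish)
  qc <- run_qc(joined$matched)
  stream <- qc$stream
  stream$value <- correct_tide(stream$value, stream$timestamp, sim$tide)
  rich <- select_data_rich(stream, period = "spawning")
  stream <- stream[stream$fish_id %in% rich & stream$period == "spawning", ]
  daily <- daily_maxima(stream)
  fit <- periodic_descents(daily, descent_criteria(), fish = sim$fish)
  recovery_cache$run <- list(params = params, sim = sim, qc = qc,
                             stream = stream, daily = daily, fit = fit)
  recovery_cache$run
}
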