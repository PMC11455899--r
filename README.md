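# codescent

Rule-based detection of periodic spawning descents in acoustic-telemetry
depth records of Atlantic cod (*Gadus morhua*), with the full data
pipeline around it: receiver clock-drift correction, detection quality
control, tidal correction of pressure-derived depth, solar day/night
labelling, inter-descent interval statistics, and a synthetic telemetry
generator with a ground-truth log so every stage is testable without
field data.

## The science

Female coastal cod are batch spawners in a lek-like mating system:
males hold a deep layer on the spawning ground while females sit
shallower and descend towards the males when a batch of eggs is ready —
roughly every 2–6 days, about 70 h near 5.5 °C. Depth-sensing acoustic
tags (one pressure reading per transmission, uniform random 200–300 s
delays) make that rhythm visible as brief daily spikes in a female's
maximum depth.

The detector formalises it with three rules applied to the per-day
maximum of tide-corrected depth $D_d$:

* **depth** — day $d$ is a *periodic descent* if
  $D_d \ge r \cdot \tfrac{1}{2}(D_{d-1} + D_{d+1})$, with $r = 1.5$
  ("at least 50 % deeper than the flanking days"); days missing either
  calendar neighbour are ineligible;
* **gap** — consecutive descent days at most $g = 6$ calendar days apart
  chain into one sequence;
* **count** — a sequence with at least $m = 2$ descents is valid, and a
  fish owning one is a *periodic-descent* fish.

A 2×2×2 sensitivity grid ($r \in \{1.5, 2\}$, $g \in \{6, 10\}$,
$m \in \{2, 3\}$ — eight scenarios) shows how the classification moves
as each rule is relaxed or restricted. Within valid sequences, the hours
between successive times of maximum depth proxy the spawning interval,
and each descent is labelled day or night against NOAA sunrise/sunset
times for comparison with a random-timing expectation.

## Worked example

Simulate the default study conditions — 40 spawner females (22 m
baseline, descents to 45 m at Normal(68 h, 6 h) renewal intervals),
40 males (35 m baseline, no descents), detection probability 0.5,
harmonic tide and 2 s/day receiver clock drift — then run the whole
pipeline:

```r
library(codescent)
params <- sim_params(seed = 42)
sim <- simulate_telemetry(params)

det <- correct_clock_drift(sim$detections, sim$clocks)
stream <- run_qc(join_metadata(det, sim$fish)$matched)$stream
stream$value <- correct_tide(stream$value, stream$timestamp, sim$tide)

rich <- select_data_rich(stream, period = "spawning")
daily <- daily_maxima(stream[stream$fish_id %in% rich &
                               stream$period == "spawning", ])
fit <- periodic_descents(daily, fish = sim$fish)
summary(fit)
#> descent criteria: depth >= 1.50 x neighbour mean, gap <= 6 d, >= 2 descents
#> fish: 80   descent days: 726   valid sequences: 47   flagged: 40 (50.0%)
#> by sex:
#>  sex  n n_flagged prop_flagged
#>    F 40        40            1
#>    M 40         0            0

iv <- descent_intervals(fit)
median_interval(iv)
#> [1] 68.55133
head(interval_histogram(iv), 4)
#>   bin_low_h bin_high_h count
#> 1        40         50     1
#> 2        50         60    59
#> 3        60         70   334
#> 4        70         80   205
```

Every planted spawner female and no male is flagged; the recovered
interval median sits within an hour of the planted 68 h, and the modal
10-h bin is [60, 70). `plot(fit)` draws a fish's daily maxima with
descent days and valid sequences marked; `run_scenarios(daily,
fish = sim$fish)` sweeps the eight-scenario grid;
`export_model_tables()` emits analysis-ready tables for external
mixed-model software.

A thin command-line wrapper covering the same pipeline
(`simulate` / `filter` / `detect` / `report`) is installed at
`inst/scripts/codescent-cli.R`.

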