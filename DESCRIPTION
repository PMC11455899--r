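Package: codescent
Title: Periodic-Descent Detection for Acoustic Telemetry of Spawning Cod
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for depth records from acoustically tagged
    Atlantic cod on coastal spawning grounds. Provides detection-table
    quality control (dead-fish removal, cross-receiver deduplication,
    single-day stray removal), receiver clock-drift correction, tidal
    correction of pressure-derived depth, NOAA solar day/night labelling,
    a rule-based detector for periodic spawning descents with a
    sensitivity-scenario grid, inter-descent interval statistics, and a
    synthetic telemetry generator with a ground-truth log so every stage
    can be validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
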