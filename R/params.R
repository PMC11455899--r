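#' Simulation parameters for the synthetic telemetry generator
#'
#' Bundles every knob of the synthetic cod-telemetry generator into a single
#' validated object. Defaults encode the study conditions the generator
#' emulates: depth-sensor tags transmitting at uniform random 200--300 s
#' delays, sex-specific baseline depths (females near 22 m, males near 35 m
#' during spawning), female spawning descents to about 45 m recurring at
#' intervals of roughly 68 h, a semidiurnal harmonic tide (12.42 h), and
#' receiver clocks drifting linearly over the deployment.
#'
#' @param n_females,n_males number of tagged fish of each sex.
#' @param study_start,study_end UTC dates bounding the simulated deployment
#'   (defaults span a February--March spawning season).
#' @param female_baseline_depth_m,male_baseline_depth_m baseline swimming
#'   depths in metres (positive down).
#' @param depth_noise_sd_m Gaussian depth noise, metres.
#' @param diel_amplitude_m night-time shoaling, metres: fish sit this much
#'   shallower between sunset and sunrise.
#' @param descent_target_depth_m peak depth of a planted spawning descent.
#' @param descent_duration_h total duration of the symmetric descent ramp.
#' @param batch_interval_mean_h,batch_interval_sd_h Normal parameters of the
#'   interval between successive planted descents of one female, hours.
#' @param prop_spawning_females fraction of females planted as batch spawners.
#' @param transmit_delay_min_s,transmit_delay_max_s uniform bounds of the tag
#'   transmission delay, seconds.
#' @param detection_prob probability a transmission is logged at all.
#' @param n_stations number of receiver stations.
#' @param duplicate_prob probability a detected transmission is additionally
#'   logged at a second station within 200 s.
#' @param n_dead_fish number of cohort fish planted as dying mid-study
#'   (flat depth afterwards).
#' @param n_stray_fish number of cohort fish reduced to isolated single-day
#'   detections.
#' @param clock_drift_s_per_day linear receiver clock drift, seconds per day.
#' @param tide_amplitude_m,tide_period_h,tide_mean_m harmonic tide parameters
#'   (metres, hours, metres); period defaults to the principal lunar
#'   semidiurnal constituent M2.
#' @param solar_lon,solar_lat location used for sunrise/sunset, decimal
#'   degrees (defaults: the western-Norway study gauge).
#' @param seed integer seed making the whole simulation reproducible.
#'
#' @return An object of class `sim_params` (a validated named list).
#' @seealso [simulate_telemetry()], [read_sim_config()]
#' @export
sim_params <- function(n_females = 40L,
                       n_males = 40L,
                       study_start = as.Date("2019-02-01"),
                       study_end = as.Date("2019-04-01"),
                       female_baseline_depth_m = 22.0,
                       male_baseline_depth_m = 35.0,
                       depth_noise_sd_m = 1.5,
                       diel_amplitude_m = 3.0,
                       descent_target_depth_m = 45.0,
                       descent_duration_h = 6.0,
                       batch_interval_mean_h = 68.0,
                       batch_interval_sd_h = 6.0,
                       prop_spawning_females = 1.0,
                       transmit_delay_min_s = 200,
                       transmit_delay_max_s = 300,
                       detection_prob = 0.5,
                       n_stations = 5L,
                       duplicate_prob = 0.0,
                       n_dead_fish = 0L,
                       n_stray_fish = 0L,
                       clock_drift_s_per_day = 2.0,
                       tide_amplitude_m = 0.5,
                       tide_period_h = 12.42,
                       tide_mean_m = 1.0,
                       solar_lon = 5.149636,
                       solar_lat = 60.080593,
                       seed = 1L) {
  p <- list(n_females = as.integer(n_females), n_males = as.integer(n_males),
            study_start = as.Date(study_start), study_end = as.Date(study_end),
            female_baseline_depth_m = female_baseline_depth_m,
            male_baseline_depth_m = male_baseline_depth_m,
            depth_noise_sd_m = depth_noise_sd_m,
            diel_amplitude_m = diel_amplitude_m,
            descent_target_depth_m = descent_target_depth_m,
            descent_duration_h = descent_duration_h,
            batch_interval_mean_h = batch_interval_mean_h,
            batch_interval_sd_h = batch_interval_sd_h,
            prop_spawning_females = prop_spawning_females,
            transmit_delay_min_s = transmit_delay_min_s,
            transmit_delay_max_s = transmit_delay_max_s,
            detection_prob = detection_prob,
            n_stations = as.integer(n_stations),
            duplicate_prob = duplicate_prob,
            n_dead_fish = as.integer(n_dead_fish),
            n_stray_fish = as.integer(n_stray_fish),
            clock_drift_s_per_day = clock_drift_s_per_day,
            tide_amplitude_m = tide_amplitude_m,
            tide_period_h = tide_period_h,
            tide_mean_m = tide_mean_m,
            solar_lon = solar_lon, solar_lat = solar_lat,
            seed = as.integer(seed))
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

#' @keywords internal
validate_sim_params <- function(p) {
  .check(p$n_females >= 0L && p$n_males >= 0L, "fish counts must be >= 0")
  .check(p$study_start < p$study_end, "study window is empty")
  .check(p$detection_prob >= 0 && p$detection_prob <= 1,
         "detection_prob must be in [0, 1]")
  .check(p$duplicate_prob >= 0 && p$duplicate_prob <= 1,
         "duplicate_prob must be in [0, 1]")
  .check(p$prop_spawning_females >= 0 && p$prop_spawning_females <= 1,
         "prop_spawning_females must be in [0, 1]")
  .check(p$transmit_delay_min_s < p$transmit_delay_max_s,
         "transmit_delay_min_s must be < transmit_delay_max_s")
  .check(p$batch_interval_mean_h > 0, "batch_interval_mean_h must be > 0")
  .check(p$tide_period_h > 0, "tide_period_h must be > 0")
  .check(p$n_dead_fish + p$n_stray_fish <= p$n_females + p$n_males,
         "more dead+stray fish than cohort fish")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic cod-telemetry parameters\n")
  cat(sprintf("  cohort: %d F + %d M, %s to %s (seed %d)\n",
              x$n_females, x$n_males, x$study_start, x$study_end, x$seed))
  cat(sprintf("  depths: F %.1f m / M %.1f m baseline, descents to %.1f m every %.0f +- %.0f h\n",
              x$female_baseline_depth_m, x$male_baseline_depth_m,
              x$descent_target_depth_m, x$batch_interval_mean_h,
              x$batch_interval_sd_h))
  cat(sprintf("  tags: delay U(%g, %g) s, detection prob %.2f at %d stations\n",
              x$transmit_delay_min_s, x$transmit_delay_max_s,
              x$detection_prob, x$n_stations))
  invisible(x)
}

#' Load simulation parameters from a YAML config file
#'
#' Reads a flat YAML mapping whose keys are [sim_params()] argument names;
#' unspecified keys keep their defaults. Unknown keys are an error so typos
#' never pass silently.
#'
#' @param path path to a YAML file.
#' @return A `sim_params` object.
#' @export
read_sim_config <- function(path) {
  .check(file.exists(path), paste("config file not found:", path))
  cfg <- yaml::read_yaml(path)
  known <- names(formals(sim_params))
  bad <- setdiff(names(cfg), known)
  .check(length(bad) == 0L,
         paste("unknown config keys:", paste(bad, collapse = ", ")))
  do.call(sim_params, cfg)
}
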