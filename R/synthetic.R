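#' Synthetic farm study configuration
#'
#' Bundles every knob of the synthetic barn: instrumentation (15 T/RH sensors
#' sampling every 5 minutes, 40 collared cows), the summer climate the barn
#' sits in (daily mean 23 C, maximum 33.2 C, minimum 13.8 C, mean RH 50%),
#' the circadian behavior models per stress regime (defaults:
#' [default_behavior_models()]), behavior noise, and a heatwave schedule that
#' creates genuinely contrasting heat-load strata. The diurnal temperature
#' sinusoid peaks at 15:00 local time, anchored so the daily maximum and
#' minimum equal `temperature_max`/`temperature_min` exactly; relative
#' humidity swings in anti-phase around `rh_mean`.
#'
#' By default the second half of the study days carries a +6 C heatwave
#' offset, so the 24-h accumulated heat load separates cleanly into low
#' (no-stress) and high (heat-stress) quartiles; with a diurnal cycle alone
#' the 24-h load is nearly constant and the quartile labels would be
#' noise-driven.
#'
#' @param n_sensors number of T/RH sensors (default 15).
#' @param n_animals number of collared cows (default 40).
#' @param n_days study length in days (default 14; minimum 2 so the first
#'   24-h heat-load window can complete).
#' @param sample_interval_minutes sensor sampling interval (default 5).
#' @param temperature_mean,temperature_max,temperature_min summer climate
#'   normals in degrees C; must satisfy min < mean < max.
#' @param rh_mean mean relative humidity, percent.
#' @param rh_halfrange half-amplitude of the diurnal RH swing, percentage
#'   points (default 15).
#' @param sensor_noise_sd per-reading Gaussian temperature noise, C
#'   (default 0.3).
#' @param rh_noise_sd per-reading Gaussian RH noise, percentage points
#'   (default 2).
#' @param behavior_models nested list of circadian specs per behavior and
#'   regime, as [default_behavior_models()].
#' @param behavior_noise_sd per-animal-hour Gaussian behavior noise, minutes
#'   (default 5; chosen so circadian fits on a 40-cow, 14-day study land in
#'   a realistic goodness-of-fit range).
#' @param activity_mid_fraction fraction of the aggregated activity minutes
#'   assigned to mid (vs high) activity (default 0.73; the true collar split
#'   is unpublished and this stand-in is configuration).
#' @param heatwave_schedule list of `list(days = <integer vector>, offset =
#'   <degrees C>)` entries; default one +6 C block over the second half of
#'   the study.
#' @param start_date first day of the simulated study (UTC date).
#' @param seed integer seed driving all randomness.
#' @return a list of class `farm_config`.
#' @export
farm_config <- function(n_sensors = 15, n_animals = 40, n_days = 14,
                        sample_interval_minutes = 5,
                        temperature_mean = 23, temperature_max = 33.2,
                        temperature_min = 13.8,
                        rh_mean = 50, rh_halfrange = 15,
                        sensor_noise_sd = 0.3, rh_noise_sd = 2,
                        behavior_models = default_behavior_models(),
                        behavior_noise_sd = 5,
                        activity_mid_fraction = 0.73,
                        heatwave_schedule = NULL,
                        start_date = "2020-07-01",
                        seed = 1) {
  if (n_days < 2) stop("n_days must be at least 2 (24-h heat-load warm-up)")
  if (!(temperature_min < temperature_mean &&
        temperature_mean < temperature_max)) {
    stop("need temperature_min < temperature_mean < temperature_max")
  }
  if (is.null(heatwave_schedule)) {
    heatwave_schedule <- list(
      list(days = seq(floor(n_days / 2) + 1L, n_days), offset = 6)
    )
  }
  structure(
    list(n_sensors = n_sensors, n_animals = n_animals, n_days = n_days,
         sample_interval_minutes = sample_interval_minutes,
         temperature_mean = temperature_mean,
         temperature_max = temperature_max,
         temperature_min = temperature_min,
         rh_mean = rh_mean, rh_halfrange = rh_halfrange,
         sensor_noise_sd = sensor_noise_sd, rh_noise_sd = rh_noise_sd,
         behavior_models = behavior_models,
         behavior_noise_sd = behavior_noise_sd,
         activity_mid_fraction = activity_mid_fraction,
         heatwave_schedule = heatwave_schedule,
         start_date = start_date, seed = as.integer(seed)),
    class = "farm_config"
  )
}

# noise-free diurnal base values for day-of-study/hour-of-day grids.
# The profile is hourly-resolved: every sample within an hour shares the
# hour's base value, so the ground-truth hourly table is exact.
.env_truth_grid <- function(config) {
  days <- seq_len(config$n_days)
  grid <- expand.grid(hour_of_day = 0:23, day = days)
  centre <- (config$temperature_max + config$temperature_min) / 2
  half <- (config$temperature_max - config$temperature_min) / 2
  temp <- centre + half * cos(2 * pi * (grid$hour_of_day - 15) / 24)
  for (hw in config$heatwave_schedule) {
    temp[grid$day %in% hw$days] <- temp[grid$day %in% hw$days] + hw$offset
  }
  rh <- config$rh_mean - config$rh_halfrange *
    cos(2 * pi * (grid$hour_of_day - 15) / 24)
  rh <- pmin(pmax(rh, 5), 100)
  origin <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")
  data.frame(
    hour_start = origin + ((grid$day - 1) * 24 + grid$hour_of_day) * 3600,
    day = grid$day, hour_of_day = grid$hour_of_day,
    temperature = temp, rh = rh,
    thi = compute_thi(temp, rh)
  )
}

#' Generate synthetic environmental sensor readings
#'
#' Simulates every sensor reading of the study: a diurnal temperature
#' sinusoid peaking at 15:00 (hourly-resolved), plus any heatwave offsets,
#' plus independent Gaussian sensor noise per reading; relative humidity in
#' anti-phase, clamped to \[5, 100\]. One reading per sensor per sampling
#' interval. The noise-free hourly table is returned as ground truth for
#' testing recovery of the hourly means.
#'
#' @param config a [farm_config()].
#' @return list with `samples` (data.frame `sensor_id`, `timestamp`,
#'   `temperature_c`, `rh_pct`) and `truth` (noise-free hourly table with
#'   `hour_start`, `temperature`, `rh`, `thi`).
#' @export
generate_environment <- function(config) {
  stopifnot(inherits(config, "farm_config"))
  set.seed(config$seed)
  truth <- .env_truth_grid(config)
  per_hour <- 60 %/% config$sample_interval_minutes
  n_hours <- nrow(truth)
  # one block of readings per sensor, ordered sensor > hour > within-hour slot
  slot_min <- (seq_len(per_hour) - 1) * config$sample_interval_minutes
  base_idx <- rep(seq_len(n_hours), each = per_hour)
  ts_hour <- rep(truth$hour_start, each = per_hour) + slot_min * 60
  n_per_sensor <- n_hours * per_hour
  sensor_ids <- sprintf("S%02d", seq_len(config$n_sensors))
  n_total <- n_per_sensor * config$n_sensors
  temp <- rep(truth$temperature[base_idx], times = config$n_sensors) +
    stats::rnorm(n_total, sd = config$sensor_noise_sd)
  rh <- rep(truth$rh[base_idx], times = config$n_sensors) +
    stats::rnorm(n_total, sd = config$rh_noise_sd)
  rh <- pmin(pmax(rh, 5), 100)
  samples <- data.frame(
    sensor_id = rep(sensor_ids, each = n_per_sensor),
    timestamp = rep(ts_hour, times = config$n_sensors),
    temperature_c = temp,
    rh_pct = rh,
    stringsAsFactors = FALSE
  )
  list(samples = samples,
       truth = truth[, c("hour_start", "temperature", "rh", "thi")])
}

#' Generate synthetic collar behavior records
#'
#' Simulates per-animal per-hour minutes for the six collar behaviors. Each
#' behavior's minutes are its regime circadian model evaluated at the hour of
#' day plus independent Gaussian noise, truncated at zero; `INTERMEDIATE` and
#' `UNDEFINED` hours use the midpoint of the NS and HS model values.
#' Aggregated activity is simulated from the activity model and split into
#' mid/high activity by `activity_mid_fraction`. If the six-behavior total of
#' an animal-hour exceeds the 60-minute budget, all six are rescaled
#' proportionally to sum to 60 (truncate first, then rescale, preserving
#' non-negativity and the hour budget).
#'
#' @param config a [farm_config()].
#' @param stress_labels data.frame with `hour_start` (POSIXct) and `stress`
#'   (`NS`/`HS`/`INTERMEDIATE`/`UNDEFINED`) covering every simulated hour.
#' @return list with `records` (data.frame `animal_id`, `hour_start`, six
#'   behavior columns) and `truth` (the behavior model specs used).
#' @export
generate_behavior <- function(config, stress_labels) {
  stopifnot(inherits(config, "farm_config"))
  if (!all(c("hour_start", "stress") %in% names(stress_labels))) {
    stop("stress_labels must have hour_start and stress columns")
  }
  set.seed(config$seed + 1L)
  labels <- stress_labels[order(stress_labels$hour_start), , drop = FALSE]
  n_hours <- nrow(labels)
  hour_of_day <- as.integer(
    floor(as.numeric(labels$hour_start) / 3600) %% 24)
  behaviors <- c("eating", "rumination", "rest", "activity",
                 "heavy_breathing")
  # per-hour model values per behavior under the hour's regime
  base <- matrix(NA_real_, n_hours, length(behaviors),
                 dimnames = list(NULL, behaviors))
  for (bh in behaviors) {
    ns <- evaluate_model(config$behavior_models[[bh]]$NS, hour_of_day)
    hs <- evaluate_model(config$behavior_models[[bh]]$HS, hour_of_day)
    mid <- (ns + hs) / 2
    base[, bh] <- ifelse(labels$stress == "NS", ns,
                         ifelse(labels$stress == "HS", hs, mid))
  }
  n_animals <- config$n_animals
  n_rows <- n_animals * n_hours
  # rows ordered animal > hour
  vals <- matrix(NA_real_, n_rows, length(behaviors),
                 dimnames = list(NULL, behaviors))
  for (bh in behaviors) {
    noise <- if (config$behavior_noise_sd > 0) {
      stats::rnorm(n_rows, sd = config$behavior_noise_sd)
    } else 0
    vals[, bh] <- pmax(rep(base[, bh], times = n_animals) + noise, 0)
  }
  records <- data.frame(
    animal_id = rep(sprintf("A%03d", seq_len(n_animals)), each = n_hours),
    hour_start = rep(labels$hour_start, times = n_animals),
    eating = vals[, "eating"],
    rumination = vals[, "rumination"],
    rest = vals[, "rest"],
    mid_activity = config$activity_mid_fraction * vals[, "activity"],
    high_activity = (1 - config$activity_mid_fraction) * vals[, "activity"],
    heavy_breathing = vals[, "heavy_breathing"],
    stringsAsFactors = FALSE
  )
  total <- rowSums(records[, .behavior_cols])
  over <- total > 60
  if (any(over)) {
    scale <- 60 / total[over]
    records[over, .behavior_cols] <- records[over, .behavior_cols] * scale
  }
  list(records = records, truth = config$behavior_models)
}

#' Generate a complete synthetic farm study
#'
#' Runs the full simulation: sensor readings, the hourly THI / heat-load /
#' stress-label chain derived from them through the analysis functions, and
#' behavior records conditioned on those labels. Fully deterministic given
#' `config$seed`. Optionally writes the two CSV inputs (and a ground-truth
#' JSON bundle) so the pipeline can be exercised from files.
#'
#' @param config a [farm_config()].
#' @param out_dir optional directory; when given, writes `sensors.csv`,
#'   `behavior.csv` and `truth.json` there.
#' @return list with `sensor_samples`, `behavior_records`, `hourly`
#'   (aggregated hourly environment), `heat_load` (classified), `labels`
#'   (hour_start + stress), `truth` (environment table + behavior model
#'   specs), and `paths` when files were written.
#' @export
generate_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "farm_config"))
  env <- generate_environment(config)
  hourly <- aggregate_hourly(env$samples)
  load <- classify_stress(compute_heat_load(hourly))
  labels <- load[, c("hour_start", "stress")]
  beh <- generate_behavior(config, labels)
  out <- list(
    sensor_samples = env$samples,
    behavior_records = beh$records,
    hourly = hourly,
    heat_load = load,
    labels = labels,
    truth = list(environment = env$truth, behavior_models = beh$truth,
                 boundaries = attr(load, "boundaries"))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      sensors = file.path(out_dir, "sensors.csv"),
      behavior = file.path(out_dir, "behavior.csv"),
      truth = file.path(out_dir, "truth.json")
    )
    write_sensor_log(env$samples, paths$sensors)
    write_behavior_log(beh$records, paths$behavior)
    truth_json <- list(
      seed = config$seed,
      boundaries = attr(load, "boundaries"),
      environment = data.frame(
        hour_start = format(env$truth$hour_start, "%Y-%m-%dT%H:%M:%S",
                            tz = "UTC"),
        temperature = env$truth$temperature,
        rh = env$truth$rh, thi = env$truth$thi
      ),
      behavior_models = lapply(beh$truth, function(pair) {
        lapply(pair, function(s) s[c("form", "mu", "a", "b", "period1",
                                     "c", "d", "period2")])
      })
    )
    jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE,
                         digits = NA, null = "null")
    out$paths <- paths
  }
  out
}
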