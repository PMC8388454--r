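# in-code fixtures shared across the suite

# write a sensor CSV from vectors; returns the path
sensor_csv <- function(sensor_id, timestamp, temperature_c, rh_pct,
                       path = tempfile(fileext = ".csv")) {
  df <- data.frame(sensor_id = sensor_id, timestamp = timestamp,
                   temperature_c = temperature_c, rh_pct = rh_pct)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

behavior_csv <- function(animal_id, timestamp, eating = 5, rumination = 20,
                         rest = 15, mid_activity = 5, high_activity = 2,
                         heavy_breathing = 1,
                         path = tempfile(fileext = ".csv")) {
  df <- data.frame(animal_id = animal_id, timestamp = timestamp,
                   eating = eating, rumination = rumination, rest = rest,
                   mid_activity = mid_activity,
                   high_activity = high_activity,
                   heavy_breathing = heavy_breathing)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# hourly environment table with a given THI vector on consecutive hours
hourly_from_thi <- function(thi, start = "2020-07-01 00:00:00") {
  h0 <- as.POSIXct(start, tz = "UTC")
  data.frame(hour_start = h0 + (seq_along(thi) - 1) * 3600, thi = thi)
}

hour_seq <- function(n, start = "2020-07-01 00:00:00") {
  as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * 3600
}

# hour-of-day of a POSIXct vector
hod <- function(ts) floor(as.numeric(ts) / 3600) %% 24

# naive RSS of a double/single-harmonic candidate, used as the independent
# brute-force oracle against grid_initialize
naive_rss <- function(hours, values, mu, a, b, period1 = 24,
                      cc = NULL, d = NULL, period2 = NULL) {
  f <- mu + a * sin(2 * pi / period1 * hours + b)
  if (!is.null(cc)) f <- f + cc * cos(2 * pi / period2 * hours - d)
  sum((values - f)^2)
}
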