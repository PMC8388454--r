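test_that("generate_environment produces the expected reading counts", {
  cfg <- farm_config(n_days = 3, seed = 2)
  env <- generate_environment(cfg)
  # 15 sensors x 288 five-minute slots x 3 days
  expect_equal(nrow(env$samples), 15 * 288 * 3)
  expect_equal(length(unique(env$samples$sensor_id)), 15)
  expect_equal(nrow(env$truth), 3 * 24)
  expect_true(all(env$samples$rh_pct >= 5 & env$samples$rh_pct <= 100))
})

test_that("the noise-free diurnal cycle peaks at 15:00 at the daily maximum", {
  cfg <- farm_config(n_days = 2, n_sensors = 2, sensor_noise_sd = 0,
                     rh_noise_sd = 0, heatwave_schedule = list(), seed = 3)
  env <- generate_environment(cfg)
  hourly <- aggregate_hourly(env$samples)
  hod15 <- hod(hourly$hour_start) == 15
  expect_equal(unique(hourly$mean_temperature[hod15]),
               cfg$temperature_max, tolerance = 1e-12)
  hod3 <- hod(hourly$hour_start) == 3
  expect_equal(unique(hourly$mean_temperature[hod3]),
               cfg$temperature_min, tolerance = 1e-12)
  # RH is in anti-phase: lowest at 15:00
  expect_lt(hourly$mean_relative_humidity[hod15][1],
            hourly$mean_relative_humidity[hod3][1])
})

test_that("recovered hourly means track the stored ground truth", {
  cfg <- farm_config(n_days = 2, seed = 4)
  env <- generate_environment(cfg)
  hourly <- aggregate_hourly(env$samples)
  stopifnot(nrow(hourly) == nrow(env$truth))
  # each hourly mean pools 15 sensors x 12 readings of sd-0.3 noise
  se <- cfg$sensor_noise_sd / sqrt(15 * 12)
  err <- hourly$mean_temperature - env$truth$temperature
  expect_lt(max(abs(err)), 5 * se)
})

test_that("heatwave days are offset and drive both stress strata", {
  cfg0 <- farm_config(n_days = 6, n_sensors = 3, sensor_noise_sd = 0,
                      rh_noise_sd = 0, seed = 5,
                      heatwave_schedule = list(list(days = 4:6, offset = 6)))
  env <- generate_environment(cfg0)
  t_by_day <- tapply(env$truth$temperature,
                     rep(1:6, each = 24), mean)
  expect_equal(unname(t_by_day[4] - t_by_day[1]), 6, tolerance = 1e-12)
  # with sensor noise present (the default), heat-load ties are broken and
  # a half-study heatwave populates both strata
  cfg <- farm_config(n_days = 6, n_sensors = 3, seed = 5,
                     heatwave_schedule = list(list(days = 4:6, offset = 6)))
  st <- generate_study(cfg)
  tab <- table(st$labels$stress)
  labelled <- sum(tab[c("NS", "HS", "INTERMEDIATE")])
  expect_gte(tab[["NS"]] / labelled, 0.1)
  expect_gte(tab[["HS"]] / labelled, 0.1)
})

test_that("generate_behavior passes model values through at zero noise", {
  cfg <- farm_config(n_days = 2, n_animals = 2, behavior_noise_sd = 0,
                     seed = 6)
  labels <- data.frame(hour_start = hour_seq(48),
                       stress = rep(c("NS", "HS"), 24))
  beh <- generate_behavior(cfg, labels)
  m <- cfg$behavior_models
  rec <- beh$records
  cols <- c("eating", "rumination", "rest", "mid_activity",
            "high_activity", "heavy_breathing")
  ns_rows <- rec$hour_start %in% labels$hour_start[labels$stress == "NS"]
  h_ns <- hod(rec$hour_start[ns_rows])
  # at zero noise each behavior is its model value, scaled only when the
  # six-behavior total exceeds the 60-minute budget
  model_total <- evaluate_model(m$eating$NS, h_ns) +
    evaluate_model(m$rumination$NS, h_ns) +
    evaluate_model(m$rest$NS, h_ns) +
    evaluate_model(m$activity$NS, h_ns) +
    evaluate_model(m$heavy_breathing$NS, h_ns)
  scale <- pmin(1, 60 / model_total)
  expect_equal(rec$rest[ns_rows],
               scale * evaluate_model(m$rest$NS, h_ns), tolerance = 1e-12)
  # untouched rows are exact pass-throughs
  free <- ns_rows & rowSums(rec[, cols]) < 60 - 1e-9
  expect_gt(sum(free), 0)
  expect_equal(rec$rest[free],
               evaluate_model(m$rest$NS, hod(rec$hour_start[free])),
               tolerance = 1e-12)
  # activity splits into mid/high by the configured fraction
  act <- rec$mid_activity + rec$high_activity
  expect_equal(rec$mid_activity[act > 0] / act[act > 0],
               rep(0.73, sum(act > 0)), tolerance = 1e-9)
  # INTERMEDIATE hours sit midway between the NS and HS model values
  labels_mid <- data.frame(hour_start = hour_seq(24),
                           stress = rep("INTERMEDIATE", 24))
  beh_mid <- generate_behavior(cfg, labels_mid)
  rec_mid <- beh_mid$records
  free_mid <- rowSums(rec_mid[, cols]) < 60 - 1e-9
  h_mid <- hod(rec_mid$hour_start[free_mid])
  expect_equal(rec_mid$rest[free_mid],
               (evaluate_model(m$rest$NS, h_mid) +
                  evaluate_model(m$rest$HS, h_mid)) / 2, tolerance = 1e-12)
})

test_that("every generated animal-hour respects the 60-minute budget", {
  cfg <- farm_config(n_days = 3, n_animals = 10, seed = 7)
  st <- generate_study(cfg)
  beh <- st$behavior_records
  cols <- c("eating", "rumination", "rest", "mid_activity",
            "high_activity", "heavy_breathing")
  expect_true(all(as.matrix(beh[, cols]) >= 0))
  expect_true(all(rowSums(beh[, cols]) <= 60 + 1e-9))
  expect_equal(nrow(beh), 10 * 3 * 24)
})

test_that("generate_study is byte-deterministic under its seed", {
  cfg <- farm_config(n_days = 2, n_animals = 3, n_sensors = 2, seed = 10)
  d1 <- tempfile(); d2 <- tempfile()
  generate_study(cfg, out_dir = d1)
  generate_study(cfg, out_dir = d2)
  for (f in c("sensors.csv", "behavior.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # a different seed changes the data
  cfg2 <- farm_config(n_days = 2, n_animals = 3, n_sensors = 2, seed = 11)
  st_a <- generate_study(cfg)
  st_b <- generate_study(cfg2)
  expect_false(identical(st_a$sensor_samples$temperature_c,
                         st_b$sensor_samples$temperature_c))
})

test_that("animal noise streams are independent across animals", {
  cfg <- farm_config(n_days = 4, n_animals = 2, behavior_noise_sd = 5,
                     seed = 12)
  labels <- data.frame(hour_start = hour_seq(96), stress = rep("NS", 96))
  beh <- generate_behavior(cfg, labels)$records
  a1 <- beh$rumination[beh$animal_id == "A001"]
  a2 <- beh$rumination[beh$animal_id == "A002"]
  r <- cor(a1 - mean(a1), a2 - mean(a2))
  expect_lt(abs(r), 3 / sqrt(96))
})

test_that("generated strata reproduce the published behavior ordering", {
  st <- generate_study(farm_config(n_days = 8, n_animals = 15, seed = 13))
  lab <- join_with_stress(st$behavior_records, st$heat_load)
  cmp <- compare_groups(lab)
  up_ns <- cmp$behavior[cmp$ns_mean > cmp$hs_mean]
  expect_setequal(up_ns, c("eating", "rumination", "rest"))
  up_hs <- cmp$behavior[cmp$hs_mean > cmp$ns_mean]
  expect_setequal(up_hs, c("activity", "heavy_breathing"))
})
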