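test_that("evaluate_model reproduces direct evaluations and periodicity", {
  flat <- circadian_spec("single", mu = 10, a = 0, b = 0)
  expect_equal(evaluate_model(flat, c(0, 7.3, 23)), rep(10, 3))

  # reference no-stress rest model at midnight: 16.247 - 2.466*sin(-2.763)
  m <- default_behavior_models()
  expect_equal(evaluate_model(m$rest$NS, 0), 17.158, tolerance = 5e-4)

  s <- circadian_spec("single", mu = 5, a = 2, b = 0.7)
  h <- seq(0, 23.5, by = 0.5)
  expect_equal(evaluate_model(s, h), evaluate_model(s, h + 24),
               tolerance = 1e-9)
  # double form repeats after the common period of its two waves
  d <- circadian_spec("double", mu = 5, a = 2, b = 0.7, period1 = 12,
                      c = 1, d = -0.2, period2 = 8)
  expect_equal(evaluate_model(d, h), evaluate_model(d, h + 24),
               tolerance = 1e-9)
})

test_that("model_mean equals the baseline for full-period harmonics", {
  m <- default_behavior_models()
  for (bh in c("rest", "activity", "heavy_breathing")) {
    for (g in c("NS", "HS")) {
      spec <- m[[bh]][[g]]
      expect_equal(model_mean(spec), spec$mu, tolerance = 1e-9)
    }
  }
  # both harmonics of a 24/12-h double model integrate to zero over a day
  d <- circadian_spec("double", mu = 7, a = 3, b = 1, period1 = 24,
                      c = 2, d = 0.4, period2 = 12)
  expect_equal(model_mean(d), 7, tolerance = 1e-9)
  # free periods that do not divide 24 h shift the daily mean off mu
  expect_gt(abs(model_mean(m$eating$NS) - m$eating$NS$mu), 0.05)
  expect_error(model_mean(d, n_grid = 100), "1440")
})

test_that("adjusted_r2 follows the penalized formula", {
  expect_equal(adjusted_r2(0, 10, 50, 3), list(r2 = 1, r2_adj = 1))
  # p = 1 collapses the penalty
  r <- adjusted_r2(4, 10, 50, 1)
  expect_equal(r$r2_adj, r$r2)
  # direct evaluation: r2 = 0.75, adj = 1 - (99/97)*0.25
  r2 <- adjusted_r2(25, 100, 100, 3)
  expect_equal(r2$r2, 0.75)
  expect_equal(r2$r2_adj, 1 - (99 / 97) * 0.25)
  expect_equal(round(r2$r2_adj, 5), 0.74485)
  # more parameters never increase the adjusted value
  adjs <- sapply(1:6, function(p) adjusted_r2(25, 100, 100, p)$r2_adj)
  expect_true(all(diff(adjs) <= 0))
  expect_error(adjusted_r2(1, 0, 10, 2), "tss")
  expect_error(adjusted_r2(1, 10, 3, 3), "n must exceed p")
})

test_that("phase normalization preserves the model pointwise", {
  set.seed(9)
  h <- seq(0, 24, by = 0.25)
  for (i in 1:25) {
    form <- sample(c("single", "double"), 1)
    spec <- if (form == "single") {
      circadian_spec("single", mu = rnorm(1, 10), a = rnorm(1, 0, 5),
                     b = rnorm(1, 0, 20))
    } else {
      circadian_spec("double", mu = rnorm(1, 10), a = rnorm(1, 0, 5),
                     b = rnorm(1, 0, 20), period1 = runif(1, 4, 26),
                     c = rnorm(1, 0, 5), d = rnorm(1, 0, 20),
                     period2 = runif(1, 4, 26))
    }
    norm <- normalize_spec(spec)
    expect_gte(norm$a, 0)
    expect_true(norm$b > -pi && norm$b <= pi)
    if (form == "double") {
      expect_gte(norm$c, 0)
      expect_true(norm$d > -pi && norm$d <= pi)
    }
    expect_equal(evaluate_model(norm, h), evaluate_model(spec, h),
                 tolerance = 1e-9)
  }
})

test_that("grid_initialize finds a zero-residual grid member exactly", {
  # b = pi/4 puts the peak on an integer hour, so the data half-range
  # equals the amplitude and (a, b) sits exactly on the default grid
  truth <- circadian_spec("single", mu = 10, a = 2, b = pi / 4)
  h <- rep(0:23, 3)
  y <- evaluate_model(truth, h)
  got <- grid_initialize(h, y, "single")
  expect_equal(got$mu, 10, tolerance = 1e-12)
  expect_equal(got$a, 2, tolerance = 1e-12)
  expect_equal(got$b, pi / 4, tolerance = 1e-12)
  expect_lt(attr(got, "grid_rss"), 1e-18)
})

test_that("grid ties resolve to the smallest period then smallest phase", {
  # constant data: every candidate has amplitude 0 and identical RSS
  h <- 0:23
  y <- rep(5, 24)
  s1 <- grid_initialize(h, y, "single")
  expect_equal(s1$b, 0)
  s2 <- grid_initialize(h, y, "double")
  expect_equal(s2$period1, 4)
  expect_equal(s2$period2, 4)
  expect_equal(s2$b, 0)
  expect_equal(s2$d, 0)
  expect_error(grid_initialize(h, y, "single",
                               list(phases = numeric(), amp_fracs = numeric())),
               "empty grid")
})

test_that("grid_initialize equals exhaustive enumeration on small grids", {
  set.seed(21)
  h <- rep(0:23, 2)
  y <- 8 + 3 * sin(2 * pi / 24 * h + 1.1) + rnorm(48, sd = 2)

  # single form, 64 candidates
  got <- grid_initialize(h, y, "single")
  cfg <- default_grid_config("single")
  mu <- mean(y)
  hr <- (max(y) - min(y)) / 2
  best <- Inf
  best_par <- NULL
  for (b in sort(cfg$phases)) for (a in sort(cfg$amp_fracs) * hr) {
    rss <- naive_rss(h, y, mu, a, b)
    if (rss < best) { best <- rss; best_par <- c(a, b) }
  }
  expect_equal(c(got$a, got$b), best_par)
  expect_equal(attr(got, "grid_rss"), best, tolerance = 1e-9)

  # double form with a coarse grid (<= 1000 candidates)
  dcfg <- list(periods = c(6, 8, 12, 24), phases = c(0, pi / 2, pi),
               amp_frac = 0.5)
  got2 <- grid_initialize(h, y, "double", dcfg)
  amp <- 0.5 * hr
  best2 <- Inf
  best_par2 <- NULL
  n_cand <- 0
  for (p1 in dcfg$periods) for (p2 in dcfg$periods[dcfg$periods <= p1]) {
    for (b in dcfg$phases) for (d in dcfg$phases) {
      n_cand <- n_cand + 1
      rss <- naive_rss(h, y, mu, amp, b, p1, amp, d, p2)
      if (rss < best2) { best2 <- rss; best_par2 <- c(p1, p2, b, d) }
    }
  }
  expect_lte(n_cand, 1000)
  expect_equal(c(got2$period1, got2$period2, got2$b, got2$d), best_par2)
  expect_equal(attr(got2, "grid_rss"), best2, tolerance = 1e-9)
  expect_equal(attr(got2, "grid_candidates"), n_cand)
})

test_that("fit_model recovers a noiseless single harmonic exactly", {
  truth <- circadian_spec("single", mu = 10, a = 2, b = 1)
  h <- rep(0:23, 2)
  y <- evaluate_model(truth, h)
  fit <- fit_model(h, y, "single")
  expect_true(fit$converged)
  expect_lt(fit$rss, 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(fit$r2_adj, 1, tolerance = 1e-9)
  nf <- normalize_spec(fit$spec)
  expect_equal(nf$mu, 10, tolerance = 1e-6)
  expect_equal(nf$a, 2, tolerance = 1e-6)
  expect_equal(nf$b, 1, tolerance = 1e-6)
  expect_error(fit_model(0:2, rnorm(3), "single"), "more observations")
})

test_that("refinement never degrades the grid start", {
  set.seed(33)
  for (i in 1:10) {
    h <- rep(0:23, 4)
    spec <- circadian_spec("double", mu = 10, a = runif(1, 1, 4),
                           b = runif(1, -3, 3), period1 = runif(1, 8, 24),
                           c = runif(1, 1, 4), d = runif(1, -3, 3),
                           period2 = runif(1, 4, 14))
    y <- evaluate_model(spec, h) + rnorm(length(h), sd = 3)
    form <- sample(c("single", "double"), 1)
    fit <- suppressWarnings(fit_model(h, y, form))
    expect_lte(fit$rss, attr(fit$start, "grid_rss") + 1e-9)
  }
})

test_that("baseline recovery is unbiased across seeded replicates", {
  # median absolute error of the fitted baseline stays below 0.1 min/h for
  # every single-form behavior at study scale (40 animals x 14 days, sd 5)
  m <- default_behavior_models()
  for (bh in c("rest", "activity", "heavy_breathing")) {
    for (g in c("NS", "HS")) {
      err <- vapply(1:20, function(s) {
        d <- simulate_behavior_series(m[[bh]][[g]], 40, 14, 5, seed = s)
        abs(fit_model(d$hour, d$value, "single")$spec$mu - m[[bh]][[g]]$mu)
      }, numeric(1))
      expect_lt(median(err), 0.1)
    }
  }
})

test_that("simulate_behavior_series is seeded and reproducible", {
  m <- default_behavior_models()
  d1 <- simulate_behavior_series(m$rest$NS, 5, 2, 5, seed = 8)
  d2 <- simulate_behavior_series(m$rest$NS, 5, 2, 5, seed = 8)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 5 * 2 * 24)
  d3 <- simulate_behavior_series(m$rest$NS, 5, 2, 5, seed = 9)
  expect_false(identical(d1$value, d3$value))
  expect_error(simulate_behavior_series(m$rest$NS, 5, 2, 5), "seed")
})

test_that("pattern summaries locate peaks of the reference models", {
  m <- default_behavior_models()
  # a single harmonic has exactly one peak and one trough, at the analytic
  # phase position
  pat <- summarize_pattern(m$rest$NS)
  expect_length(pat$peak_hours, 1)
  expect_length(pat$trough_hours, 1)
  norm <- normalize_spec(m$rest$NS)
  analytic_peak <- ((pi / 2 - norm$b) * 24 / (2 * pi)) %% 24
  expect_equal(pat$peak_hours, analytic_peak, tolerance = 1 / 60)
  expect_equal(pat$daily_range, 2 * norm$a, tolerance = 1e-3)

  # heat-stress heavy breathing peaks in the afternoon window
  hb <- summarize_pattern(m$heavy_breathing$HS)
  expect_length(hb$peak_hours, 1)
  expect_gte(hb$peak_hours, 12)
  expect_lte(hb$peak_hours, 20)

  # rumination: two differentiated daily peaks in both strata (the
  # heat-stress equation carries a shallow fast ripple that prominence
  # filtering removes)
  expect_length(summarize_pattern(m$rumination$NS,
                                  min_prominence = 1)$peak_hours, 2)
  expect_length(summarize_pattern(m$rumination$HS,
                                  min_prominence = 1)$peak_hours, 2)
})

test_that("compare_patterns contrasts the reference stress pairs", {
  m <- default_behavior_models()
  same <- compare_patterns(m$rest$NS, m$rest$NS)
  expect_equal(same$mean_difference, 0)
  expect_equal(same$peak_shift_hours, 0)
  expect_true(all(same$hourly_difference_curve$difference == 0))

  rest <- compare_patterns(m$rest$NS, m$rest$HS)
  expect_equal(rest$mean_difference, 16.247 - 13.371, tolerance = 1e-9)

  hb <- compare_patterns(m$heavy_breathing$NS, m$heavy_breathing$HS)
  expect_equal(hb$range_difference, 2 * 0.608 - 2 * 4.492, tolerance = 1e-3)

  expect_error(compare_patterns(m$rest$NS, m$activity$HS), "mismatch")
})

test_that("curve standard errors are positive and shrink with more data", {
  m <- default_behavior_models()
  d_small <- simulate_behavior_series(m$rest$NS, 10, 3, 5, seed = 2)
  d_big <- simulate_behavior_series(m$rest$NS, 40, 14, 5, seed = 2)
  f_small <- fit_model(d_small$hour, d_small$value, "single")
  f_big <- fit_model(d_big$hour, d_big$value, "single")
  se_small <- curve_se(f_small, 0:23)
  se_big <- curve_se(f_big, 0:23)
  expect_true(all(se_small > 0))
  expect_true(all(se_big < se_small))
})
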