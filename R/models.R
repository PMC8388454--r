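#' Reference circadian behavior models for dairy cows under heat stress
#'
#' The published fitted daily-pattern equations for five collar-detected
#' behaviors of lactating dairy cows, under no-heat-stress (`NS`, lowest
#' heat-load quartile) and heat-stress (`HS`, highest quartile) hours.
#' Eating and rumination follow the double-harmonic form (free periods, the
#' timing being driven by feed delivery after milking); rest, aggregated
#' activity and heavy breathing follow the single-harmonic 24-h form.
#' Amplitudes and phases are stored exactly as printed (including negative
#' amplitudes and phases outside \eqn{(-\pi,\pi]}); use [normalize_spec()]
#' for canonical parameters.
#'
#' These equations are the default ground truth of the synthetic farm
#' generator ([farm_config()]) and the reference surface for the worked
#' examples: e.g. the 24-h time average of each single-harmonic model equals
#' its printed baseline (`Rest_NS` 16.247, `Rest_HS` 13.371, `Activity_NS`
#' 7.503, `Activity_HS` 7.796, heavy breathing 1.476 / 5.71 min per hour).
#'
#' @return a named list (`eating`, `rumination`, `rest`, `activity`,
#'   `heavy_breathing`), each element a list with `NS` and `HS`
#'   [circadian_spec()] entries.
#' @examples
#' m <- default_behavior_models()
#' model_mean(m$rest$NS)   # 16.247
#' @export
default_behavior_models <- function() {
  list(
    eating = list(
      NS = circadian_spec("double", mu = 8.77, a = 4.114, b = 2.052,
                          period1 = 9.82, c = 2.814, d = 3.84,
                          period2 = 5.922,
                          behavior = "eating", group = "NS"),
      HS = circadian_spec("double", mu = 8.142, a = 3.710, b = -1.325,
                          period1 = 6.19, c = 5.006, d = -0.964,
                          period2 = 10.56,
                          behavior = "eating", group = "HS")
    ),
    rumination = list(
      NS = circadian_spec("double", mu = 23.133, a = -4.330, b = -97.534,
                          period1 = 18.628, c = -5.150, d = -1.827,
                          period2 = 12.473,
                          behavior = "rumination", group = "NS"),
      HS = circadian_spec("double", mu = 22.137, a = -0.386, b = -12.284,
                          period1 = 1.808, c = -2.660, d = -1.334,
                          period2 = 11.220,
                          behavior = "rumination", group = "HS")
    ),
    rest = list(
      NS = circadian_spec("single", mu = 16.247, a = -2.466, b = -2.763,
                          behavior = "rest", group = "NS"),
      HS = circadian_spec("single", mu = 13.371, a = -4.872, b = -2.680,
                          behavior = "rest", group = "HS")
    ),
    activity = list(
      NS = circadian_spec("single", mu = 7.503, a = 2.496, b = -2.568,
                          behavior = "activity", group = "NS"),
      HS = circadian_spec("single", mu = 7.796, a = 2.735, b = -2.313,
                          behavior = "activity", group = "HS")
    ),
    heavy_breathing = list(
      NS = circadian_spec("single", mu = 1.476, a = 0.608, b = -2.565,
                          behavior = "heavy_breathing", group = "NS"),
      HS = circadian_spec("single", mu = 5.71, a = 4.492, b = -2.535,
                          behavior = "heavy_breathing", group = "HS")
    )
  )
}

# model form used for each behavior (assignment is configuration, not
# inference: multi-peak feeding-driven behaviors get the free-period form)
.behavior_forms <- c(eating = "double", rumination = "double",
                     rest = "single", activity = "single",
                     heavy_breathing = "single")
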