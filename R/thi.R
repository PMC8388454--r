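#' Temperature-humidity index (THI)
#'
#' Computes the THI from dry-bulb temperature and relative humidity using the
#' NRC formulation
#' \deqn{THI = (1.8 T + 32) - (0.55 - 0.555\,RH)(1.8 T - 26)}
#' where `T` is in degrees Celsius and `RH` enters the formula as a fraction.
#' The interface accepts relative humidity in percent (0-100) and divides by
#' 100 before substitution; with RH in percent the 0.555 coefficient would
#' produce physically meaningless values.
#'
#' At the pivot temperature `26/1.8` C (about 14.44 C) the humidity term
#' vanishes and THI = 58 for every RH. Above the pivot THI increases with RH,
#' below it decreases.
#'
#' @param temperature dry-bulb temperature in degrees Celsius (vectorised).
#' @param relative_humidity relative humidity in percent, in \[0, 100\]
#'   (vectorised, recycled against `temperature`).
#' @return numeric vector of THI values (dimensionless).
#' @examples
#' compute_thi(25, 50)       # 71.8225
#' compute_thi(26 / 1.8, 80) # 58, independent of RH
#' @export
compute_thi <- function(temperature, relative_humidity) {
  if (!is.numeric(temperature) || !is.numeric(relative_humidity)) {
    stop("temperature and relative_humidity must be numeric")
  }
  bad <- !is.na(relative_humidity) &
    (relative_humidity < 0 | relative_humidity > 100)
  if (any(bad)) {
    stop("relative_humidity must lie in [0, 100] percent; got ",
         relative_humidity[which(bad)[1L]])
  }
  rh <- relative_humidity / 100
  (1.8 * temperature + 32) - (0.55 - 0.555 * rh) * (1.8 * temperature - 26)
}

# plausibility window for raw temperature readings (degrees C); readings
# outside are treated as corrupt at parse time
.temp_window <- c(-30, 60)

#' Read a raw environmental sensor log
#'
#' Parses a CSV export of 5-minute temperature/relative-humidity readings
#' (EasyLog-style). Required header columns: `sensor_id`, `timestamp`
#' (ISO 8601), `temperature_c`, `rh_pct`. Rows with an unparseable timestamp,
#' a non-numeric reading, RH outside \[0, 100\] or temperature outside the
#' plausibility window \[-30, 60\] C are skipped and counted, not kept.
#'
#' @param path path to the CSV file.
#' @return list with elements
#'   \describe{
#'     \item{samples}{data.frame with columns `sensor_id`, `timestamp`
#'       (POSIXct, UTC), `temperature_c`, `rh_pct`, one row per valid reading,
#'       in file order.}
#'     \item{n_skipped}{number of invalid rows dropped.}
#'     \item{skipped_rows}{1-based data-row indices of the dropped rows.}
#'   }
#' @export
parse_sensor_log <- function(path) {
  raw <- .read_csv_strict(path, c("sensor_id", "timestamp",
                                  "temperature_c", "rh_pct"))
  ts <- .parse_timestamp(raw$timestamp)
  temp <- suppressWarnings(as.numeric(raw$temperature_c))
  rh <- suppressWarnings(as.numeric(raw$rh_pct))
  ok <- !is.na(ts) & !is.na(temp) & !is.na(rh) &
    rh >= 0 & rh <= 100 &
    temp >= .temp_window[1] & temp <= .temp_window[2]
  samples <- data.frame(
    sensor_id = as.character(raw$sensor_id)[ok],
    timestamp = ts[ok],
    temperature_c = temp[ok],
    rh_pct = rh[ok],
    stringsAsFactors = FALSE
  )
  list(samples = samples,
       n_skipped = sum(!ok),
       skipped_rows = which(!ok))
}

#' Aggregate sensor readings to hourly means and THI
#'
#' Pools all readings from all sensors falling in each half-open clock hour
#' `[t, t+1)`, takes the arithmetic mean of temperature and of relative
#' humidity, and computes the THI from those hourly means. Hours with no
#' readings are absent from the output.
#'
#' @param samples data.frame with columns `timestamp` (POSIXct),
#'   `temperature_c`, `rh_pct` (e.g. the `samples` element of
#'   [parse_sensor_log()]).
#' @return data.frame with columns `hour_start` (POSIXct), `mean_temperature`,
#'   `mean_relative_humidity`, `thi`, `n_samples`, ordered by hour.
#' @export
aggregate_hourly <- function(samples) {
  cols <- c("timestamp", "temperature_c", "rh_pct")
  if (!all(cols %in% names(samples))) {
    stop("samples must have columns: ", paste(cols, collapse = ", "))
  }
  if (nrow(samples) == 0) {
    return(data.frame(hour_start = as.POSIXct(character(), tz = "UTC"),
                      mean_temperature = numeric(),
                      mean_relative_humidity = numeric(),
                      thi = numeric(), n_samples = integer()))
  }
  hour <- .floor_hour(samples$timestamp)
  key <- as.numeric(hour)
  mt <- tapply(samples$temperature_c, key, mean)
  mrh <- tapply(samples$rh_pct, key, mean)
  n <- tapply(samples$temperature_c, key, length)
  hs <- as.POSIXct(as.numeric(names(mt)), origin = "1970-01-01", tz = "UTC")
  out <- data.frame(
    hour_start = hs,
    mean_temperature = as.numeric(mt),
    mean_relative_humidity = as.numeric(mrh),
    n_samples = as.integer(n)
  )
  out <- out[order(out$hour_start), , drop = FALSE]
  out$thi <- compute_thi(out$mean_temperature, out$mean_relative_humidity)
  rownames(out) <- NULL
  out[, c("hour_start", "mean_temperature", "mean_relative_humidity",
          "thi", "n_samples")]
}

#' Accumulated 24-hour heat load
#'
#' For each hour `t` in the input, sums the hourly THI over the `window_hours`
#' hours strictly preceding `t` (exclusive of `t` itself, so the load is causal
#' for the hour it labels; set `include_current = TRUE` for the inclusive
#' variant). The load is defined only when every hour of the window has a THI
#' value; otherwise it is `NA` (reported downstream as `UNDEFINED`).
#'
#' A constant-THI series therefore yields `thi_load = 24 * THI` from the 25th
#' hour on.
#'
#' @param hourly data.frame with columns `hour_start` (POSIXct, unique) and
#'   `thi`, e.g. the output of [aggregate_hourly()]. Gaps are allowed.
#' @param window_hours length of the accumulation window (default 24).
#' @param include_current if `TRUE` the window is `[t - window + 1, t]`
#'   instead of `[t - window, t - 1]`.
#' @return data.frame with columns `hour_start` and `thi_load` (NA where the
#'   window is incomplete), one row per input hour, ordered by hour.
#' @export
compute_heat_load <- function(hourly, window_hours = 24,
                              include_current = FALSE) {
  if (!all(c("hour_start", "thi") %in% names(hourly))) {
    stop("hourly must have columns hour_start and thi")
  }
  if (nrow(hourly) == 0) {
    return(data.frame(hour_start = as.POSIXct(character(), tz = "UTC"),
                      thi_load = numeric()))
  }
  h <- round(as.numeric(hourly$hour_start) / 3600)
  if (anyDuplicated(h)) stop("hourly contains duplicated hours")
  ord <- order(h)
  h <- h[ord]
  thi <- hourly$thi[ord]
  full <- seq(h[1], h[length(h)])
  thi_full <- rep(NA_real_, length(full))
  pos <- match(h, full)
  thi_full[pos] <- thi
  off <- if (include_current) 0L else 1L
  load_full <- vapply(seq_along(full), function(i) {
    lo <- i - off - window_hours + 1L
    hi <- i - off
    if (lo < 1L) return(NA_real_)
    w <- thi_full[lo:hi]
    if (anyNA(w)) NA_real_ else sum(w)
  }, numeric(1))
  data.frame(
    hour_start = as.POSIXct(full[pos] * 3600, origin = "1970-01-01",
                            tz = "UTC"),
    thi_load = load_full[pos]
  )
}

#' Classify hours into heat-stress strata by heat-load quartiles
#'
#' Splits the defined `thi_load` values at three boundaries into quartile
#' groups Q1-Q4 and maps them to stress labels: Q1 is no heat stress (`NS`),
#' Q4 is heat stress (`HS`), Q2/Q3 are `INTERMEDIATE`. Hours whose heat load
#' is undefined get quartile and stress `UNDEFINED`. When `boundaries` is not
#' supplied the three boundaries are the 25/50/75% sample quantiles of the
#' defined loads (linear interpolation between order statistics,
#' `stats::quantile` type 7). A load exactly equal to a boundary goes to the
#' lower group, matching the strict inequalities of the quartile definitions.
#'
#' @param records data.frame with a `thi_load` column (NA = undefined), e.g.
#'   the output of [compute_heat_load()].
#' @param boundaries optional numeric vector of three non-decreasing boundary
#'   values (for instance previously published study boundaries); when `NULL`
#'   they are estimated from the data.
#' @return `records` with added character columns `quartile` (`Q1`..`Q4` or
#'   `UNDEFINED`) and `stress` (`NS`, `INTERMEDIATE`, `HS`, `UNDEFINED`), and
#'   the boundaries used in `attr(, "boundaries")`.
#' @export
classify_stress <- function(records, boundaries = NULL) {
  if (!"thi_load" %in% names(records)) {
    stop("records must have a thi_load column")
  }
  x <- records$thi_load
  if (is.null(boundaries)) {
    defined <- x[!is.na(x)]
    if (length(defined) < 4) {
      stop("need at least 4 defined thi_load values to estimate quartile ",
           "boundaries (got ", length(defined), "); supply boundaries")
    }
    boundaries <- unname(stats::quantile(defined, c(0.25, 0.5, 0.75),
                                         type = 7, names = FALSE))
  } else {
    if (length(boundaries) != 3 || is.unsorted(boundaries)) {
      stop("boundaries must be three non-decreasing values")
    }
  }
  q <- cut(x, breaks = c(-Inf, boundaries, Inf),
           labels = c("Q1", "Q2", "Q3", "Q4"), right = TRUE)
  quartile <- as.character(q)
  quartile[is.na(x)] <- "UNDEFINED"
  map <- c(Q1 = "NS", Q2 = "INTERMEDIATE", Q3 = "INTERMEDIATE", Q4 = "HS",
           UNDEFINED = "UNDEFINED")
  records$quartile <- quartile
  records$stress <- unname(map[quartile])
  attr(records, "boundaries") <- boundaries
  records
}

## internal helpers ----------------------------------------------------------

.read_csv_strict <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("unparseable CSV '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("missing required column(s) in '", path, "' header (line 1): ",
         paste(missing, collapse = ", "))
  }
  raw
}

.parse_timestamp <- function(x) {
  as.POSIXct(as.character(x), tz = "UTC",
             tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
                            "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M"),
             optional = TRUE)
}

.floor_hour <- function(ts) {
  as.POSIXct(floor(as.numeric(ts) / 3600) * 3600,
             origin = "1970-01-01", tz = "UTC")
}
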