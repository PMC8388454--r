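#' @keywords internal
"_PACKAGE"

# the six collar-detected behavior states, in canonical column order
.behavior_cols <- c("eating", "rumination", "rest",
                    "mid_activity", "high_activity", "heavy_breathing")

#' Read a collar behavior log
#'
#' Parses a CSV of per-animal per-hour minutes devoted to the six
#' collar-detected behaviors (eating, rumination, rest, mid activity, high
#' activity, heavy breathing). Behaviors are mutually exclusive minutes within
#' the hour, so each value must lie in \[0, 60\] and the six-behavior total
#' must not exceed 60 minutes (the remainder of the hour is unclassified
#' time). Fractional minutes are allowed. Rows violating these constraints,
#' or with unparseable fields, are rejected and counted.
#'
#' @param path path to a CSV with header columns `animal_id`, `timestamp`
#'   (ISO 8601 hour start) and the six behavior columns.
#' @return list with elements `records` (data.frame with `animal_id`,
#'   `hour_start` and the six behavior columns), `n_skipped` and
#'   `skipped_rows` (1-based data-row indices of rejected rows).
#' @export
parse_behavior_log <- function(path) {
  raw <- .read_csv_strict(path, c("animal_id", "timestamp", .behavior_cols))
  ts <- .parse_timestamp(raw$timestamp)
  vals <- lapply(.behavior_cols,
                 function(cn) suppressWarnings(as.numeric(raw[[cn]])))
  names(vals) <- .behavior_cols
  m <- do.call(cbind, vals)
  tol <- 1e-9  # guard against decimal round-trip of fractional minutes
  in_range <- rowSums(is.na(m) | m < -tol | m > 60 + tol) == 0
  total_ok <- !is.na(rowSums(m)) & rowSums(m) <= 60 + tol
  ok <- !is.na(ts) & in_range & total_ok
  records <- data.frame(
    animal_id = as.character(raw$animal_id)[ok],
    hour_start = .floor_hour(ts[ok]),
    stringsAsFactors = FALSE
  )
  for (cn in .behavior_cols) records[[cn]] <- vals[[cn]][ok]
  list(records = records, n_skipped = sum(!ok), skipped_rows = which(!ok))
}

#' Add the aggregated activity column
#'
#' Activity is the sum of the mid- and high-activity minutes; eating is a
#' separate state and is not part of activity.
#'
#' @param records behavior data.frame with `mid_activity` and `high_activity`
#'   columns.
#' @return the same data.frame with an added `activity` column.
#' @export
aggregate_activity <- function(records) {
  if (!all(c("mid_activity", "high_activity") %in% names(records))) {
    stop("records must have mid_activity and high_activity columns")
  }
  records$activity <- records$mid_activity + records$high_activity
  records
}

#' Join behavior records with hourly heat-stress labels
#'
#' Attaches to each behavior record the stress label of its hour. Every input
#' record is kept: records at hours absent from the heat-load table (or at
#' hours whose heat load is undefined) are labelled `UNDEFINED`, with a
#' warning for genuinely missing hours.
#'
#' @param behavior behavior data.frame with an `hour_start` column (e.g. from
#'   [parse_behavior_log()]).
#' @param heat_load classified heat-load data.frame with `hour_start` and
#'   `stress` columns (from [classify_stress()]).
#' @return `behavior` with added `activity` and `stress` columns; row count
#'   equals the input row count.
#' @export
join_with_stress <- function(behavior, heat_load) {
  if (!"hour_start" %in% names(behavior)) {
    stop("behavior must have an hour_start column")
  }
  if (!all(c("hour_start", "stress") %in% names(heat_load))) {
    stop("heat_load must have hour_start and stress columns")
  }
  behavior <- aggregate_activity(behavior)
  idx <- match(as.numeric(behavior$hour_start),
               as.numeric(heat_load$hour_start))
  stress <- heat_load$stress[idx]
  n_missing <- sum(is.na(idx))
  if (n_missing > 0) {
    warning(n_missing, " behavior record(s) at hours absent from the ",
            "heat-load table; labelled UNDEFINED")
    stress[is.na(idx)] <- "UNDEFINED"
  }
  behavior$stress <- stress
  behavior
}

#' Write sensor or behavior tables to CSV
#'
#' Writers matched to [parse_sensor_log()] and [parse_behavior_log()]:
#' numeric fields are written with 17 significant digits so that a write/parse
#' round trip reproduces every value bit-exactly, and timestamps in ISO 8601.
#'
#' @param samples sensor samples data.frame (`sensor_id`, `timestamp`,
#'   `temperature_c`, `rh_pct`).
#' @param records behavior data.frame (`animal_id`, `hour_start`, six
#'   behavior columns).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_sensor_log <- function(samples, path) {
  out <- data.frame(
    sensor_id = samples$sensor_id,
    timestamp = format(samples$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    temperature_c = .num17(samples$temperature_c),
    rh_pct = .num17(samples$rh_pct),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sensor_log
#' @export
write_behavior_log <- function(records, path) {
  out <- data.frame(
    animal_id = records$animal_id,
    timestamp = format(records$hour_start, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    stringsAsFactors = FALSE
  )
  for (cn in .behavior_cols) out[[cn]] <- .num17(records[[cn]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.num17 <- function(x) formatC(x, digits = 17, format = "g")
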