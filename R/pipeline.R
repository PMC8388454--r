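#' Export fitted daily-pattern curves
#'
#' Numeric basis of the daily-pattern figure: for each behavior, the fitted
#' NS and HS model values with pointwise standard-error bands (see
#' [curve_se()]) on a regular grid over `[0, 24)`.
#'
#' @param fits named list, one element per behavior, each a list with `NS`
#'   and `HS` [fit_model()] results (at least one converged fit required).
#' @param resolution_minutes grid step in minutes (default 60: 24 rows per
#'   behavior).
#' @return data.frame with columns `behavior`, `hour`, `ns_value`, `ns_se`,
#'   `hs_value`, `hs_se`.
#' @export
export_model_curves <- function(fits, resolution_minutes = 60) {
  if (length(fits) == 0) stop("no fits supplied")
  if (!any(vapply(fits, function(f)
    isTRUE(f$NS$converged) || isTRUE(f$HS$converged), logical(1)))) {
    stop("need at least one converged fit")
  }
  step <- resolution_minutes / 60
  h <- seq(0, 24 - step / 2, by = step)
  rows <- lapply(names(fits), function(bh) {
    f <- fits[[bh]]
    data.frame(
      behavior = bh, hour = h,
      ns_value = evaluate_model(f$NS$spec, h),
      ns_se = curve_se(f$NS, h),
      hs_value = evaluate_model(f$HS$spec, h),
      hs_se = curve_se(f$HS, h),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# flatten a list of circadian fits to one row each (raw + normalized params)
.fits_table <- function(fits) {
  rows <- lapply(names(fits), function(bh) {
    do.call(rbind, lapply(c("NS", "HS"), function(g) {
      f <- fits[[bh]][[g]]
      s <- f$spec
      ns <- normalize_spec(s)
      data.frame(
        behavior = bh, group = g, form = s$form,
        mu = s$mu, a = s$a, b = s$b, period1 = s$period1,
        c = s$c, d = s$d, period2 = s$period2,
        a_norm = ns$a, b_norm = ns$b, c_norm = ns$c, d_norm = ns$d,
        rss = f$rss, tss = f$tss, r2 = f$r2, r2_adj = f$r2_adj,
        n = f$n, p = f$p, converged = f$converged,
        stringsAsFactors = FALSE
      )
    }))
  })
  do.call(rbind, rows)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full heat-stress behavior pipeline
#'
#' Orchestrates every stage on a pair of input CSVs (real or simulated):
#' sensor parsing and hourly THI aggregation, 24-h heat-load accumulation and
#' quartile stress classification, behavior parsing and labelling, the
#' NS-vs-HS time-budget comparison, and the circadian model fits (eating and
#' rumination with the free-period double form, rest/activity/heavy breathing
#' with the 24-h single form) with exported curve tables. All result tables
#' are written as CSV plus a machine-readable JSON report; outputs carry no
#' timestamps, so re-running on unchanged inputs is byte-identical.
#'
#' @param sensor_path sensor CSV (see [parse_sensor_log()]).
#' @param behavior_path behavior CSV (see [parse_behavior_log()]).
#' @param out_dir output directory, created if needed; when `NULL` nothing
#'   is written and only the report object is returned.
#' @param boundaries optional fixed heat-load quartile boundaries
#'   (`classify_stress()`); default: estimated from the data.
#' @param forms named character vector assigning `"single"`/`"double"` to
#'   each behavior (the assignment is configuration, not inference).
#' @param hourly_means fit on per-hour means instead of all animal-hours.
#' @param curve_resolution_minutes resolution of the exported curves.
#' @return (invisibly) a `pipeline_report` list: `heat_load_summary`
#'   (boundaries, hours per class), `comparison`, `fits` (the fit objects),
#'   `fits_table`, `curves`, `provenance`, and `files` when written.
#' @export
run_pipeline <- function(sensor_path, behavior_path, out_dir = NULL,
                         boundaries = NULL,
                         forms = .behavior_forms,
                         hourly_means = FALSE,
                         curve_resolution_minutes = 60) {
  sens <- .stage("env_thi", {
    parsed <- parse_sensor_log(sensor_path)
    if (parsed$n_skipped > 0) {
      message("env_thi: skipped ", parsed$n_skipped, " invalid sensor rows")
    }
    parsed
  })
  hourly <- .stage("env_thi", aggregate_hourly(sens$samples))
  heat_load <- .stage("env_thi",
                      classify_stress(compute_heat_load(hourly), boundaries))
  message("env_thi: ", nrow(sens$samples), " readings -> ", nrow(hourly),
          " hours (", sum(!is.na(heat_load$thi_load)),
          " with defined heat load)")

  beh <- .stage("behavior_io", {
    parsed <- parse_behavior_log(behavior_path)
    if (parsed$n_skipped > 0) {
      message("behavior_io: rejected ", parsed$n_skipped, " invalid rows")
    }
    join_with_stress(parsed$records, heat_load)
  })
  message("behavior_io: ", nrow(beh), " labelled animal-hour records")

  comparison <- .stage("stress_comparison", compare_groups(beh))

  fit_one <- function(bh, grp) {
    sub <- beh[beh$stress == grp, , drop = FALSE]
    hod <- as.numeric(floor(as.numeric(sub$hour_start) / 3600) %% 24)
    fit_model(hod, sub[[bh]], form = forms[[bh]], behavior = bh,
              group = grp, hourly_means = hourly_means)
  }
  fits <- .stage("circadian", {
    out <- lapply(names(forms), function(bh) {
      list(NS = fit_one(bh, "NS"), HS = fit_one(bh, "HS"))
    })
    names(out) <- names(forms)
    out
  })
  curves <- .stage("circadian",
                   export_model_curves(fits, curve_resolution_minutes))

  report <- structure(
    list(
      heat_load_summary = list(
        boundaries = attr(heat_load, "boundaries"),
        hours_per_class = as.list(table(heat_load$stress))
      ),
      comparison = comparison,
      fits = fits,
      fits_table = .fits_table(fits),
      curves = curves,
      provenance = list(
        package_version = as.character(utils::packageVersion("heatrhythm")),
        sensor_path = sensor_path,
        behavior_path = behavior_path,
        boundaries_supplied = !is.null(boundaries)
      )
    ),
    class = "pipeline_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(
      hourly = file.path(out_dir, "hourly_environment.csv"),
      heat_load = file.path(out_dir, "heat_load.csv"),
      labelled = file.path(out_dir, "labelled_behavior.csv"),
      comparison = file.path(out_dir, "comparison.csv"),
      fits = file.path(out_dir, "fits.csv"),
      curves = file.path(out_dir, "model_curves.csv"),
      report = file.path(out_dir, "report.json"),
      summary = file.path(out_dir, "summary.md")
    )
    .write_table <- function(df, path) {
      df2 <- df
      for (cn in names(df2)) {
        if (inherits(df2[[cn]], "POSIXct")) {
          df2[[cn]] <- format(df2[[cn]], "%Y-%m-%dT%H:%M:%S", tz = "UTC")
        }
      }
      utils::write.csv(df2, path, row.names = FALSE, quote = FALSE)
    }
    .write_table(hourly, files$hourly)
    .write_table(heat_load, files$heat_load)
    .write_table(beh, files$labelled)
    .write_table(comparison, files$comparison)
    .write_table(report$fits_table, files$fits)
    .write_table(curves, files$curves)
    jsonlite::write_json(
      list(heat_load_summary = report$heat_load_summary,
           comparison = comparison,
           fits = report$fits_table,
           provenance = report$provenance),
      files$report, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    writeLines(.summary_md(report), files$summary)
    report$files <- files
  }
  invisible(report)
}

.summary_md <- function(report) {
  hl <- report$heat_load_summary
  cmp <- report$comparison
  ft <- report$fits_table
  c(
    "# Heat-stress behavior pipeline summary",
    "",
    "## Heat load",
    sprintf("Quartile boundaries: %.2f / %.2f / %.2f",
            hl$boundaries[1], hl$boundaries[2], hl$boundaries[3]),
    paste0("Hours per class: ",
           paste(sprintf("%s=%s", names(hl$hours_per_class),
                         unlist(hl$hours_per_class)), collapse = ", ")),
    "",
    "## Time budget (NS vs HS, min/h)",
    "",
    "| behavior | NS mean (se) | HS mean (se) | F | p |",
    "|---|---|---|---|---|",
    sprintf("| %s | %.2f (%.3f) | %.2f (%.3f) | %.1f | %.3g |",
            cmp$behavior, cmp$ns_mean, cmp$ns_se, cmp$hs_mean, cmp$hs_se,
            cmp$f, cmp$p),
    "",
    "## Circadian fits",
    "",
    "| behavior | group | form | mu | amplitude | R2 | adj R2 |",
    "|---|---|---|---|---|---|---|",
    sprintf("| %s | %s | %s | %.3f | %.3f | %.3f | %.3f |",
            ft$behavior, ft$group, ft$form, ft$mu, ft$a_norm, ft$r2,
            ft$r2_adj)
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(.summary_md(x), sep = "\n")
  invisible(x)
}
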