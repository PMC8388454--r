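#' Group mean and standard error of a behavior
#'
#' Summarises the minutes per hour devoted to one behavior in the no-stress
#' and heat-stress strata: arithmetic mean, standard error (sample standard
#' deviation over the square root of the record count) and record count.
#' Records labelled `INTERMEDIATE` or `UNDEFINED` are excluded.
#'
#' @param labelled labelled behavior data.frame (see [join_with_stress()]).
#' @param behavior name of the behavior column to summarise (e.g. `"rest"`,
#'   `"activity"`).
#' @return data.frame with one row per group (`NS`, `HS`) and columns
#'   `behavior`, `group`, `mean`, `se`, `n`.
#' @export
group_summary <- function(labelled, behavior) {
  if (!behavior %in% names(labelled)) {
    stop("no column '", behavior, "' in labelled records")
  }
  out <- lapply(c("NS", "HS"), function(g) {
    x <- labelled[[behavior]][labelled$stress == g]
    x <- x[!is.na(x)]
    if (length(x) == 0) stop("group ", g, " has no records for ", behavior)
    data.frame(behavior = behavior, group = g, mean = mean(x),
               se = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0,
               n = length(x), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' One-way analysis of variance
#'
#' Fits the one-way layout \eqn{y_{ij} = \mu + \tau_i + \varepsilon_{ij}}
#' (group effect of the stress level on an animal-hour observation) and
#' returns the F test of the group effect. Computation is delegated to
#' `stats::lm`/`stats::anova`; sums of squares satisfy
#' `ss_between + ss_within = total SS`.
#'
#' @param values numeric observations (e.g. minutes per hour of one
#'   behavior).
#' @param groups group labels, same length; at least two groups with at
#'   least two observations each.
#' @return list of class `anova_result` with `f_stat`, `df_between`,
#'   `df_within`, `p_value`, `ss_between`, `ss_within`.
#' @examples
#' one_way_anova(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
#' @export
one_way_anova <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  g <- factor(groups[keep])
  if (nlevels(g) < 2) stop("need at least 2 groups")
  sizes <- table(g)
  if (any(sizes < 2)) {
    stop("every group needs at least 2 observations; group '",
         names(sizes)[which(sizes < 2)[1]], "' has ", min(sizes))
  }
  # anova.lm warns on essentially perfect fits; the degenerate
  # zero-within-variance case is handled explicitly below
  tab <- suppressWarnings(stats::anova(stats::lm(values ~ g)))
  ss_b <- tab[["Sum Sq"]][1]
  ss_w <- tab[["Sum Sq"]][2]
  f <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  if (ss_b > 0 && ss_w <= 1e-12 * (ss_b + ss_w)) {
    warning("zero within-group variance with nonzero between-group ",
            "variance; p reported as 0")
    f <- Inf
    p <- 0
  }
  structure(
    list(f_stat = f, df_between = tab$Df[1], df_within = tab$Df[2],
         p_value = p, ss_between = ss_b, ss_within = ss_w),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f_stat, x$p_value))
  cat(sprintf("  SS between = %.6g, SS within = %.6g\n",
              x$ss_between, x$ss_within))
  invisible(x)
}

#' Behavior time-budget comparison between stress strata
#'
#' Builds the NS-vs-HS comparison table: for each behavior, the group means
#' with standard errors and the one-way ANOVA of the stress effect on
#' animal-hour observations. Observations are treated as independent
#' animal-hours (no repeated-measures correction), matching the analysis
#' model of the comparison.
#'
#' @param labelled labelled behavior data.frame with an `activity` column
#'   (see [join_with_stress()]).
#' @param behaviors behavior columns to compare; defaults to the five
#'   reported behaviors with activity aggregated.
#' @return data.frame with one row per behavior: `behavior`, `ns_mean`,
#'   `ns_se`, `ns_n`, `hs_mean`, `hs_se`, `hs_n`, `f`, `df1`, `df2`, `p`.
#' @export
compare_groups <- function(labelled,
                           behaviors = c("eating", "rumination", "rest",
                                         "activity", "heavy_breathing")) {
  keep <- labelled$stress %in% c("NS", "HS")
  sub <- labelled[keep, , drop = FALSE]
  rows <- lapply(behaviors, function(bh) {
    gs <- group_summary(sub, bh)
    an <- one_way_anova(sub[[bh]], sub$stress)
    data.frame(
      behavior = bh,
      ns_mean = gs$mean[gs$group == "NS"], ns_se = gs$se[gs$group == "NS"],
      ns_n = gs$n[gs$group == "NS"],
      hs_mean = gs$mean[gs$group == "HS"], hs_se = gs$se[gs$group == "HS"],
      hs_n = gs$n[gs$group == "HS"],
      f = an$f_stat, df1 = an$df_between, df2 = an$df_within,
      p = an$p_value, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
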