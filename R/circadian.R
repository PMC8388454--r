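#' Circadian harmonic model specification
#'
#' Constructs the parameter set of a circadian behavior model. Two forms are
#' supported:
#' \describe{
#'   \item{single}{\eqn{y(h) = \mu + a \sin(2\pi h / 24 + b)} — one harmonic
#'     with the period fixed at 24 h (3 free parameters). Used for behaviors
#'     with a single daily peak (rest, activity, heavy breathing).}
#'   \item{double}{\eqn{y(h) = \mu + a \sin(2\pi h/T + b) +
#'     c \cos(2\pi h/T' - d)} — two waves with freely estimated periods
#'     \eqn{T, T'} (7 free parameters). Used for behaviors with multiple
#'     daily peaks (eating, rumination, whose timing follows feed delivery).}
#' }
#' `mu` is the baseline in minutes per hour, `a`/`c` are amplitudes (possibly
#' negative as published equations are sometimes written with leading minus
#' signs), `b`/`d` are phases in radians, periods are in hours. Use
#' [normalize_spec()] for a canonical representation with non-negative
#' amplitudes and phases in \eqn{(-\pi, \pi]}.
#'
#' @param form `"single"` or `"double"`.
#' @param mu baseline minutes/hour.
#' @param a amplitude of the sine wave.
#' @param b phase of the sine wave, radians.
#' @param period1 period of the sine wave in hours (must be 24 for `single`).
#' @param c amplitude of the cosine wave (`double` only).
#' @param d phase of the cosine wave, radians (`double` only; note the minus
#'   sign in the model: the cosine argument is `2*pi/period2*h - d`).
#' @param period2 period of the cosine wave in hours (`double` only).
#' @param behavior,group optional labels (behavior name; `NS`/`HS`) carried
#'   through fitting and reporting.
#' @return an object of class `circadian_spec`.
#' @export
circadian_spec <- function(form = c("single", "double"), mu, a, b,
                           period1 = 24, c = NA_real_, d = NA_real_,
                           period2 = NA_real_,
                           behavior = NA_character_, group = NA_character_) {
  form <- match.arg(form)
  if (form == "single") {
    period1 <- 24
    c <- d <- period2 <- NA_real_
  } else {
    if (!is.finite(period1) || !is.finite(period2) ||
        period1 <= 0 || period2 <= 0) {
      stop("double form requires positive period1 and period2")
    }
    if (!is.finite(c) || !is.finite(d)) {
      stop("double form requires amplitude c and phase d")
    }
  }
  if (!is.finite(period1) || period1 <= 0) stop("period1 must be positive")
  structure(
    list(form = form, mu = mu, a = a, b = b, period1 = period1,
         c = c, d = d, period2 = period2,
         behavior = behavior, group = group),
    class = "circadian_spec"
  )
}

#' @export
print.circadian_spec <- function(x, ...) {
  lab <- paste(stats::na.omit(c(x$behavior, x$group)), collapse = "_")
  if (nzchar(lab)) lab <- paste0(lab, ": ")
  if (x$form == "single") {
    cat(sprintf("%s%.4g %+.4g * sin(2pi/24 * Hour %+.4g)\n",
                lab, x$mu, x$a, x$b))
  } else {
    cat(sprintf(
      "%s%.4g %+.4g * sin(2pi/%.4g * Hour %+.4g) %+.4g * cos(2pi/%.4g * Hour - (%.4g))\n",
      lab, x$mu, x$a, x$period1, x$b, x$c, x$period2, x$d))
  }
  invisible(x)
}

#' Evaluate a circadian model at given hours
#'
#' @param spec a [circadian_spec()].
#' @param hour numeric vector of hours (any real number; periodicity is
#'   handled by the trigonometry). No clamping to \[0, 60\] is applied: the
#'   models are descriptive.
#' @return numeric vector of modelled minutes per hour.
#' @export
evaluate_model <- function(spec, hour) {
  stopifnot(inherits(spec, "circadian_spec"))
  y <- spec$mu + spec$a * sin(2 * pi / spec$period1 * hour + spec$b)
  if (spec$form == "double") {
    y <- y + spec$c * cos(2 * pi / spec$period2 * hour - spec$d)
  }
  y
}

#' Time-average of a circadian model over one day
#'
#' Averages [evaluate_model()] over a uniform grid of `n_grid` points spanning
#' `[0, 24)`. For the single form (period exactly 24 h) the harmonic averages
#' to zero over the full period, so the result equals `mu` to floating-point
#' precision; for the double form with periods that do not divide 24 h the
#' daily average generally differs from `mu`.
#'
#' @param spec a [circadian_spec()].
#' @param n_grid number of grid points (at least 1440, i.e. minute
#'   resolution).
#' @return the mean modelled minutes per hour over one 24-h span.
#' @export
model_mean <- function(spec, n_grid = 1440) {
  if (n_grid < 1440) stop("n_grid must be at least 1440")
  h <- (seq_len(n_grid) - 1) * 24 / n_grid
  mean(evaluate_model(spec, h))
}

#' Canonical phase/amplitude representation
#'
#' Maps a spec to the equivalent representation with non-negative amplitudes
#' and phases in \eqn{(-\pi, \pi]}, using \eqn{-a\sin(x+b) = a\sin(x+b+\pi)}
#' and \eqn{-c\cos(x-d) = c\cos(x-(d-\pi))}. [evaluate_model()] is pointwise
#' unchanged. Published equations print raw phases far outside
#' \eqn{(-\pi,\pi]}; comparisons between fitted and printed models should go
#' through model values or normalized parameters, never raw phases.
#'
#' @param spec a [circadian_spec()].
#' @return an equivalent `circadian_spec` with `a >= 0`, `c >= 0` (double)
#'   and phases wrapped into \eqn{(-\pi, \pi]}.
#' @export
normalize_spec <- function(spec) {
  stopifnot(inherits(spec, "circadian_spec"))
  a <- spec$a; b <- spec$b
  if (!is.na(a) && a < 0) {
    a <- -a
    b <- b + pi
  }
  b <- .wrap_pi(b)
  out <- spec
  out$a <- a; out$b <- b
  if (spec$form == "double") {
    cc <- spec$c; d <- spec$d
    if (!is.na(cc) && cc < 0) {
      cc <- -cc
      d <- d - pi
    }
    out$c <- cc; out$d <- .wrap_pi(d)
  }
  out
}

# wrap an angle into (-pi, pi]
.wrap_pi <- function(x) {
  w <- ((x + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  w
}

#' Adjusted coefficient of determination
#'
#' Computes \eqn{R^2 = 1 - RSS/TSS} and the parameter-penalized
#' \eqn{R^2_{adj} = 1 - \frac{n-1}{n-p}(1 - R^2)}.
#'
#' @param rss residual sum of squares.
#' @param tss total sum of squares (must be positive).
#' @param n number of observations (must exceed `p`).
#' @param p number of fitted parameters (at least 1).
#' @return list with elements `r2` and `r2_adj`.
#' @export
adjusted_r2 <- function(rss, tss, n, p) {
  if (!is.finite(tss) || tss <= 0) stop("tss must be positive")
  if (p < 1) stop("p must be at least 1")
  if (n <= p) stop("n must exceed p (got n = ", n, ", p = ", p, ")")
  r2 <- 1 - rss / tss
  list(r2 = r2, r2_adj = 1 - (n - 1) / (n - p) * (1 - r2))
}

## grid initialization -------------------------------------------------------

#' Default brute-force grid configuration
#'
#' Grid ranges for [grid_initialize()]. For the single form the baseline is
#' pinned at the sample mean and the grid spans 16 phases times 4 amplitude
#' fractions of the data half-range. For the double form both periods sweep
#' 4-26 h in 0.5-h steps (with `period2 <= period1` to remove the
#' wave-exchange symmetry), phases take the four quadrant values, and both
#' amplitudes are seeded at half the data half-range. The period range covers
#' all daily-pattern periods a feeding-driven behavior plausibly shows
#' (roughly 6-19 h in practice) with margin.
#'
#' @param form `"single"` or `"double"`.
#' @return a list of grid vectors understood by [grid_initialize()].
#' @export
default_grid_config <- function(form = c("single", "double")) {
  form <- match.arg(form)
  if (form == "single") {
    list(phases = seq(0, 2 * pi - pi / 8, by = pi / 8),
         amp_fracs = c(0.25, 0.5, 0.75, 1))
  } else {
    list(periods = seq(4, 26, by = 0.5),
         phases = c(0, pi / 2, pi, 3 * pi / 2),
         amp_frac = 0.5)
  }
}

#' Brute-force grid search for starting parameters
#'
#' Evaluates the residual sum of squares of every candidate on a fixed
#' parameter grid and returns the best one as the start for the nonlinear
#' refinement in [fit_model()]. The baseline is pinned at the sample mean and
#' amplitudes are seeded from the data half-range `(max - min)/2`. The search
#' is deterministic given the grid; exact RSS ties are broken in favour of
#' the smallest period, then the smallest phase (candidates are scanned in
#' lexicographic (period1, period2, b, d) order and only a strictly smaller
#' RSS displaces the incumbent).
#'
#' Because observations share repeated hour values, RSS is computed from
#' per-hour sufficient statistics (counts, sums, sums of squares), making the
#' sweep linear in the number of distinct hours rather than observations.
#'
#' @param hours numeric vector of observation hours (hour-of-day).
#' @param values numeric vector of observed minutes, same length.
#' @param form `"single"` or `"double"`.
#' @param grid_config list as from [default_grid_config()].
#' @return the best-scoring `circadian_spec`, with attributes
#'   `grid_candidates` (number evaluated) and `grid_rss`.
#' @export
grid_initialize <- function(hours, values, form = c("single", "double"),
                            grid_config = NULL) {
  form <- match.arg(form)
  stopifnot(length(hours) == length(values), all(is.finite(values)))
  if (is.null(grid_config)) grid_config <- default_grid_config(form)
  mu <- mean(values)
  half_range <- (max(values) - min(values)) / 2
  # per-hour sufficient statistics: RSS = q - 2*sum(f_h s_h) + sum(n_h f_h^2)
  key <- match(hours, sort(unique(hours)))
  uh <- sort(unique(hours))
  n_h <- tabulate(key, nbins = length(uh))
  s_h <- as.numeric(tapply(values, key, sum))
  q <- sum(values^2)

  if (form == "single") {
    phases <- sort(grid_config$phases)
    amps <- sort(grid_config$amp_fracs) * half_range
    cand <- expand.grid(a = amps, b = phases)   # b varies slowest after sort
    cand <- cand[order(cand$b, cand$a), , drop = FALSE]
    if (nrow(cand) == 0) stop("empty grid")
    best <- NULL
    best_rss <- Inf
    for (i in seq_len(nrow(cand))) {
      f <- mu + cand$a[i] * sin(2 * pi / 24 * uh + cand$b[i])
      rss <- q - 2 * sum(f * s_h) + sum(n_h * f^2)
      if (rss < best_rss) {
        best_rss <- rss
        best <- i
      }
    }
    spec <- circadian_spec("single", mu = mu, a = cand$a[best],
                           b = cand$b[best])
    n_cand <- nrow(cand)
  } else {
    periods <- sort(grid_config$periods)
    phases <- sort(grid_config$phases)
    amp <- grid_config$amp_frac * half_range
    cand <- expand.grid(d = phases, b = phases,
                        period2 = periods, period1 = periods)
    cand <- cand[cand$period2 <= cand$period1, , drop = FALSE]
    cand <- cand[order(cand$period1, cand$period2, cand$b, cand$d), ,
                 drop = FALSE]
    if (nrow(cand) == 0) stop("empty grid")
    # vectorised RSS over the candidate matrix
    S <- sin(outer(2 * pi / cand$period1, uh) + cand$b)
    C <- cos(outer(2 * pi / cand$period2, uh) - cand$d)
    f_mat <- mu + amp * S + amp * C
    rss_vec <- q - 2 * drop(f_mat %*% s_h) + drop((f_mat^2) %*% n_h)
    best <- which.min(rss_vec)   # first index wins ties after ordering
    best_rss <- rss_vec[best]
    spec <- circadian_spec("double", mu = mu, a = amp, b = cand$b[best],
                           period1 = cand$period1[best], c = amp,
                           d = cand$d[best], period2 = cand$period2[best])
    n_cand <- nrow(cand)
  }
  attr(spec, "grid_candidates") <- n_cand
  attr(spec, "grid_rss") <- best_rss
  spec
}

## nonlinear least-squares fit -----------------------------------------------

# free parameter vector <-> spec
.spec_to_par <- function(spec) {
  if (spec$form == "single") {
    c(mu = spec$mu, a = spec$a, b = spec$b)
  } else {
    c(mu = spec$mu, a = spec$a, b = spec$b, period1 = spec$period1,
      c = spec$c, d = spec$d, period2 = spec$period2)
  }
}

.par_to_spec <- function(par, form, behavior, group) {
  if (form == "single") {
    circadian_spec("single", mu = par[["mu"]], a = par[["a"]], b = par[["b"]],
                   behavior = behavior, group = group)
  } else {
    circadian_spec("double", mu = par[["mu"]], a = par[["a"]], b = par[["b"]],
                   period1 = par[["period1"]], c = par[["c"]], d = par[["d"]],
                   period2 = par[["period2"]],
                   behavior = behavior, group = group)
  }
}

# analytic Jacobian of model values wrt free parameters (n x p)
.model_jacobian <- function(par, form, hours) {
  if (form == "single") {
    arg <- 2 * pi / 24 * hours + par[["b"]]
    cbind(mu = rep(1, length(hours)),
          a = sin(arg),
          b = par[["a"]] * cos(arg))
  } else {
    v <- 2 * pi / par[["period1"]] * hours + par[["b"]]
    u <- 2 * pi / par[["period2"]] * hours - par[["d"]]
    cbind(mu = rep(1, length(hours)),
          a = sin(v),
          b = par[["a"]] * cos(v),
          period1 = -par[["a"]] * cos(v) * 2 * pi * hours /
            par[["period1"]]^2,
          c = cos(u),
          d = par[["c"]] * sin(u),
          period2 = par[["c"]] * sin(u) * 2 * pi * hours /
            par[["period2"]]^2)
  }
}

.eval_par <- function(par, form, hours) {
  y <- par[["mu"]] + par[["a"]] * sin(2 * pi / par[["period1"]] * hours +
                                        par[["b"]])
  if (form == "double") {
    y <- y + par[["c"]] * cos(2 * pi / par[["period2"]] * hours - par[["d"]])
  }
  y
}

#' Fit a circadian model by nonlinear least squares
#'
#' Refines the brute-force grid start ([grid_initialize()]) by damped
#' (Levenberg-Marquardt) least squares over all free parameters — `mu`, `a`,
#' `b` for the single form; additionally `c`, `d` and both periods for the
#' double form. Convergence is declared when the relative RSS change falls
#' below `1e-10` or the parameter step below `1e-8`, with at most 500
#' iterations; non-convergence returns the best iterate with
#' `converged = FALSE` and a warning. The refinement never reports a higher
#' RSS than its grid start.
#'
#' Goodness of fit is reported as \eqn{R^2 = 1 - RSS/TSS} and the
#' parameter-penalized adjusted version (see [adjusted_r2()]).
#'
#' @param hours observation hours (hour-of-day of each animal-hour record).
#' @param values observed minutes per hour, same length as `hours`.
#' @param form `"single"` or `"double"`.
#' @param grid_config optional grid override, see [default_grid_config()].
#' @param behavior,group optional labels carried into the result.
#' @param hourly_means if `TRUE`, observations are collapsed to per-hour
#'   means before fitting (unweighted animal-hour fitting is the default).
#' @return an object of class `circadian_fit`: a list with the fitted `spec`,
#'   the grid `start`, `rss`, `tss`, `r2`, `r2_adj`, `n`, `p`, `sigma2`,
#'   `converged`, `grid_candidates_evaluated` and the parameter covariance
#'   `cov` from the linearized (Gauss-Newton) approximation at the optimum.
#' @export
fit_model <- function(hours, values, form = c("single", "double"),
                      grid_config = NULL, behavior = NA_character_,
                      group = NA_character_, hourly_means = FALSE) {
  form <- match.arg(form)
  stopifnot(length(hours) == length(values))
  if (any(!is.finite(values))) stop("values must be finite")
  if (hourly_means) {
    uh <- sort(unique(hours))
    values <- as.numeric(tapply(values, match(hours, uh), mean))
    hours <- uh
  }
  p <- if (form == "single") 3L else 7L
  n <- length(values)
  if (n <= p) stop("need more observations (n = ", n,
                   ") than parameters (p = ", p, ")")
  start <- grid_initialize(hours, values, form, grid_config)
  par0 <- .spec_to_par(start)
  # period1 = 24 is fixed for the single form; carry it through evaluation
  if (form == "single") par_fixed <- c(period1 = 24)
  resid_fn <- function(pp) {
    full <- if (form == "single") c(pp, par_fixed) else pp
    values - .eval_par(full, form, hours)
  }
  jac_fn <- function(pp) {
    -.model_jacobian(pp, form, hours)
  }
  out <- minpack.lm::nls.lm(
    par = par0, fn = resid_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-8,
                                         maxiter = 500)
  )
  converged <- out$info %in% 1:4
  if (!converged) {
    warning("nonlinear refinement did not converge (info = ", out$info,
            "): ", out$message)
  }
  par_hat <- out$par
  rss <- sum(resid_fn(par_hat)^2)
  grid_rss <- attr(start, "grid_rss")
  if (rss > grid_rss) {    # defensive: refinement must be monotone
    par_hat <- par0
    rss <- grid_rss
    converged <- FALSE
  }
  tss <- sum((values - mean(values))^2)
  gof <- adjusted_r2(rss, tss, n, p)
  sigma2 <- rss / (n - p)
  J <- .model_jacobian(if (form == "single") c(par_hat, par_fixed) else
    par_hat, form, hours)[, names(par_hat), drop = FALSE]
  jtj <- crossprod(J)
  cov <- tryCatch(sigma2 * solve(jtj), error = function(e) {
    matrix(NA_real_, p, p, dimnames = list(names(par_hat), names(par_hat)))
  })
  spec <- .par_to_spec(if (form == "single") c(par_hat, period1 = 24) else
    par_hat, form, behavior, group)
  structure(
    list(spec = spec, start = start, rss = rss, tss = tss,
         r2 = gof$r2, r2_adj = gof$r2_adj, n = n, p = p,
         sigma2 = sigma2, cov = cov, converged = converged,
         grid_candidates_evaluated = attr(start, "grid_candidates")),
    class = "circadian_fit"
  )
}

#' @export
print.circadian_fit <- function(x, ...) {
  lab <- paste(stats::na.omit(c(x$spec$behavior, x$spec$group)),
               collapse = "_")
  cat("Circadian fit", if (nzchar(lab)) paste0(" [", lab, "]"), "\n", sep = "")
  print(x$spec)
  cat(sprintf("  n = %d, p = %d, RSS = %.4g, R2 = %.4f, adj R2 = %.4f%s\n",
              x$n, x$p, x$rss, x$r2, x$r2_adj,
              if (x$converged) "" else "  (NOT converged)"))
  invisible(x)
}

#' Pointwise standard error of the fitted curve
#'
#' Delta-method standard error of the fitted model value at each hour, from
#' the linearized parameter covariance at the optimum. This is the basis of
#' the error bands drawn around modelled daily patterns.
#'
#' @param fit a [fit_model()] result.
#' @param hours hours at which to evaluate the band.
#' @return numeric vector of standard errors, same length as `hours`.
#' @export
curve_se <- function(fit, hours) {
  stopifnot(inherits(fit, "circadian_fit"))
  par_hat <- .spec_to_par(fit$spec)
  full <- if (fit$spec$form == "single") c(par_hat, period1 = 24) else par_hat
  G <- .model_jacobian(full, fit$spec$form, hours)[, rownames(fit$cov),
                                                   drop = FALSE]
  sqrt(pmax(rowSums((G %*% fit$cov) * G), 0))
}

## pattern description --------------------------------------------------------

#' Locate daily peaks and troughs of a fitted pattern
#'
#' Scans the model on a minute grid over `[0, 24)` for local maxima and
#' minima. For the single form the curve is 24-h periodic and the scan wraps
#' around midnight; for the double form (periods need not divide 24 h) only
#' interior extrema of the `[0, 24)` window are reported. Extrema closer
#' together than `merge_minutes` are merged, keeping the most extreme.
#' `min_prominence` (in minutes) optionally suppresses shallow ripples: a
#' peak is kept only if it rises at least that much above the higher of its
#' two flanking minima (and symmetrically for troughs) — useful to count
#' "differentiated" peaks of published equations that carry a small
#' fast-oscillating term.
#'
#' @param fit a `circadian_fit` or a `circadian_spec`.
#' @param resolution_minutes grid resolution (default 1 minute).
#' @param merge_minutes merge window for near-coincident extrema.
#' @param min_prominence minimum prominence in minutes (default 0: all local
#'   extrema).
#' @return list with `peak_hours`, `peak_values`, `trough_hours`,
#'   `trough_values`, `daily_range`.
#' @export
summarize_pattern <- function(fit, resolution_minutes = 1,
                              merge_minutes = 10, min_prominence = 0) {
  spec <- if (inherits(fit, "circadian_fit")) fit$spec else fit
  stopifnot(inherits(spec, "circadian_spec"))
  step <- resolution_minutes / 60
  h <- seq(0, 24 - step / 2, by = step)
  y <- evaluate_model(spec, h)
  circular <- spec$form == "single"
  peaks <- .local_extrema(y, circular, maxima = TRUE)
  troughs <- .local_extrema(y, circular, maxima = FALSE)
  peaks <- .merge_extrema(h, y, peaks, merge_minutes / 60, decreasing = TRUE)
  troughs <- .merge_extrema(h, y, troughs, merge_minutes / 60,
                            decreasing = FALSE)
  if (min_prominence > 0) {
    peaks <- peaks[.prominence(y, peaks, circular) >= min_prominence]
    troughs <- troughs[.prominence(-y, troughs, circular) >= min_prominence]
  }
  list(peak_hours = h[peaks], peak_values = y[peaks],
       trough_hours = h[troughs], trough_values = y[troughs],
       daily_range = max(y) - min(y))
}

.local_extrema <- function(y, circular, maxima) {
  n <- length(y)
  if (!maxima) y <- -y
  if (circular) {
    left <- c(y[n], y[-n])
    right <- c(y[-1], y[1])
    which(y > left & y >= right)
  } else {
    idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
    idx
  }
}

.merge_extrema <- function(h, y, idx, window_h, decreasing) {
  if (length(idx) < 2) return(idx)
  idx <- sort(idx)
  groups <- cumsum(c(1, diff(h[idx]) > window_h))
  keep <- vapply(split(idx, groups), function(g) {
    g[order(y[g], decreasing = decreasing)[1]]
  }, integer(1))
  sort(unname(keep))
}

# topographic prominence of each peak index: height above the higher of the
# two key saddles, where each saddle is the curve minimum between the peak
# and the nearest higher terrain on that side (curve boundary for
# non-circular curves; the global minimum for the highest peak)
.prominence <- function(y, idx, circular) {
  n <- length(y)
  vapply(idx, function(i) {
    side_base <- function(step) {
      lo <- y[i]
      j <- i
      for (k in seq_len(n - 1)) {
        j <- j + step
        if (circular) j <- ((j - 1) %% n) + 1 else if (j < 1 || j > n) break
        if (y[j] > y[i]) return(lo)
        lo <- min(lo, y[j])
      }
      lo
    }
    y[i] - max(side_base(-1L), side_base(1L))
  }, numeric(1))
}

#' Contrast the fitted daily patterns of two stress groups
#'
#' @param fit_ns,fit_hs `circadian_fit` objects (or bare [circadian_spec()]
#'   objects) for the same behavior under no stress and heat stress.
#'   Behavior labels, when present, must match.
#' @param min_prominence passed to [summarize_pattern()] when locating the
#'   principal peaks.
#' @return list with `mean_difference` (NS daily mean minus HS daily mean),
#'   `peak_shift_hours` (HS principal-peak hour minus NS principal-peak hour,
#'   wrapped to \[-12, 12\] when both fits are 24-h periodic),
#'   `range_difference` (NS daily range minus HS daily range) and
#'   `hourly_difference_curve` (data.frame of NS - HS at hours 0..23).
#' @export
compare_patterns <- function(fit_ns, fit_hs, min_prominence = 0) {
  as_spec <- function(x) {
    if (inherits(x, "circadian_fit")) x$spec
    else if (inherits(x, "circadian_spec")) x
    else stop("expected a circadian_fit or circadian_spec")
  }
  spec_ns <- as_spec(fit_ns)
  spec_hs <- as_spec(fit_hs)
  bn <- spec_ns$behavior
  bh <- spec_hs$behavior
  if (!is.na(bn) && !is.na(bh) && bn != bh) {
    stop("behavior mismatch: '", bn, "' vs '", bh, "'")
  }
  pn <- summarize_pattern(spec_ns, min_prominence = min_prominence)
  ph <- summarize_pattern(spec_hs, min_prominence = min_prominence)
  principal <- function(s) s$peak_hours[which.max(s$peak_values)]
  shift <- principal(ph) - principal(pn)
  if (spec_ns$form == "single" && spec_hs$form == "single") {
    shift <- ((shift + 12) %% 24) - 12
  }
  hrs <- 0:23
  list(
    mean_difference = model_mean(spec_ns) - model_mean(spec_hs),
    peak_shift_hours = shift,
    range_difference = pn$daily_range - ph$daily_range,
    hourly_difference_curve = data.frame(
      hour = hrs,
      difference = evaluate_model(spec_ns, hrs) -
        evaluate_model(spec_hs, hrs))
  )
}

#' Simulate animal-hour observations from a circadian model
#'
#' Draws `n_animals * n_days` independent Gaussian observations around the
#' model value at every clock hour 0..23 — the sampling model underlying the
#' nonlinear fits (hourly collar summaries across animals and days). Used for
#' parameter-recovery studies.
#'
#' @param spec a [circadian_spec()] (the ground truth).
#' @param n_animals,n_days study dimensions.
#' @param noise_sd Gaussian noise standard deviation in minutes.
#' @param seed integer seed (required: recovery runs must be reproducible).
#' @return data.frame with columns `hour` and `value`, `n_animals * n_days *
#'   24` rows.
#' @export
simulate_behavior_series <- function(spec, n_animals = 40, n_days = 14,
                                     noise_sd = 5, seed) {
  stopifnot(inherits(spec, "circadian_spec"))
  if (missing(seed)) stop("an explicit seed is required")
  set.seed(seed)
  hour <- rep(0:23, times = n_animals * n_days)
  value <- evaluate_model(spec, hour) + stats::rnorm(length(hour),
                                                     sd = noise_sd)
  data.frame(hour = hour, value = value)
}
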