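---
title: "Methods: heat-load classification and circadian behavior modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heat-load classification and circadian behavior modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatrhythm)
```

This vignette is the package's own account of the statistical machinery it
implements: the models, their assumptions, the tunable parameters and the
numerical choices behind them, and what the synthetic data generator can and
cannot tell you about real barns.

## 1. From sensor readings to heat-stress strata

### THI and its units

The temperature–humidity index is computed as

$$\mathrm{THI} = (1.8\,T + 32) - (0.55 - 0.555\,\mathrm{RH})(1.8\,T - 26),$$

with $T$ the dry-bulb temperature in °C. A point that deserves emphasis:
in this formulation RH must enter as a **fraction** even though field
instruments (and our interface) report percent. The coefficient
$0.555 \cdot \mathrm{RH}_{frac}$ is the familiar
$0.0055 \cdot \mathrm{RH}_{pct}$ of the NRC form; substituting percent
directly produces physically absurd values. `compute_thi()` therefore takes
percent in $[0, 100]$ and divides by 100. Two structural facts about the
formula are used as test invariants: at the pivot $T = 26/1.8$ °C
($\approx 14.44$) the humidity term vanishes and THI $= 58$ for every RH;
above the pivot THI increases with RH, below it decreases.

### Accumulated heat load

An hour's stress reflects the heat endured over the preceding day, not the
instantaneous index, so each hour $t$ carries
$\mathrm{THI}_{load}(t) = \sum_{s=t-24}^{t-1} \mathrm{THI}(s)$ — the 24
hours **strictly before** $t$. We chose the exclusive window because a load
index used to explain hour $t$ should be causal; `include_current = TRUE`
switches to the inclusive convention. A load is defined only when all 24
window hours have a THI value; hours with incomplete windows are labelled
`UNDEFINED` and excluded from every downstream statistic rather than
imputed. In any study this silently removes the first day — by design.

### Quartile classification

Defined loads are split at three boundaries into Q1–Q4, with Q1 = no heat
stress (NS) and Q4 = heat stress (HS). Boundaries default to the 25/50/75%
sample quantiles with linear interpolation between order statistics
(`stats::quantile` type 7, the common default); published boundary values
can be supplied verbatim instead. Values exactly equal to a boundary fall
to the lower group, matching the strict inequalities in the usual quartile
definitions. Degenerate inputs are worth knowing about: with heavy ties
(e.g. a noise-free periodic simulation, where whole blocks of hours share
one load value) a quartile class can be empty. That is a property of sample
quantiles under ties, not a defect; any realistic noise level breaks it.

## 2. The behavior data model

Collar summaries give, per animal-hour, minutes devoted to six mutually
exclusive states: eating, rumination, rest, mid activity, high activity and
heavy breathing. Each value lies in $[0, 60]$ and the six-state total may
not exceed 60 minutes; the remainder is unclassified time (milking,
drinking, transitions). Fractional minutes are allowed — collars aggregate
per-second classifications. "Activity" in all analyses means mid + high
activity; eating is deliberately not part of it. Rows violating the budget
are rejected at parse time and counted, never silently repaired.

## 3. The stress comparison

Per behavior we report NS/HS group means with standard errors and the
one-way ANOVA $y_{ij} = \mu + \tau_i + \varepsilon_{ij}$, computed through
`stats::lm`/`stats::anova`. With exactly two groups the F test is
equivalent to Fisher's LSD, so no separate post-hoc machinery exists. Two
caveats are inherited deliberately from the analysis design rather than
fixed: animal-hours are treated as independent (no repeated-measures
structure over animals or autocorrelation over hours), and the p-value is
reported at full precision even when the independence assumption makes it
optimistic. When the within-group variance is numerically zero against a
nonzero between-group effect, the F statistic is infinite; we report
$p = 0$ with a warning rather than `NaN`.

## 4. Circadian models

### Forms and parameters

Behaviors with a single daily peak (rest, activity, heavy breathing) use

$$y(h) = \mu + a \sin\!\left(\tfrac{2\pi}{24} h + b\right),$$

three free parameters with the period pinned at 24 h. Behaviors whose
timing follows feed delivery (eating, rumination) show multiple daily peaks
and use

$$y(h) = \mu + a \sin\!\left(\tfrac{2\pi}{T} h + b\right)
       + c \cos\!\left(\tfrac{2\pi}{T'} h - d\right),$$

seven free parameters including both periods. The assignment of form to
behavior is configuration, not model selection. $\mu$ is minutes/hour, $a,
c$ are amplitudes in minutes, $b, d$ phases in radians, $T, T'$ periods in
hours. Model values are not clamped to $[0, 60]$: the curves are
descriptive and realistic parameter sets stay in range.

Parameterizations are degenerate in two ways — $(a, b)$ and $(-a, b+\pi)$
describe the same curve, as do phases modulo $2\pi$ — so fitted and
published equations are compared through model values or through
`normalize_spec()` (amplitudes $\ge 0$, phases in $(-\pi, \pi]$), never
through raw coefficients.

### Brute-force initialization

Free-period harmonic regression has a multimodal objective, so the fit is
started from the best point of a deterministic parameter grid
(`grid_initialize()`), with $\mu$ pinned at the sample mean and amplitudes
seeded from the data half-range $(\max - \min)/2$:

* single form: 16 phases ($0, \pi/8, \dots, 15\pi/8$) × 4 amplitude
  fractions ($\tfrac14 \dots 1$ of the half-range) — 64 candidates;
* double form: both periods over 4–26 h in 0.5-h steps with $T' \le T$ to
  remove the wave-exchange symmetry, phases over the four quadrant values,
  both amplitudes at half the half-range — 16 560 candidates.

The period range covers, with margin, every daily-pattern period a
feeding-driven behavior plausibly exhibits. Exact RSS ties are broken
toward the smallest period, then the smallest phase, by scanning candidates
in lexicographic order and displacing the incumbent only on strict
improvement — this makes the initializer fully deterministic. Because
observations repeat over at most 24 distinct clock hours, the RSS of a
candidate is computed from per-hour sufficient statistics (counts, sums,
sums of squares), making the sweep independent of the number of
animal-hours.

### Refinement and goodness of fit

From the grid start, `fit_model()` runs Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) with analytic Jacobians over all free parameters.
Convergence: relative RSS change $< 10^{-10}$ or parameter step
$< 10^{-8}$, at most 500 iterations; non-convergence returns the best
iterate flagged `converged = FALSE` with a warning. Damped least squares
only accepts improving steps, so the refinement never reports a higher RSS
than its start (asserted defensively and tested as an invariant).

Fit quality is $R^2 = 1 - \mathrm{RSS}/\mathrm{TSS}$ and
$R^2_{adj} = 1 - \frac{n-1}{n-p}(1 - R^2)$. Both are reported. Note that
$R^2$ depends strongly on what the observations are: fitted to raw
animal-hours (the default, $n$ in the tens of thousands) a correct model
explains only the between-hour variance share, e.g. $\approx 0.1$–$0.4$ on
the default synthetic study; fitted to the 24 hourly means
(`hourly_means = TRUE`) the same model scores far higher because
animal-level noise has been averaged out. Published coefficient-of-
determination values for such models are only comparable across studies if
the observation unit matches.

Pointwise standard-error bands for the fitted curves come from the
delta method on the linearized parameter covariance
$\hat\sigma^2 (J^\top J)^{-1}$ at the optimum — an interpretation choice,
flagged as such, since error bands around daily-pattern curves are rarely
defined precisely in the applied literature.

### Identifiability at hourly sampling

Hourly records impose a Nyquist limit: waves with periods below 2 h cannot
be identified, and their fitted period will land on an alias or absorb
noise. One published heat-stress rumination equation contains exactly such
a term (period 1.808 h, amplitude 0.386 min). The package fits what the
data support; the parameter-recovery tests therefore assert recovery of
every identifiable period and explicitly exempt that sub-Nyquist wave. The
same shallow ripple means that a raw local-extrema count of that printed
curve yields ten "peaks". `summarize_pattern()` consequently exposes a
topographic-prominence filter (`min_prominence`, in minutes): a peak
counts only if it rises at least that much above the saddle separating it
from higher terrain. With a 1-minute prominence both rumination curves
show their two differentiated daily peaks; the default (0) reports all raw
extrema. Single-form curves are scanned circularly across midnight;
free-period curves are scanned on the open $[0, 24)$ window only, since
they need not wrap continuously.

## 5. The synthetic farm

`generate_study()` produces a complete, deterministic study from one seed:
sensor readings, then hourly THI / heat load / stress labels derived by the
same analysis functions users run, then behavior records conditioned on
those labels.

**Environment.** The diurnal temperature cycle is a sinusoid peaking at
15:00 local time — aligning the THI maximum with the observed afternoon
panting peak — anchored so the daily maximum and minimum equal the
configured climate extremes (defaults 33.2 / 13.8 °C, summer normals of
the study region; the anchor point is the extremes rather than the 23 °C
mean because the two constraints are mutually inconsistent for an
asymmetric climate and the extremes are what the heat-load tails respond
to). The profile is hourly-resolved: all 5-minute samples within an hour
share the hour's base value, so the generator's ground-truth hourly table
is exact rather than an approximation. Per-reading Gaussian noise (sd
0.3 °C, 2 %RH) plays the role of sensor error; RH swings in anti-phase
with a 15-point half-range (a typical summer barn swing — the
configuration exposes it, as no published value exists) and is clamped to
$[5, 100]$.

**Heatwave.** A flat diurnal summer makes the 24-h load nearly constant,
leaving the quartile labels noise-driven. The default schedule therefore
applies a +6 °C offset to the second half of the study days, giving
cleanly separated NS and HS strata; the schedule is a list of day-ranges
with offsets and fully configurable.

**Behavior.** Each animal-hour draws every behavior from its regime's
circadian model (defaults: the published equations in
`default_behavior_models()`) plus independent Gaussian noise (sd 5 min),
truncated at zero; if the six-state total exceeds 60 the row is rescaled
proportionally onto the budget (truncate first, then rescale — the only
order that preserves both non-negativity and the budget). `INTERMEDIATE`
and `UNDEFINED` hours use the NS/HS midpoint, as no published model covers
them. Aggregated activity is split 73 % mid / 27 % high; the real collar
split is unpublished, so this is an exposed configuration stand-in.

**What the generator does not emulate — and what that means for tests.**
No milking-parlor absences, no fan/misting interventions, no pen spatial
structure, no between-animal heterogeneity in circadian parameters, no
autocorrelation of noise within an animal's day. Passing tests on this
generator therefore demonstrate that the estimators recover the structure
they assume, not that real barn data satisfy those assumptions. Two
quantitative consequences are worth knowing. First, truncation at zero
biases low-baseline behaviors upward (heavy breathing under NS has
baseline 1.476 min but a truncated-Gaussian mean near 2.6 at sd 5), and
the budget rescale compresses all means by a few percent — so realized
group means sit below the model baselines, and parameter-recovery tests
simulate from the plain Gaussian model (`simulate_behavior_series()`)
rather than through the budget machinery. Second, with noise sd 5 on
animal-hours the attainable animal-hour $R^2$ is bounded well below the
0.6–0.9 range hourly-mean fits produce, as discussed above.

## 6. Problem sizes and determinism

Every stochastic routine takes an explicit seed; there is no hidden RNG
state between stages (environment and behavior use seed and seed + 1, so
each stage is independently reproducible). The test suite and worked
examples run the full published design — 40 animals × 14 days, 15 sensors
at 5-minute cadence (60 480 readings, 13 440 animal-hours) — since the
whole pipeline completes in seconds; property-style tests use 20 seeded
replicates at the same scale. The default double-form grid evaluates
16 560 candidates per fit.

## 7. Known limitations

* The THI formula is the classic NRC one; newer formulations may suit
  modern genetics better, but alternatives are out of scope.
* Independence of animal-hours is assumed throughout the ANOVA and the
  fits; standard errors are optimistic for clustered data.
* Free-period double-harmonic models are not constrained to be 24-h
  periodic; curves are reported on $[0, 24)$ without enforcing wrap
  continuity.
* The quartile classifier needs at least 4 defined loads to estimate
  boundaries, and under massive ties classes can be empty.
* Phases are reported raw and normalized, but any comparison across
  software should go through model values.
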