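# heatrhythm

Heat stress is a major welfare and production problem for dairy cattle in
warm climates. Modern barns carry the instrumentation to quantify it:
temperature/relative-humidity sensors logging every few minutes, and
accelerometer collars that summarise each cow's hour into minutes of eating,
rumination, rest, mid/high activity and heavy breathing (panting).
**heatrhythm** turns those two data streams into a complete heat-stress
behavior analysis for researchers and precision-livestock practitioners:

1. **Hourly THI.** Sensor readings are pooled into hourly means and the
   temperature–humidity index is computed from the NRC formulation

   THI = (1.8·T + 32) − (0.55 − 0.555·RH)·(1.8·T − 26),

   with T in °C and RH entering as a fraction (the interface takes percent).

2. **Accumulated heat load.** Because an animal's stress reflects the heat
   endured over the preceding day, each hour gets THI_load = the sum of the
   24 hourly THI values strictly before it. Hours are classified by the
   quartiles of THI_load: Q1 = no heat stress (NS), Q4 = heat stress (HS),
   Q2/Q3 intermediate.

3. **Time-budget comparison.** Per behavior, NS vs HS group means ± s.e. and
   a one-way ANOVA (Y_ij = μ + τ_i + ε_ij) of the stress effect on
   animal-hour observations.

4. **Circadian modelling.** Each behavior's daily pattern is fitted by
   nonlinear least squares, initialized by a brute-force parameter grid:
   - single-harmonic, fixed 24-h period (rest, activity, heavy breathing):
     y(h) = μ + a·sin(2π·h/24 + b)
   - double-harmonic with free periods (eating, rumination, which track
     feed delivery): y(h) = μ + a·sin(2π·h/T + b) + c·cos(2π·h/T′ − d)

   Goodness of fit is reported as R² = 1 − RSS/TSS and the adjusted
   R²_adj = 1 − ((n−1)/(n−p))(1−R²). Fitted curves come with delta-method
   standard-error bands, peak/trough summaries and NS-vs-HS contrasts.

Because raw collar data are proprietary, the package ships a synthetic farm
generator (`farm_config()`, `generate_study()`) that emulates the study
design end to end — 15 sensors at 5-minute cadence over a summer diurnal
cycle, 40 collared cows whose behavior follows published circadian
equations plus noise, with per-hour budgets capped at 60 minutes — so every
pipeline stage is testable without external data.

## Worked example

Simulate a 14-day, 40-cow study (the second week carries a +6 °C heatwave)
and run the full pipeline:

```r
library(heatrhythm)

cfg <- farm_config(n_days = 14, n_animals = 40, seed = 1)
st  <- generate_study(cfg, out_dir = "demo")
rep <- run_pipeline("demo/sensors.csv", "demo/behavior.csv",
                    out_dir = "demo/out")
print(rep)
```

```
## Heat load
Quartile boundaries: 1659.11 / 1755.19 / 1847.69
Hours per class: HS=78, INTERMEDIATE=156, NS=78, UNDEFINED=24

## Time budget (NS vs HS, min/h)

| behavior | NS mean (se) | HS mean (se) | F | p |
|---|---|---|---|---|
| eating | 8.30 (0.089) | 7.92 (0.094) | 8.4 | 0.00367 |
| rumination | 22.11 (0.097) | 21.03 (0.086) | 68.3 | 1.67e-16 |
| rest | 15.02 (0.084) | 12.34 (0.100) | 421.0 | 1.36e-90 |
| activity | 7.25 (0.080) | 7.60 (0.082) | 9.8 | 0.00177 |
| heavy_breathing | 2.77 (0.056) | 5.78 (0.084) | 879.5 | 6.21e-181 |
```

Reading the output: the first 24 hours are `UNDEFINED` (no complete
heat-load window yet); the remaining 312 hours split into quartiles. Heat
stress cuts rest by ~2.7 min/h and roughly doubles heavy breathing, while
activity rises — the expected panting/standing response to heat. The fitted
circadian table (`rep$fits_table`) and hourly curve export (`rep$curves`)
give the daily patterns behind those averages, e.g. the heat-stress
heavy-breathing curve peaking in the 12:00–20:00 afternoon window.

Single behaviors can be fitted directly:

```r
m <- default_behavior_models()          # published reference equations
model_mean(m$rest$NS)                   # 16.247 min/h daily average
d <- simulate_behavior_series(m$rest$NS, n_animals = 40, n_days = 14,
                              noise_sd = 5, seed = 1)
fit_model(d$hour, d$value, "single")
#> Circadian fit
#> 16.2 +2.402 * sin(2pi/24 * Hour +0.3811)
#>   n = 13440, p = 3, RSS = 3.394e+05, R2 = 0.1025, adj R2 = 0.1024
```

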