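# urbansami

Scale-adjusted analysis of city-level indicator panels: allometric fits,
residual ("scale-adjusted") metrics, group trends, one-lag memory, and
cross-indicator forecasting — with a ground-truth synthetic generator for
validation.

## The problem

Urban indicators scale with population as power laws,

```
Y_i = 10^A_i * N^beta_i ,
```

with exponents `beta_i` that are rarely 1 (homicides and unemployment are
superlinear, illiteracy and elderly population sublinear in the Brazilian
municipal censuses). Per-capita values `Y/N ~ N^(beta-1)` therefore stay
biased by city size, which distorts rankings and time trends alike. The
remedy implemented here is the scale-adjusted metric: the log residual from
the fitted law,

```
D_Yi(t) = log10 Y_i(t) - [A_i + beta_i * log10 N(t)] ,
```

a size-independent measure of how a city performs *for its size* (`D > 0`:
above the law; `D < 0`: below). On top of it the package provides:

* **Allometry fits** by orthogonal-distance (Deming/major-axis) regression
  in log-log space, closed form, with bootstrap or analytic standard errors
  and an explicit error-variance-ratio knob (`Inf` = ordinary least
  squares).
* **Group trends**: cities labelled above/below the law at a baseline
  census, group means per year with 95% percentile-bootstrap intervals.
* **Memory**: per indicator, `D(t+dt) = A + alpha D(t)` by OLS; its
  continuous-time solution, the characteristic time `1/(1-alpha)`, and
  residual diagnostics (simple-null Cramér–von Mises vs the standard
  normal, windowed SD profile).
* **Forecasting**: `D_i(t+dt) = C_0 + sum_k C_k D_k(t)` over all eight
  indicators, per census interval, coefficients averaged across intervals
  and applied one step ahead; predicted-vs-empirical comparisons and a
  GeoJSON/ggplot bubble map of predicted changes.
* **Synthetic city systems** with known `A`, `beta`, dynamics matrix and
  noise scales, for parameter-recovery and calibration studies.

Intended users: quantitative urban-science / public-health researchers
working with census-style panels (the design target is the Brazilian
municipal panel: ~1600 cities, eight indicators, censuses 1991/2000/2010),
and anyone needing a tested major-axis regression with honest error-model
semantics.

## Worked example

```r
library(urbansami)

cfg <- suppressWarnings(synthetic_config(seed = 2020))  # 1600 cities, 3 censuses
sys <- generate_panel(cfg)

fit <- fit_allometry(sys$panel, "homicides", 1991,
                     variance_ratio = Inf, n_boot = 1000, seed = 1)
fit
#> Allometric fit: homicides (1991)
#>   A = -5.1622 (SE 0.1132)   beta = 1.2967 (SE 0.0260)
#>   rho = 0.772   n = 1600 (dropped nonpositive: 0)

sami <- compute_sami(sys$panel,
                     fit_allometry_panel(sys$panel, variance_ratio = Inf,
                                         se_method = "analytic"))
mem <- fit_memory(sami, "homicides", c(2000, 2010))
mem
#> Memory fit: homicides, 2010-2000
#>   alpha = 0.5258 (SE 0.0204)   A = -1.39e-16   rho = 0.541   n = 1600
characteristic_time(mem$slope)
#> [1] 2.11
```

Reading the output: the generator planted `beta = 1.35` with the residual
spread implied by a log-log correlation of 0.769, and the fit recovers
`beta = 1.297 ± 0.026` with `rho = 0.772` — a superlinear law, so homicide
*counts* grow faster than population and per-capita homicide rates are
biased against large cities. The memory slope `alpha = 0.53 < 1` says
city-level deviations from the law decay: the characteristic time of about
2 census steps (~20 years) measures how fast cities regress towards the
law. (The generator planted `alpha = 0.505` for homicides; the
`variance_ratio = Inf` choice matches the generator's vertical-residual
error model — see the methods vignette for when the major-axis default is
the right one.)

## Analysis workflow

The `analysis/` scripts run the whole study on the reference synthetic
system, writing tables, figures and GeoJSON under `results/`:

```sh
Rscript analysis/01_simulate.R      # reference panel + ground truth + coords
Rscript analysis/02_allometry.R     # per-year exponents, per-capita contrast
Rscript analysis/03_sami_groups.R   # metrics, baseline groups, group means
Rscript analysis/04_memory.R        # memory slopes, characteristic times, diagnostics
Rscript analysis/05_forecast.R      # cross models, averaging, 2020 forecast
Rscript analysis/06_change_map.R    # predicted-change map + GeoJSON
```

`run_full_pipeline()` performs the same chain as one call with a manifest
of content-hashed artifacts.

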