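---
title: "Scale-adjusted metrics for urban indicators: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scale-adjusted metrics for urban indicators: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbansami)
```

## The problem

Aggregate urban indicators — homicides, illiteracy counts, unemployment,
population segments, household income — scale with city population $N$ as
power laws,

$$Y_i = 10^{\mathcal{A}_i}\, N^{\beta_i},$$

usually with $\beta_i \neq 1$. Per-capita values $Y_i/N \sim N^{\beta_i-1}$
therefore retain a population dependence: superlinear indicators
($\beta > 1$, e.g. homicides) make large cities look bad regardless of how
they perform *for their size*, and sublinear ones ($\beta < 1$) do the
opposite. The scale-adjusted metric removes this bias by measuring each city
against the law fitted to its own census year:

$$D_{Y_i}(t) = \log_{10} Y_i(t) - \big[\mathcal{A}_i + \beta_i \log_{10}
N(t)\big].$$

$D > 0$ means the city sits above the expectation for its size, $D < 0$
below. The package computes these metrics, follows the group means of
cities above/below the law at a baseline census, models the one-lag memory
of $D$, forecasts the next census with a cross-indicator linear model, and
maps the predicted changes. A synthetic generator with fully known ground
truth drives every test.

One wording caveat is flagged rather than silently corrected: part of the
source literature describes superlinear/sublinear as $\beta_i > 0$ /
$\beta_i < 0$; the operative threshold — used by `per_capita_bias()` and
everywhere here — is $\beta_i = 1$, the extensive (per-capita-safe) case.

## Fitting the allometry: which member of the Deming family

Both coordinates of a city in the $(\log_{10} N, \log_{10} Y)$ plane are
measured quantities, so the default estimator is orthogonal-distance
regression with equal weight on both axes — major-axis regression, the
$\delta = 1$ member of the Deming family, with the closed-form slope

$$b = \frac{S_{yy} - \delta S_{xx} + \sqrt{(S_{yy} - \delta S_{xx})^2 +
4\delta S_{xy}^2}}{2 S_{xy}},$$

intercept through the centroid, and $\delta$ the vertical-to-horizontal
error-variance ratio (`variance_ratio` in `fit_allometry()`). $\delta \to
\infty$ recovers ordinary least squares exactly.

The choice of $\delta$ matters, and the package is deliberately explicit
about it. The synthetic generator writes its residual $D$ *vertically*
($\log_{10} Y = \mathcal{A} + \beta \log_{10} N + D$, population exact).
Under that error geometry the major axis is not a consistent estimator of
$\beta$: its population value is the first principal axis of the data
cloud, which exceeds $\beta$ by approximately
$(\sigma_D/s_x)^2\,\beta/(\beta^2+1)$ — at $n = 1600$ this bias is many
standard errors for realistic scatter. The consistent member of the family
for vertical noise is the $\delta = \infty$ (least-squares) limit, and that
is what every synthetic recovery study in the tests and the acceptance
script uses. For real census extracts, where the city's deviation from the
law is not attributable to one axis, the $\delta = 1$ default stands, and
its geometry is verified against a brute-force perpendicular-distance
minimizer (grid over the line angle plus golden-section refinement) to
$10^{-6}$ on random instances. This estimator/model matching is a design
decision, not a tuning: it follows from the algebra above.

Other allometry choices:

* All logarithms are base 10 (the intercept is $\log_{10}$ of the indicator
  at $N = 1$).
* Cities with nonpositive indicator values (a town with zero homicides)
  cannot enter a log-log fit; they are dropped *per indicator-year* and
  counted, with an optional `+offset` flag as the reversible alternative.
  No pseudo-count is added silently.
* Standard errors default to a seeded nonparametric bootstrap over cities
  (1000 resamples); a large-$n$ analytic approximation
  $\mathrm{SE}(b) = |b|\sqrt{(1/\rho^2 - 1)/(n-2)}$ — exact in the OLS
  limit — is available where speed matters. Both are recorded on the fit.
* With $S_{xy} = 0$ the orientation is degenerate; the slope sign is taken
  from $\mathrm{sign}(S_{yy} - \delta S_{xx})$ with a warning.

## The scale-adjusted metric and group trends

$D$ is always computed from the *same year's* fit, because the published
per-year parameter tables show the laws drifting between censuses; a pooled
fit would fold that drift into every city's metric. A subtlety the tests
assert rather than assume: residuals measured perpendicular to a major-axis
line average to zero, but the vertical residuals $D$ need not — their mean
is bounded by $|b - b_{\mathrm{OLS}}| \cdot \mathrm{SD}(\log_{10} N)$ and
vanishes only when the two slopes coincide.

Group labels ("above"/"below" the law) are frozen at a baseline census
(default: the earliest year, 1991 in the Brazilian panel) and follow the
same cities through time, so the group-mean trajectories answer "what
happened to the cities that started above the law?". An exact $D = 0$ at
baseline goes to "below", since "above" is defined strictly as $D > 0$.
Refreshing membership per census is available but not the default. Group
means carry 95% percentile-bootstrap confidence intervals (10,000 city
resamples by default, seeded); the percentile variant was chosen because
the group sizes (hundreds of cities) make it both simple and calibrated —
the acceptance suite measures 93–97% empirical coverage at $n = 200$.

## Memory and its continuous-time reading

Per indicator and census interval the one-lag model
$D(t+\Delta t) = A + \alpha D(t)$ is fitted by OLS. Intercepts are reported
but expected near zero (the published fits find $\sim 10^{-6}$); they are
never constrained. In the small-step limit the map becomes
$\dot D = A + (\alpha - 1) D$ with solution

$$D(t) = \frac{A}{1-\alpha} + \Big(k - \frac{A}{1-\alpha}\Big)
e^{-(1-\alpha)t} \quad (\alpha \neq 1), \qquad D(t) = At + k \quad
(\alpha = 1),$$

so $1/(1-\alpha)$ is the characteristic time of relaxation towards the law
for $\alpha < 1$, and $\alpha > 1$ (illiteracy in the Brazilian panel) is
the exponentially departing branch. The $\alpha = 1$ branch is taken when
$|1 - \alpha| < 10^{-12}$ — a removable discontinuity, verified against
4th-order Runge–Kutta integration to $10^{-6}$ across random parameter
triples. `characteristic_time()` returns `Inf` at $\alpha = 1$ and `NaN`
beyond, never an error, so tabulated summaries stay rectangular.

Residual diagnostics mirror the published supplement: residuals are
standardized and tested against the *fixed* standard normal with the
Cramér–von Mises statistic (simple null; p-values from the asymptotic
distribution via the goftest package). The composite-null variant
(parameters estimated, Stephens-corrected, via nortest) is behind a flag —
the fixed-parameter version is the default because the comparison of
interest is against the standard Gaussian after standardization. The
conditional-spread profile uses five equal-width, right-closed windows over
the observed range of $D(t)$, reporting the SD of $D(t+\Delta t)$ per
window at the window-mean abscissa; windows with fewer than two points
report a missing SD instead of failing.

## Cross-indicator forecasting

$$D_{Y_i}(t+\Delta t) = C_0 + \sum_{k=1}^{8} C_k D_{Y_k}(t) + \eta_i(t)$$

is fitted by OLS per indicator and interval, with optional HC1
heteroskedasticity-consistent standard errors (the point estimates are
unchanged — the small heteroskedasticity visible in the window profiles
justifies offering them, not switching estimators). Indicator order is
fixed alphabetically in every matrix and serialization. For forecasting
beyond the observed censuses the interval fits are averaged unweighted —
the constant-coefficient assumption; two intervals cannot identify a trend
in $C_k$ — and applied one step ahead. No shrinkage or regularization is
applied by default, for fidelity to the linear-model formulation; a ridge
flag exists for ill-conditioned synthetic configurations. Back-transforming
forecasts to raw indicator units would require a future population and a
fit choice, so it is off by default: the object of the forecast is $D$
itself.

## What the synthetic generator emulates — and what it does not

The generator is first-class, tested code; its defaults define the study
conditions used by every calibration:

* **Populations**: $\log_{10} N \sim \mathcal{N}(4.3, 0.7)$, multiplied by
  1.15 per census step. This reproduces the $10^3$–$10^7$ inhabitant range
  of the Brazilian municipal panel and its decadal growth; populations are
  rounded to whole inhabitants.
* **Allometry**: per-indicator $(\mathcal{A}_i, \beta_i)$ at the published
  1991 scale (e.g. homicides $-5.4$, $1.35$; family income $0.82$, $0.33$).
* **Initial residual spread**: the sources publish correlations, not noise
  scales, so $\sigma_{D0}$ is inverted from the log-log Pearson $\rho$:
  $\sigma_{D0} = \beta\, s_x \sqrt{1/\rho^2 - 1}$, with $\rho$ capped at
  0.9995 because the population indicators print $\rho = 1.000$. This
  yields spreads from $\approx 0.02$ (female population) to $\approx 0.79$
  (homicides) in $\log_{10}$ units.
* **Dynamics**: $D$ evolves by the lagged linear map plus Gaussian noise,
  $\sigma_\eta = |\alpha|\,\sigma_{D0}\sqrt{1/\rho_m^2 - 1}$ inverted from
  the published memory correlations. The default coefficient matrix is
  diagonal, $C_{ii}$ the mean of the indicator's two published interval
  slopes; the full cross-coefficient table is not reproduced in the
  available text, so off-diagonal truth values are user-supplied when
  wanted. The spectral radius of the default matrix is 1.03 — illiteracy's
  slope exceeds one — so the configuration constructor's non-contracting
  warning fires on the defaults, faithfully.
* **Initialisation**: independent across indicators by default, with an
  equicorrelated option; indicator values are left continuous so the stored
  ground-truth $D$ reproduces *exactly* (to $10^{-12}$) from the written
  panel.

Features of real data the generator does not emulate, and which passing
tests therefore do not certify: spatial autocorrelation (the map stage's
clustering is an empirical finding, not a model assumption — the synthetic
map is a negative control), genuinely zero indicator counts (small-town
homicides), reporting artifacts and administrative boundary changes, and
errors in the recorded populations.

## Numerical choices and degenerate inputs

Problem sizes were chosen so the full suite and the acceptance script each
run in minutes on one CPU: recovery studies use the full 1600-city,
three-census system (30–100 replicates), bootstrap calibration 500
replicates of $n = 200$ with 10,000 resamples, CvM size 1000 samples of
$n = 500$. Determinism is end-to-end: one seed fixes the generator, every
bootstrap, and the pipeline manifest; numeric CSV artifacts carry the seed
and a config hash in comment headers, and re-running a pipeline reproduces
the manifest byte-for-byte (figures are excluded from hashing since PDF
bytes embed timestamps).

Degenerate inputs are contracts, not accidents: vertical point clouds and
zero-variance regressors raise named errors; $S_{xy}=0$ warns and applies
the documented tie-break; empty groups and missing indicator-year fits are
named errors; cities lacking coordinates or a full predictor set are
skipped and counted, never silently dropped.

## Known limitations

* The exactness checks of the noise-free forecast path use ground-truth
  allometric parameters: with finite $n$ any *fitted* law differs from
  truth by sampling error, so "forecasts are exact" is a statement about
  the algebra chain, not about estimation.
* Tier-two reproduction of the published Brazilian numbers requires the
  external census extract (or the published per-city metric table); the
  readers ingest such files, but no download is performed and no external
  values are asserted offline.
* The memory model is strictly first-order and the forecast strictly
  one-step; chaining steps compounds the constant-coefficient assumption
  and is intentionally not offered.
* Coverage statements are calibrated under the generator's Gaussian noise;
  heavy-tailed indicator noise would widen true intervals relative to the
  bootstrap's.
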