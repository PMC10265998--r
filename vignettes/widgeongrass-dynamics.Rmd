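---
title: "Modeling boom-bust seagrass dynamics with density-weighted cover and piecewise SEM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling boom-bust seagrass dynamics with density-weighted cover and piecewise SEM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(savsem)
library(dplyr)
```

## The problem

Widgeongrass (*Ruppia maritima*) is an opportunistic, heat-tolerant
seagrass whose meadows in temperate estuaries expand and collapse on
annual time scales, unlike the comparatively stable eelgrass (*Zostera
marina*) it is replacing. Annual aerial surveys record, for each
monoculture bed, the vegetated area in hectares and an ordinal density
class interpreted from imagery. `savsem` turns such records into
quantitative cover dynamics and asks which watershed and water-column
drivers control the year-over-year change, using piecewise structural
equation models built from linear mixed models.

## From density classes to annual change

Each density class stands for an interval of percent bottom cover; its
midpoint converts mapped area into *density-weighted cover*:

```{r}
density_class_midpoints()
density_weighted_cover(100, "dense")
```

Per site we then:

1. **Scale to the site maximum.** Dividing by the site's best year maps
   cover onto $[0,1]$, where 1 is the site's realized habitable extent
   and 0 is bare bottom. This prevents large beds from dominating the
   regression and makes sites comparable.
2. **Difference consecutive years.** The response is the year-over-year
   difference of scaled cover, bounded in $[-1, 1]$. We interpret the
   survey's "proportional change" as this difference rather than a
   ratio: ratios are undefined at the zeros that pervade boom-bust
   series. Pairs spanning an unflown year (1988 in the bay-wide
   record) are not formed.
3. **Filter chronic zeros.** A year is dropped from regressions when it
   is the third or later year of an unbroken run of zero-cover years.
   The first two years of a bust are genuine observations of collapse
   and recovery potential; chronically bare sites carry no dynamic
   information. Zero runs are tracked within unbroken stretches of
   surveyed years and reset across a survey gap, since the state of an
   unsurveyed year is unknown. Scaling uses all years; the filter only
   controls regression inclusion.

```{r}
obs <- tibble::tibble(site_id = "S1", year = 1990:1995,
                      area_ha = c(10, 10, 20, 0, 0, 0),
                      density = c("sparse", "dense", "dense", NA, NA, NA))
build_cover_series(obs)
```

Main-channel sites are defined around fixed water-quality stations:
the bottom is divided into 30 m × 30 m cells (0.09 ha) and each cell
joins the zone of the nearest station by planar Euclidean distance
(cell membership by center point; ties broken toward the smallest
station id, so the partition is deterministic and order-independent).
Zone cover is the sum of midpoint-weighted vegetated cells.

## The mixed-model engine

Every structural equation is a Gaussian linear mixed model estimated by
maximum likelihood with

- a site random intercept (sites are subestuaries or station zones),
- AR(1) correlation among within-site residuals, with survey gaps
  entering through the lag exponent $\phi^{|\Delta t|}$,
- $\sigma^2$ parameterized as the *stationary marginal* variance of the
  AR(1) process, so the variance partition below is well defined.

We use AR(1) rather than a higher-order ARMA structure: it is the
minimal correlation model that removes the residual lag correlation in
this design (`residual_lag_correlation()` lets you check), and the
engine's contract leaves room for higher orders later. Maximum
likelihood (never REML) keeps log-likelihoods and d-separation
p-values comparable across equations with different fixed effects.

Numerically, the fixed effects are profiled out by generalized least
squares and the optimizer works on $(\log\sigma_b^2, \log\sigma^2,
\operatorname{atanh}\phi)$, so the search is unconstrained. Because the
AR(1) process is Markov, its precision matrix is tridiagonal even with
gaps, and the random intercept adds a rank-one term handled by a
Sherman-Morrison update: each likelihood evaluation is $O(n)$.
Nelder-Mead is multi-started from three fixed initial points
(convergence tolerance $10^{-8}$ on the objective; non-convergence is
an error, never a silent result). With $\phi = 0$ and $\sigma_b^2 = 0$
the estimator reduces exactly to ordinary least squares, which the test
suite checks against the closed form.

Coefficient p-values use t statistics with a containment-style
denominator df, $n - p - n_\text{groups}$ (when a random intercept is
estimated). The df convention for such tests is genuinely open; this
conservative choice is isolated in one place so a sensitivity analysis
only has to change one line.

Reported per equation:

- **standardized coefficients** $\hat\beta \cdot s_x / s_y$ using
  observation-level sample SDs (interactions via the SD of the realized
  product column) — unitless associations comparable across paths;
- **marginal and conditional R²**: variance of the fixed-effect
  predictor over (fixed + intercept + residual) variance, and with the
  intercept variance added, respectively.

## Piecewise structural equation models

A causal graph declares directed paths among drivers and the change
response, optional correlated-error pairs, and optional interactions of
a driver with the previous year's scaled cover (both main effects and
the product enter the equation whenever an interaction is declared —
prior-year density is a first-class control because recovery depends
on standing stock). Local estimation fits one mixed model per
endogenous node.

Global fit is evaluated through the d-separation basis set: one claim
per unordered non-adjacent pair, conditioned on the union of both
nodes' parents (the published piecewise convention), excluding pairs
bridged by a correlated-error arc (dependence asserted by design) and
pairs of two exogenous variables (their joint distribution is
unmodeled). Each claim augments the child's equation with the main
effect of the claimed-independent variable and records its two-sided
p-value; claims are floored at $10^{-300}$ (with a warning) so the
global statistic stays finite. Fisher's C is

$$C = -2 \sum_{i=1}^{k} \ln p_i \sim \chi^2_{2k},$$

with small upper-tail probabilities indicating missing paths.

```{r}
g <- causal_graph(rbind(c("A", "B"), c("B", "C")), group = "site")
basis_set(g)
fishers_c(c(0.5, 0.5))
```

## The synthetic generators

`generate_subestuary_scenario()` and
`generate_main_channel_scenario()` create datasets with the structure
the analysis assumes, so every stage is testable without any download.
Default layouts mirror the study conditions: 35 subestuaries surveyed
1984--2015, and 51 main-channel stations surveyed 1984--2019 with 1988
unflown.

Drivers are Gaussian on a standardized scale, wired along the allowed
edge sets (land use → nonpoint loads, flow → loads, loads + flow →
change; total N → chlorophyll-a, water column → change) and then
affine- or lognormally mapped onto survey units for the CSV outputs.
Standardized generation makes coefficient recovery directly comparable
to the SEM's standardized outputs. Scaled cover evolves as a lag-1
process

$$s_t = \operatorname{clip}_{[0,1]}\!\big(s_{t-1} + \textstyle\sum_j
\beta_j x_{jt} + b_i + \varepsilon_{it}\big), \qquad
s_t \le s_0 \Rightarrow s_t := 0,$$

with site intercepts $b_i$, AR(1) noise $\varepsilon$, and a floor
$s_0$ (`zero_threshold`) producing the zero inflation — flooring, not a
separate hurdle process, is the simplest mechanism that produces the
≥3-consecutive-zero runs the filter must exercise. A single generator
seeded once per call drives every draw, so equal seeds give
bit-identical datasets. Defaults (residual SD 0.10, site-intercept SD
0.03, $\phi = 0.3$, floor 0.05, driver-layer coefficients 0.3--0.5 and
change-edge effects of moderate size with salinity positive and
chlorophyll-a negative) were fixed once as ecologically plausible
boom-bust magnitudes; the published standardized effects appear only in
a figure graphic, so the generator is a free parameterization, not a
calibration to the study.

Two deliberate limitations matter for interpreting green tests:

- **Clipping censors extremes.** Under boom-bust defaults the $[0,1]$
  bounds truncate large excursions, which attenuates fitted
  coefficients relative to the latent ones (the generator reports the
  analytic latent standardization in `truth`). Parameter-recovery
  checks therefore use a gentle-dynamics configuration (annual step SD
  ≈ 0.03, no floor) where clipping is rare; calibration checks of
  Fisher's C use the boom-bust defaults, because conditional
  independence between a time-i.i.d. exogenous driver and the response
  survives the clipping distortion.
- **What is not emulated:** spatial covariance among neighboring sites,
  driver trends and serial dependence (drivers are i.i.d. across
  years), observation error in photo-interpretation, and the bay's
  absolute hectare magnitudes. Passing tests show the estimators work
  where their assumptions hold, not that real survey data satisfy
  those assumptions.

## Validation problem sizes

The shipped checks run the basis-set builder against exhaustive
enumeration on 500 random DAGs of up to 7 nodes; zone assignment
against per-cell brute force on 100 scenes of up to 10 stations and
2,500 cells; mixed-model recovery on 100 panels of 40 sites × 30 years
(generating values $\beta = (0.8, -0.5)$, $\phi = 0.4$, $\sigma_b =
0.3$); Fisher's C calibration and power on 200 replicates of the
35 × 32 study layout; and the exact KS p-value against full label
enumeration for 200 draws at all sample sizes up to 8 + 8. These sizes
were chosen so each Monte-Carlo standard error is small relative to
the tolerance being asserted.

## Bay-scale variability statistics

Species shares of total SAV cover and deviance ratios (annual cover
over the long-term mean) put species with different extents on a common
scale; by construction the ratio averages 1 over the reference period.
The variability contrast between two species applies a two-sample
Kolmogorov-Smirnov test to the two deviance-ratio samples — the exact
permutation distribution when $nm \le 10{,}000$ and the sample is
tie-free, the asymptotic Kolmogorov distribution with effective size
$nm/(n+m)$ otherwise — plus the ratio of sample SDs as an effect size
("how many times more variable"). Whether the published comparison used
ratios or raw areas, and an exact or asymptotic p, is not recoverable
from the text; the ratio + exact convention is this package's
documented operationalization.

Seasonal discharge aggregation uses calendar windows (spring
March--May; winter December--February assigned to the January year, the
standard climatological DJF convention), excludes missing days and
warns below 90% coverage. The flow--change relationship is an ordinary
simple regression of bay-wide annual areal change on natural-log
discharge; the log base only rescales the slope, never R², F or p.

```{r, fig.alt = "Scaled cover trajectories for simulated sites"}
sim <- generate_subestuary_scenario(
  scenario_config("subestuary", seed = 7, n_sites = 6, n_years = 20))
plot_cover_series(build_cover_series(sim$beds), max_sites = 6)
```

## Design choices that were genuinely open

- **Difference vs ratio** for "proportional change": difference of
  scaled covers (see above).
- **Zero-year density labels**: a zero-area year carries no meaningful
  class; readers accept any label there and the weighting ignores it.
- **Filter placement**: filtering flags years after scaling and
  differencing; it gates regression inclusion only.
- **Zone clipping**: zones are not clipped to navigable or shallow
  water; assignment is purely nearest-station.
- **Ordering of claims**: the claim response is the endogenous member
  of the pair, or the later node in the (declared-order-refined)
  topological order when both are endogenous.
- **Degrees of freedom** for coefficient tests, and AR(1) as the
  correlation structure: as discussed under the engine.

## Limitations

Beyond the generator caveats above: the engine fits random intercepts
only (no random slopes or crossed effects) and Gaussian responses
only; the SEM performs no model search, no AIC comparison and no
latent variables; and the pipeline assumes inputs are pre-classified
monoculture beds — mixed-meadow handling is out of scope.
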