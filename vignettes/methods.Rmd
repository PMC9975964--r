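---
title: "Methods: exposure weighting, exposure-response models, and the synthetic study system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exposure weighting, exposure-response models, and the synthetic study system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqhia)
```

`aqhia` estimates the air-quality and all-cause-mortality consequences of
city-level climate scenarios. This vignette records the models it
implements, the assumptions behind them, the parameters that matter, and
the design choices made where more than one defensible option existed.

## The scenario system

The package works with three kinds of scenario, configured in one YAML
file: a baseline year, a business-as-usual (BAU) future in which a coal
plant inside the city grows its output, and a mitigation-and-adaptation
(M&A) future in which the plant's emissions are eliminated, its supply is
replaced by renewables, and expanded cool roofs damp cooling-electricity
demand. Air quality enters as gridded monthly daily-average PM2.5
surfaces; health effects are computed from the difference between a
scenario surface and the baseline surface over a gridded population.

## Seasonal weighting of representative months

Chemical-transport simulations of a full year are expensive, so the
standard practice the pipeline follows is to model four representative
months — January (winter, Dec–Feb), May (pre-monsoon, Mar–May), July
(monsoon, Jun–Sep), October (post-monsoon, Oct–Nov) — and weight them into
an annual mean. The weights are month counts over twelve:

$$\bar{C}_i^{ann} = \sum_s \frac{m_s}{12}\, C_{i,s}, \qquad
(m_{Jan}, m_{May}, m_{Jul}, m_{Oct}) = (3, 3, 4, 2).$$

The weighting is a design decision: published tables that use this scheme
describe it only as "manual". Month-count weights were chosen because they
reproduce the published annual means from the published monthly means to
two decimals (the test suite asserts 63.40 and 64.90 within ±0.05), which
day-count weights do not, and because they make the annual operator an
affine average — it maps constant fields to themselves and is cellwise
linear, both of which are tested as properties. The ±0.05 tolerance
absorbs the rounding of the printed monthly inputs; one published annual
value (the BAU 65.50) recomputes to 65.53 from its rounded inputs, which
is why the package does not assert that value.

Two exposure summaries are produced per scenario: the unweighted city mean
(all cells counted equally — whether the original analyses masked to
municipal boundaries is unstated, so the default is all cells of the
domain), and the population-weighted mean
$\bar{C}_{pop} = \sum_i C_i P_i / \sum_i P_i$, which is the quantity the
health model responds to. With population clustered where concentrations
are high, the weighted mean exceeds the unweighted one, and the package's
population generator reproduces that structure on demand.

## Exposure-response functions

Two families are implemented. Their numeric parameters are configuration,
not estimates: the headline values ship as defaults taken from the cited
cohort literature, and every one can be overridden in the configuration.

**Log-linear.** Parameterized by a relative risk per 10 µg m⁻³ with its
95% CI; the slope is $\beta = \ln(RR_{10})/10$. Attributable deaths for a
population $P$ at baseline rate $y_0$ (per 100 000 per year) and
concentration change $\Delta C$:

$$\Delta M = \frac{y_0}{10^5}\, P\, \left(1 - e^{-\beta \Delta C}\right).$$

Negative $\Delta C$ gives negative (avoided) deaths. The defaults are the
two all-cause cohort risks used in the motivating analysis, both 1.06 per
10 µg m⁻³ with different CIs (1.02–1.11 and 1.04–1.08), applied to ages
30–99.

**GEMM.** The Global Exposure Mortality Model hazard ratio

$$RR(z) = \exp\!\big(\theta \log(1 + z/\alpha)\, \omega(z)\big), \quad
\omega(z) = \frac{1}{1 + e^{-(z-\mu)/\nu}}, \quad z = \max(0,\, C - c_0),$$

with defaults $\theta = 0.143$ (SE 0.01807), $\alpha = 1.6$, $\mu = 15.5$,
$\nu = 36.8$ µg m⁻³ — the published adult all-age non-accidental
parameters — and counterfactual $c_0 = 2.4$ µg m⁻³, below which
$RR \equiv 1$. Deaths use the risk-ratio form
$\Delta M = (y_0/10^5) P\, (RR_{scen} - RR_{ref})/RR_{scen}$, which is
zero when the concentrations coincide and antisymmetric in the linear
limit.

**Cellwise computation.** The pipeline evaluates these formulas per grid
cell with the cell's band population and sums. The exposed band population
of a cell is its total times the citywide band fraction: no spatial age
structure is available, so age composition is assumed spatially uniform.
The GEMM endpoint applies to ages 25–99, for which no separate baseline
rate is published; the 30–99 all-cause rate (684.21 per 100 000) is
applied to that band as well, and every GEMM result flags the mismatch.
This reuse, and cellwise-vs-aggregate Jensen effects (per-cell avoided
deaths are convex in the size of a reduction, so heterogeneous reductions
beat the same mean reduction applied uniformly — a tested property), are
the two reasons aggregate desk calculations land near, but not on,
published cellwise results; the test suite therefore checks the GEMM BAU
estimate only within ±15%.

**Uncertainty.** Confidence bounds re-run the entire cellwise computation
with the risk coefficient at its CI endpoints ($\beta$ from the RR bounds;
$\theta \pm 1.96\,\mathrm{SE}$) rather than linearizing. For an exposure
increase the bounds bracket the central estimate from below and above; for
a decrease the order reverses, matching the usual reporting convention for
avoided deaths. An ERF without uncertainty information yields `NA` bounds,
and `confidence_interval()` raises an error rather than inventing a width.

## Attainment rollback

`rollback_to_target()` scales every cell by `goal / current` when the
surface's population-weighted mean exceeds the goal — a uniform
proportional rollback, after which the weighted mean equals the goal to
1e-9. The targets ship as a 30% reduction from a baseline mean, an
absolute 40 µg m⁻³, and an absolute 5 µg m⁻³. Proportional scaling was
chosen because the counterfactual method behind the published attainment
numbers is not stated; a per-cell cap-at-level alternative is available
(`method = "cap"`) but is excluded from the package's own verification,
which asserts only the depth ordering of avoided deaths (WHO guideline >
national standard > 30%-reduction) — the ordering is invariant to the
rollback method, while the magnitudes are not.

## Energy and CO2 bookkeeping

The energy module does arithmetic on scenario quantities that are inputs,
not things this package models: supplies and demands in TWh from an
upstream building-stock/cooling-demand analysis, temperatures from a
downscaled climate product. Cool-roof savings convert area times intensity
with exact powers of ten (km² → m², kWh → TWh); the default intensity is
14.2 kWh m⁻² yr⁻¹. Note the deliberate asymmetry carried from the source
tables: 20.60 km² of cool roofs yields 0.2925 TWh of gross savings, while
the scenario demand gap is 0.21 TWh net of climate-driven demand growth
(0.17 TWh); both numbers are reported, neither is "corrected". CO2
emission factors for displaced coal are not printed in the source
material; the defaults (0.938–1.243 kg CO2 per kWh) are back-solved from
the published avoided-CO2 range and labelled as calibration in the
documentation.

## The synthetic study system

The generator exists so that every downstream stage is testable, seeded
and self-contained. What it emulates, and what it does not:

- **Background fields** are white noise smoothed by a separable Gaussian
  kernel (the simplest generator with a controllable correlation length,
  default 3 cells), standardized to a chosen spatial SD (default
  12 µg m⁻³, of the order of the published monthly SDs), shifted to the
  seasonal city mean and clipped at zero. Standardizing before the shift
  pins the pre-clipping field mean to the seasonal mean exactly. With
  `spatial_sd = 0` the field is exactly constant, which the tests exploit
  for closed-form comparisons.
- **The plume** is an isotropic exponential kernel
  $e^{-d/\ell}$ in cell distance, additive and hence commutative across
  sources. Real dispersion is directional chemistry-and-meteorology;
  representing it is out of scope, and the kernel is a documented,
  configurable stand-in. The demo configuration sets the source term
  (28 µg m⁻³ at the source cell, $\ell = 6$ cells on a 32×32 grid) so the
  plume contributes roughly 10% of the city mean, consistent with the
  ~12% industrial share of urban PM2.5 reported for the motivating city;
  this is a knob, not a measured value.
- **Population** is allocated by largest-remainder apportionment
  (floors plus largest fractional parts, ties broken by cell order), so
  integer counts sum to the configured citywide total exactly — growth to
  a future year is exact in the same sense. Age bands are citywide
  fractions. Lognormal cell heterogeneity (dispersion 0.5) and an optional
  tilt toward a concentration surface give the weighted-above-unweighted
  exposure structure.
- **Monitors** observe the field at distinct cells with multiplicative
  model bias — monitor = field / (1 − bias) + noise — matching the
  percent-difference diagnostic `seasonal_model_bias()` computes
  (positive = model underestimate). The closure test injects 25% and
  recovers it within Monte-Carlo error at 10 monitors × 30 days/season;
  the demo configuration's bias defaults (30%, 25%, 20%, 0.5%) mirror the
  seasonal under-estimation pattern reported for the motivating model
  evaluation.

What passing tests on this system do **not** show: that a real
chemical-transport model is unbiased, that real plumes are isotropic, that
age structure is spatially uniform, or that real populations follow a
lognormal field. The generator's role is to verify the *accounting* —
weighting, aggregation, ERF evaluation, CI propagation, conservation —
under known truth.

## Numerical choices and degenerate inputs

- Grid default 32×32 cells at 4.2 km²; the source resolution is published
  but the domain cell count is not, and 32×32 keeps a full pipeline run
  well under a second. Tests use 4×4 to 10×10 grids; oracle-equivalence
  checks run 100 seeded 8×8 trials at 1e-9 relative tolerance.
- All generators save and restore the RNG state, so calling them does not
  disturb a user's random stream; identical seeds give bit-identical
  output (tested).
- A 1×1 grid, zero spatial SD, zero emission scale, equal scenarios,
  degenerate (zero-width) CIs and empty seasons are all defined and
  tested; zero band population and a zero current population total raise
  typed errors rather than returning NaN.
- Percent changes are computed against the reference (earlier) scenario's
  population-weighted mean.
- `validate_config()` accumulates every violation before reporting, so a
  user fixes a configuration in one pass.

## Interfaces

Stages are plain functions over tibbles; `run_pipeline()` composes them
and `write_run_report()` serializes the tables (long-format CSV for
gridded fields; CSV report tables; a JSON manifest with the configuration
hash and seeds). A thin command-line wrapper (`inst/cli/aqhia`) runs the
whole pipeline from a shell; it deliberately exposes a single end-to-end
command rather than per-stage subcommands, since each stage is an exported
function and partial runs are more natural from R. Serialization is
CSV/JSON only.

## Known limitations

- No atmospheric chemistry, meteorology or emission speciation; scenario
  air quality differences enter through configured seasonal means and the
  plume scale.
- No morbidity, cause-specific mortality, life-table/years-of-life-lost
  computation, or monetary valuation.
- The 30–99 baseline rate stands in for the 25–99 band (flagged in every
  GEMM result).
- Published mortality-rate increments are not arithmetically consistent
  with published death counts over the published populations; this package
  always derives rates from its own death counts and does not attempt to
  reproduce printed rate rows.
- Attainment magnitudes depend on the unpublished rollback method and ERF
  assignment; only their ordering is treated as a verifiable claim.
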