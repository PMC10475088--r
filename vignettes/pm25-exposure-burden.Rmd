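---
title: "Methods: population-weighted PM2.5 exposure, attributable mortality, and driver decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-weighted PM2.5 exposure, attributable mortality, and driver decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmburden)
```

This vignette is the package's own account of the science it
implements: the models and their assumptions, the tunable parameters and
why their defaults are what they are, what the synthetic data generator
does and does not emulate, and the numerical conventions adopted where
the methodology leaves choices open.

## 1. Population-weighted exposure and its normalization

For a scope (territory, region, or the globe) with gridded annual-mean
concentration $PM_l$ and population $P_l$ over cells $l$,

$$E = \frac{\sum_l PM_l \, P_l}{\sum_l P_l}.$$

Population weighting is the only weighting applied: cells are treated as
samples of where people live, and no additional area weighting is used
(`pwExposure()`). Cell coordinates are cell-center latitude/longitude on
a regular grid; no equal-area reprojection is attempted, because the
population weights already carry all the mass that matters to $E$.

The *normalized* PW exposure of a sub-scope $k$,

$$NE_k = \frac{E_k P_k}{P_{global}}, \qquad \sum_k NE_k = E_{global},$$

expresses each region's contribution to global exposure in the same
units (µg/m³); `contributionShare()` divides by $E_{global}$ to give the
fractional contribution. The additivity identity is exact by
construction and the package asserts it to a relative tolerance of
1e-9 in its tests and pipeline invariants.

**Missing data.** Cells with missing concentration but non-zero
population are excluded from both numerator and denominator (weight
renormalization), and the exclusion is reported via a message. A
seamless concentration product never triggers this path; a gappy one
will, and the message makes the renormalization visible. A scope with
zero total population raises an explicit error rather than returning
`NaN`.

**Population harmonization.** `rescalePopulationRaster()` rescales a
gridded population within each territory to match external per-territory
totals, the standard harmonization between a gridded population product
and national demographic tables. The synthetic generator produces
rasters already consistent with its demography tables, so the pipeline
itself does not need the rescaling step; it is provided for real-data
use.

## 2. Trend estimation

`olsTrend()` fits `value ~ year` by least squares and reports the slope,
its 95% confidence interval (slope standard error times the $t$
quantile at $n-2$ degrees of freedom) and the two-tailed $t$-test
p-value; with this construction `p < 0.05` and "the CI excludes zero"
are exactly equivalent statements. `mannKendallTrend()` provides the
non-parametric cross-check: the tie-corrected Mann–Kendall test with
continuity correction and Sen's slope (median of pairwise slopes). On a
noiseless line the two slope estimators agree exactly;
`trendConsistency()` quantifies their agreement across a collection of
series as the squared correlation of the slope vectors.

Numerical conventions:

* a zero-residual fit has an undefined $t$ statistic; the package
  returns p-value 0 and a zero-width interval with a warning, which is
  the limiting behaviour as noise vanishes;
* sub-period fits split at the pivot year with the pivot included in
  *both* periods (e.g. 1998–2011 and 2011–2019). With annual data this
  uses the pivot as the hinge observation of both regimes; excluding it
  from one side would discard the only observation the two regimes
  share;
* no autocorrelation correction (prewhitening) is applied; the method is
  plain OLS on annual means.

## 3. Counterfactual projections

`projectCounterfactual()` supports two scenarios beyond a pivot year:
`extend_pre_trend` continues the OLS slope fitted to the years up to and
including the pivot ("business as usual"), and `hold_at_pivot` freezes
exposure at the pivot value. The business-as-usual slope is taken from
the OLS fit rather than from endpoint differences: the package's own
trend machinery is OLS throughout, and multi-year fits are less
sensitive to single anomalous years than endpoint differencing.
Projected concentrations are floored at zero.

## 4. Concentration-response curves and attributable mortality

The relative-risk family is the GEMM functional form

$$RR(E) = \exp\!\left(\theta\,
  \frac{\log(1 + z/\alpha)}{1 + \exp(-(z-\mu)/\nu)}\right),
  \qquad z = \max(0, E - z_{cf}),$$

which equals 1 at and below the counterfactual concentration $z_{cf}$
and rises monotonically but ever more slowly — the supra-linear shape
that makes a unit of exposure reduction worth more in cleaner air. The
counterfactual $z_{cf}$ defaults to 2.4 µg/m³, the conventional
theoretical minimum-risk exposure level for this curve family, and is
configurable per curve.

The shipped parameter set (`defaultCRFParameters()`) is a **synthetic
fixture**: curves with realistic magnitudes and the correct structure —
age-resolved in 5-year bands from 25–29 to 95+ for IHD and Stroke (with
hazard scale declining with age), one age-independent curve each for
COPD, lung cancer and diabetes (25+), and LRI curves for children under
5 and adults 25+ — but the $\theta, \alpha, \mu, \nu$ values are not
estimates from any cohort. The published parameter sets live in external
repositories; consequently absolute mortality magnitudes computed with
the fixtures are structurally meaningful but not comparable to published
totals. The 95% band is carried as lower/central/upper values of
$\theta$ (±20% for the fixtures); since $RR$ is monotone in $\theta$ the
variants are ordered pointwise at every concentration, which guarantees
ordered burden bounds without further checks. The CRF interface is
pluggable (`crfSpec()`, `readCRFTable()`), so tabulated or alternative
curve families can be swapped in without touching the pipeline.

Attributable deaths follow
$D_{PM} = \sum_i \sum_j D_{ij}\,\mathrm{PAF}_{ij}(E)$ with
$\mathrm{PAF} = 1 - 1/RR$, evaluated at each territory's own PW
exposure — one exposure value per territory-year, not per cell. The
disease-age eligibility rule (LRI: under 5 or 25+; the other five
diseases: 25+) is enforced when tables are loaded
(`validateDeathsTable()`). Single-year ages map into 5-year CRF bands by
containment (ages 25–29 to the first adult band, and so on); the under-1
bin carries age 0 and the 95+ bin age 95. Confidence intervals for
$D_{PM}$ re-evaluate the sum with the lower/upper curve variants only;
baseline-mortality and exposure uncertainty are *not* propagated into
the interval.

## 5. Marginal benefits: finite differences and their clamp

The sensitivity of the burden to a marginal exposure change is

$$\frac{\Delta D_{PM}}{\Delta E} = \sum_i \sum_j D_{ij}\,
  \frac{\mathrm{PAF}_{ij}(E + \Delta E) - \mathrm{PAF}_{ij}(E - \Delta E)}
       {2\Delta E},$$

with $\Delta E = 5\%\,E$ by default and the full window $2\Delta E$
clamped into $[1, 5]$ µg/m³. The clamp is interpreted as acting on the
*window* before it is split symmetrically around $E$; the alternative
(clamping after splitting) differs only in how the bound is reached and
not in the evaluated window width. If the lower evaluation point would
be negative — possible only when $E < 0.5$ µg/m³ — a forward difference
over $[E, E + 2\Delta E]$ is used and reported. The per-capita variant
divides by the relevant population (ages under 5 or 25+) and is
expressed as annual deaths per million persons per µg/m³.

The clamp bounds are exposed as arguments so tests can shrink the window
and verify convergence of the finite difference to the analytic
derivative of $\mathrm{PAF}\circ RR$; the package's tests require
relative error below $10^{-3}$ at a window of 0.01 µg/m³ and agreement
within 2% between 5% and 10% relative steps at 30 µg/m³.

## 6. The order-ensemble decomposition

Each (territory, age, disease) cell factorizes as

$$D_{PM}(i,j,k) = P_k \cdot AF_{ik} \cdot MR_{ijk} \cdot
  \mathrm{PAF}_{ij}(E_k),$$

total population × age fraction × mortality rate × attributable
fraction. Between two consecutive years the four factors are switched
from old to new values one at a time; a switching order assigns each
factor the change observed when it flips. Averaging over all $4! = 24$
orderings gives each factor's Shapley value, which is symmetric in the
factors and conserves the total change exactly — the package tests
conservation at 1e-9 relative tolerance and equality with a brute-force
subset-enumeration Shapley computation.

Conventions:

* the decomposition runs per neighbouring-year pair (not endpoint to
  endpoint) to minimize nonlinearity effects, at (territory, age,
  disease) granularity, and is summed to regions or the globe
  afterwards; this order of operations is fixed because summation and
  the nonlinear PAF factor do not commute;
* cumulative contributions are referenced to a pivot year: zero at the
  pivot, forward pair sums after it, and *negated backward* sums before
  it, so every ledger entry reads "change relative to the pivot" with a
  consistent sign on both sides;
* the sensitivity decomposition replaces $\mathrm{PAF}$ with
  $\Delta\mathrm{PAF}/\Delta E$ and is conventionally presented
  normalized to the scope's pivot-year value
  (`aggregateLedger(..., normalize = TRUE)`), since its absolute scale
  mixes deaths and concentration units;
* accumulation "since the pivot" sums the pairs pivot→pivot+1 through
  horizon−1→horizon, each pair exactly once.

## 7. What the synthetic generator emulates — and what it does not

`scenarioConfig()` describes a world of `nTerritories` rectangular
territories tiled over a regular lat/lon grid and grouped into
`nRegions` regions. Its components:

* **Exposure fields.** Territory means follow
  $base + pre \cdot (y - y_0)$ up to the breakpoint and continue with
  slope $post$ after it — piecewise linear and continuous. A fixed
  smooth spatial texture (demeaned within each territory, so territory
  means are exact) and i.i.d. Gaussian cell noise (clipped at zero) are
  superimposed. The noise model is a stand-in: the error structure of
  real satellite-derived products is spatially correlated and regionally
  heterogeneous in ways that are not publicly characterized beyond
  aggregate validation statistics, so only aggregate behaviour (means,
  trends, their recovery) should be read from the synthetic fields.
* **Population rasters.** Three isotropic Gaussian foci per territory
  over a thin uniform background, mimicking the urban concentration that
  makes PW exposure diverge from area means; totals compound at
  `popGrowthRate`. Focus locations are drawn once from the seed and are
  identical across years, so totals grow exactly geometrically.
* **Demography.** Single-year ages 0–95 with an exponential age pyramid
  whose scale is solved (by `uniroot`, tolerance 1e-10) so the mean age
  drifts upward at exactly `agingRate` years/year; baseline mortality
  follows Gompertz-like age curves per disease, declining at
  `mortalityDeclineRate` per year, with the LRI childhood rate flat
  below age 5. The construction is deterministic — no demographic noise.

**Reference scenario defaults** (all overridable): 24 territories in 6
regions on a 60×120 grid of 0.1° cells, years 1998–2019 with the
breakpoint at 2011; base exposures 15–60 µg/m³ positively associated
with territory population (populous territories are the polluted ones,
the skew that drives PW exposure); pre-breakpoint trends +0.3 to +1.5
µg/m³/yr, post-breakpoint trends +0.2 down to −1.5 µg/m³/yr so
high-exposure, high-population territories reverse hardest; population
growth 0.6%/yr, mean-age drift 0.15 yr/yr, mortality decline 1.2%/yr,
cell noise 1 µg/m³. The demographic rates are set so that, after the
breakpoint, the extra deaths from population growth and aging
approximately offset the reductions from falling exposure and falling
mortality rates — the driver balance that produces a plateau in
attributable mortality alongside the exposure reversal, which is the
regime the pipeline is designed to dissect. The 0.1°-class grid (rather
than the 0.01° of real products) is a deliberate choice: every method in
the package is resolution-agnostic, and desk-scale grids keep a full
end-to-end run in seconds.

The generator makes no attempt to mimic real geography, actual border
shapes, or empirical age-pattern detail; territories are rectangles and
pyramids are exponential. Passing tests on synthetic data therefore
demonstrate the *estimators and identities* (trend recovery,
conservation, additivity, monotonicity), not the realism of any
particular mortality total.

**Determinism.** All randomness flows from the single config seed
through fixed substreams (one per module and year), so every generated
raster and table — and hence every pipeline output — is bit-identical
across reruns and independent of call order.

## 8. Validation metrics

`rmsd()`/`nrmsd()` implement the root-mean-square difference between
collocated estimates and observations and its normalization by the
observed mean. `bootstrapPwNrmsd()` evaluates PW exposure computed from
a monitor network: for each draw size $n$ it samples sites *without
replacement* $m = \mathrm{round}(N/n \times 200)$ times and reports the
NRMSD across the $m$ paired PW values. Sampling without replacement
makes the $n = N$ case degenerate-exact (every draw is the whole
network), a useful identity check; $m$ is rounded to the nearest
integer since the formula can be fractional. Site weights use the
population of the raster cell containing the site — the natural choice
when no catchment definition is available, and the one the tests
assume. The module is exercised on synthetic monitors only; no
real-network statistics are reproduced.

## 9. Problem sizes and test design

The test suite builds all fixtures in code. Typical sizes, chosen so the
default suite completes in well under a minute of compute per module:
4-territory 12×12 worlds for pipeline identities, a 50-territory 20×50
world for the estimator-agreement check, 100 seeded replicates of a
2-territory 8×8 world for slope-recovery coverage, 1000 replicates of a
10-point series for CI coverage, and 100 random two-territory factor
states for decomposition conservation. Statistical checks with nominal
error rates (2-standard-error bands, 95% CI coverage) are asserted as
near-universal success across fits rather than universal success, with
the strict threshold placed where the binomial variability of the check
itself is negligible.

## 10. Known limitations

* Fixture CRF parameters: absolute burden magnitudes are synthetic (see
  §4); only structure, identities and qualitative regimes transfer to
  real data.
* CI propagation covers the risk-curve uncertainty only.
* Exposure enters at territory level; within-territory covariance of
  exposure and demography is invisible to the burden model.
* Equitoxicity of PM2.5 mass is assumed, as in the underlying
  risk-curve literature; no chemical-composition adjustment.
* No autocorrelation-aware trend variants, no sub-annual analysis, no
  alternative decomposition families (the Shapley brute-force oracle in
  the tests plays the robustness-check role instead).
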