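---
title: "Methods: material-balance capacity, warning index and mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: material-balance capacity, warning index and mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilcap)
```

This vignette documents the models implemented in `soilcap`, the
assumptions behind them, the parameters that matter, and the numerical
and design choices made where the methodology leaves room.

## The material-balance capacity model

A unit of agricultural topsoil is treated as a fixed reservoir of mass
`M` per hectare — by default 2.25 × 10⁶ kg/hm², the conventional weight
of the 0–20 cm plough layer. Three concentrations parameterize each
element: the natural background `C_ib`, the regulatory risk reference
value `C_ic` (the screening concentration above which risk to produce
is presumed), and the measured status `C_io`, all mg/kg.

**Static capacity** `Qs = M (C_ic − C_ib) 10⁻⁶` is the total admissible
load of pristine soil, in kg/hm². **Residual capacity**
`Qi = M (C_ic − C_io) 10⁻⁶` replaces the background with the current
status; it is the quantity that warning grades and maps are built on.
Both are signed: a background or status above the reference value
yields a negative capacity, which the package carries through every
stage unchanged — truncating would erase the overload signal, and the
shipped city tables themselves contain negative cells (Zhongshan Cd
static −0.12 kg/hm², Foshan Cu residual −3.79 kg/hm²).

**Dynamic capacity** adds a first-order retention model. Each year a
fraction `K` (the *residual rate*, default 0.9 — losses to crop uptake,
runoff and leaching are folded into the 10 % that leaves) of the soil
content persists, so with constant annual input `a` the content obeys
`C_{t+1} = K (C_t + a)`. Solving for the constant input that drives the
content from `C_io` to the admissible total over `n` years gives the
average annual capacity

```
Qn = M (C_ic − C_ib − C_io K^n) (1 − K) / (K (1 − K^n)) 10⁻⁶   [kg/(hm² a)]
```

Two checks pin this closed form down: at `n = 1` with `C_io = 0` it
reduces to `Qs / K` exactly, and the test suite solves the recursion
independently by bisection (`accumulation_trajectory()`) and verifies
the closed form drives the trajectory to `C_ic` at year `n` to 1e−9.
`K` is a single scalar by default because element-specific retention
data are rarely available; `model_config()` accepts a named per-element
vector where they are. The formula degenerates at `K = 0` and `K = 1`,
which are rejected. Default horizons are 14 and 24 years from the
2014 baseline (evaluation years 2028 and 2038).

Aggregation to an administrative unit uses the arithmetic mean of the
unit's sample concentrations. Because every capacity is an affine map
of concentration, the capacity of the mean equals the mean of the
capacities, which is what makes the published per-city tables exactly
invertible (below).

## Warning index and classification

Per element, residual capacities are min–max normalized over the
*normalization population* — by definition the set of evaluation units
in the current run (the nine cities, or the grid cells in map mode).
This is the one genuinely open choice in the method: the composite
index of a unit depends on which other units it is compared against,
so indices from runs over different populations are not comparable.
`warn_units()` therefore records the bounds it used (exposed in the
pipeline manifest) and accepts externally supplied per-element bounds
to reproduce a previous run's frame of reference; reruns that reuse
manifest bounds are byte-identical. Negative capacities enter
normalization unmodified and, as worst-in-population values, typically
map to 0 after clamping to [0, 1].

The comprehensive index replaces the classical Nemerow maximum term
with the *minimum* normalized capacity,
`P = sqrt((P_ave² + P_min²) / 2)`, so a single overloaded element
dominates the score downwards — appropriate when the score warns about
risk rather than rewards average quality. Algebraically
`P_min ≤ P ≤ P_ave`, which the suite asserts over randomized
populations. Grades I–V partition [0, 1) in 0.2-wide bins,
lower-inclusive/upper-exclusive as the grade table's `0.2 ≤ Pi < 0.4`
notation reads; `P` is clamped to [0, 1] before classification and
`P = 1` closes into grade V, since the table leaves the endpoints
undefined. The shipped per-city index table keeps its published labels
verbatim even where one row (Zhuhai, Pi = 0.87, labelled medium
capacity) disagrees with the bin table; classification code follows
the bins.

## IDW mapping

`Z*(x₀) = Σ φᵢ Z(xᵢ)` with weights `dᵢ^−power` renormalized over the
`k` nearest samples. Power 2 and `k = 12` are the conventional GIS
defaults; both are exposed in the configuration. A target within
1e−9 m of a sample returns the sample value exactly (the weight is
singular there, and exactness at data points is the defining IDW
property). Predictions are convex combinations, so every cell lies
within the range of the contributing samples; the suite checks
agreement with a brute-force double loop to 1e−10. Cells are evaluated
at cell centers; the value matrix is stored with the northernmost row
first while the grid is georeferenced from its lower-left corner —
the fixed convention that makes the Esri ASCII export unambiguous.
Coordinates are planar meters in an arbitrary projected CRS; distances
are Euclidean and no geodesic handling or reprojection is attempted.

## Fixtures and the synthetic-data generator

The shipped city tables give capacities, not concentrations, so
`build_city_fixtures()` inverts the static and residual formulas cell
by cell (`C_ib = C_ic − Qs/(M·10⁻⁶)`, `C_io = C_ic − Qi/(M·10⁻⁶)`) and
asserts that the forward model reproduces all 144 published cells to
better than their two-decimal rounding. The inversion implies
city-specific backgrounds (the basin-wide standards table alone cannot
reproduce per-city static capacities), so backgrounds are treated as a
per-unit input throughout; `fixture_standards()` expands them into the
per-unit layout `capacity_table()` accepts. One back-derived background
exceeds its reference value (Zhongshan Cd) and is kept as-is.

`generate_campaign()` emulates a field campaign: per city and element,
concentrations are i.i.d. lognormal with the city's fixture mean and a
requested coefficient of variation (lognormal because trace-element
concentrations are positive and right-skewed), and coordinates are
uniform in a synthetic rectangular city extent derived from approximate
city-center positions rescaled to planar kilometers — rectangles exist
only to exercise interpolation and are not administrative boundaries.
No sample count or concentration variance is published for the
original campaign, so the defaults `n_per_city = 50`, `cv = 0.3` are
fixed here as a realistic mid-size survey; the recovery tests use
`n_per_city = 200`, `cv = 0.2` with 50 replicates, sized so the suite
completes in seconds on one CPU. What passing these tests shows is
that the pipeline recovers its own generator's ground truth; real
soils add spatial autocorrelation, measurement error and non-lognormal
tails that the generator deliberately omits.

## Known limitations

- The basin-wide composite index depends on an unstated normalization
  population and is therefore checked by properties (bounds, ordering
  of cities, Foshan minimal) rather than reproduced as a number.
- Grade recovery under sampling noise is limited by bin-edge
  adjacency: Jiangmen's noiseless composite index (0.3986) lies 0.0014
  below the 0.4 grade boundary, so with 200 samples per city at
  cv = 0.2 its grade flips in roughly a third of replicates even
  though its status means are recovered to well under 1 %. Grade-level
  agreement is asserted across all (city, replicate) pairs, where it
  exceeds 95 %; a per-city guarantee is unattainable for units sitting
  on a boundary.
- `K` is assumed, not estimated; plant-uptake and leaching submodels
  are out of scope, as is kriging (plain IDW only) and cartography
  beyond raster export.
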