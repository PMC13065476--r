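---
title: "Methods: two-stage SMCE for offshore mussel site selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage SMCE for offshore mussel site selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musselsmce)
```

## The model

The package answers two ordered questions about a gridded sea area:
*where is blue-mussel longline cultivation feasible at all*, and *how
suitable is it where feasible*. The first is Boolean, the second fuzzy —
this split matters because the suitability index (SI) averages each
factor's score over the record, so a short lethal event (a heat spike)
that would barely dent a 5-year mean must instead act as a hard exclusion.

**Feasibility.** A cell survives only if all three hold over the record:

* no heat-spike episode: an episode is a *maximal* run of at least
  `heat_min_run = 3` consecutive days with daily SST strictly above
  `heat_threshold = 25` °C (a 7-day run is one episode, not five
  overlapping ones). "Above" is read as a strict inequality; a day at
  exactly 25 °C does not extend a run. Missing days break runs, which is
  the conservative reading for gap-free daily products with sparse gaps.
* depth within the inclusive band 5–100 m ("5–100 m" is a closed range as
  printed; inclusivity only moves cells whose depth is exactly on a
  bound). Bathymetry must declare its sign convention (`depth` or
  `elevation`) — silent sign guessing is a classic source of inverted
  masks.
* daily-average current speed always below 1 m s⁻¹. The criterion "1 m s⁻¹
  daily average" is ambiguous between *no daily mean may reach the limit*
  and *the period mean stays under it*. The record-max rule is the
  default: a single extreme day endangers longline gear, mirroring the
  logic of the heat-spike exclusion. The period-mean alternative is kept
  as `rule = "mean"`.

Feasibility runs on the fine (0.05°-like) grid. Areas are spherical cell
areas, A = R²·Δλ·(sin φ_top − sin φ_bot) with R = 6371 km; whether
published km² figures used spherical areas or an equal-area projection is
not stated anywhere we could check, so spherical areas are assumed and
stated here.

**Suitability.** Four factors are scored per time step at their native
cadence (daily SST and chlorophyll, monthly salinity and sediment), the
scores are averaged per cell (*score-then-average*: the response functions
are nonlinear, so averaging the data first would bias the score), and the
means are combined cellwise as SI = Σᵢ wᵢ F̄ᵢ, classed into five bands.
Bins are left-closed, right-open, the last closed, so every SI in [0, 1]
lands in exactly one class and a value at a boundary (0.2) goes to the
upper band ("Low").

The response functions and their tunables:

| factor | form | parameters (defaults) | units |
|---|---|---|---|
| SST | cardinal-temperature product, 0 at/above T_max | T_max = 30, T_opt = 15.8, c = 0.393 | °C, °C, °C⁻¹ |
| CHL | Michaelis–Menten saturation | X_K = 1.06 | mg m⁻³ |
| SSS | fitted quartic, clamped + standardized | intercept −0.875038; domain [0, 40] | practical salinity |
| SPM | fitted quadratic, clamped + standardized | intercept 0.8273; domain [0, 100] | g m⁻³ |

The published standardization rule is min–max rescaling "from 0 to 1", but
the evaluation domain is not printed. We take SSS ∈ [0, 40] (fresh to
fully marine, covering every input the pipeline can produce) and
SPM ∈ [0, 100] g m⁻³ (the quadratic crosses zero near 54.7 g m⁻³, so any
wider domain changes nothing once negatives are clamped). Both are
configurable and recorded in run metadata. The SST and CHL forms already
have infimum 0 and supremum 1 on their domains, so standardization is the
identity for them. Negative polynomial values are clamped to zero *before*
standardizing: a negative condition index or absorption efficiency is
physiologically meaningless, and clamping first keeps the zero of the
score aligned with the zero of the response.

**Weights.** The AHP machinery takes any positive reciprocal matrix,
derives the principal right eigenvector by power iteration (convergence
tolerance 1e-12 on the normalized vector; a dense eigendecomposition is
used as an independent oracle in the tests, never as the implementation),
and reports λmax, CI = (λmax − n)/(n − 1) and CR = CI/RI(n) with Saaty's
RI table (RI(4) = 0.90). The expert judgment matrix behind the published
weights (0.45, 0.30, 0.16, 0.09) is not public, so the default
configuration ships the perfectly consistent ratio matrix a_ij = wᵢ/wⱼ
rebuilt from those weights — it reproduces them exactly with CR = 0 and
keeps the consistency check exercised — while any user matrix can be
supplied in its place.

**Mixed resolutions.** Factor scores are computed at each variable's
native grid, time-averaged, then moved to the coarse (0.25°-like) working
grid by block averaging; the feasibility mask moves to the coarse grid by
strict majority (>50 % of valid fine cells). Block means are
*area-weighted*: a coarse cell's area is exactly the sum of its fine
cells' spherical areas, so the area-weighted field mean is conserved to
rounding (tested at 1e-9 relative). Majority was chosen for Boolean
coarsening as the unbiased default; how a published fine mask maps onto a
coarser suitability grid is never specified, so the rule is configurable.
Missing data propagate leniently: a coarse cell is missing only when
*every* contributing fine cell is missing, which suits gap-free daily
products.

**Climate delta.** The SI change to mid-century replaces only the SST
factor, scored from decadal-mean SST rasters (no temporal averaging), with
the other factor means held fixed; the delta is 100 × (Proj − Ref)/Ref per
cell, with Ref = 0 cells returned missing rather than infinite. Both the
reference and the projected SI go through the same decadal-mean pathway so
the two decades are processed identically — comparing a daily-pathway
reference with a decadal-pathway projection would confound the delta with
the pathway difference. The feasibility mask is deliberately *not*
updated under projection: decadal means cannot resolve heat-spike runs,
and pretending otherwise would fabricate information.

**Co-location.** Zonal means over wind-farm polygons use cell-center
rasterization (a cell belongs to a farm if its center is inside the
polygon); a farm too small to contain any center takes the value at the
center nearest its centroid, so small farms are never silently dropped.
Fractional-coverage weighting would be the natural extension but adds
geometry complexity without changing the ranking at these farm/cell size
ratios. Farms are ranked by mean SI descending, ties by accessibility
descending, remaining ties by id — a deterministic total order; farms with
no valid SI cell sort last and are flagged rather than dropped.

## The synthetic scenario

The generator emulates the *structure* of the real input layers — their
grids, cadences and the qualitative gradients the method keys on — not
their physics:

* daily SST: southern-edge mean 14 °C, poleward gradient 0.8 °C per
  degree latitude, seasonal amplitude 5 °C (peak near day 210), AR(1)
  noise (sd 0.4 °C, lag-1 correlation 0.8, independent across cells);
  the background can never reach 25 °C, so heat spikes exist only where
  injected — which is what makes exact-recovery tests possible;
* heat-spike injection: inside a region box, the series is capped just
  below threshold and exactly *n* runs of the requested duration at
  25 °C + `exceed` are placed, evenly spaced with at least two
  sub-threshold days between runs; outside the box the series is
  bit-identical to the input;
* chlorophyll and sediment: offshore baselines (0.4 mg m⁻³, 1 g m⁻³) plus
  exponential coastal enrichment (e-folding 30 and 20 km) and, for SPM,
  river hotspot boxes — enough to give suitability its coastal gradient;
* salinity: marine baseline 35 with a brackish sub-basin fixed at 4. The
  basin emulates an inner-Baltic-type surface (practical salinity 3–5),
  where the quartic condition response is near zero; this is what makes
  the basin the low-SI region of the domain, reproducing the pattern of a
  salinity-limited marginal sea. (Mid-range brackish values around 10–20
  would *not* reproduce it — the quartic peaks near salinity 21.)
* currents: background 0.25 m s⁻¹ with a channel box at 1.3 m s⁻¹
  exceeding the 1 m s⁻¹ limit;
* waves: 3-hourly by default (hourly optional) — the accessibility metric
  is a fraction of time steps and cadence-invariant in expectation, and
  3-hourly bounds the record length; domain-wide triangular storm pulses
  (about 1.5 per month, 24–72 h, amplitude 3 m) on an offshore-increasing
  base of 1.0–1.3 m. Setting the storm amplitude to zero switches storms
  and their noise off entirely, which pins accessibility at exactly 100 %
  below the 1.5 m limit — a degenerate configuration kept for testing;
* bathymetry: a <5 m nearshore fringe, a shelf deepening to 60 m by 80 km
  offshore, then a slope to a 500 m basin, so all three depth regimes
  (too shallow, workable, too deep) are present;
* land: missing cells along the western grid edge; "distance from coast"
  is eastward distance to that edge. One straight coast is the minimum
  geometry that makes coastal gradients exist.

The default domain is 2° × 2° (fine 40 × 40 at 0.05°, coarse 8 × 8 at
0.25°) over 5 years; the test suite mostly runs 1-year versions of the
same scenario, sizes chosen so the whole suite and the end-to-end
pipeline stay fast while every code path (leap days included via
2019–2023-style calendars) is exercised. A single master seed expands
into fixed per-variable child seeds, so adding one variable to a scenario
never perturbs the others, and identical configurations are byte-identical.

What passing tests on this scenario do *not* show: skill on real oceans.
The generator has no advection, no spatially correlated noise, no
tides, no realistic wave climatology, and a one-edge coastline; it
validates the *mechanics* (masking, run-length detection, averaging,
weighting, ranking, determinism), not the geophysics. Continental-scale
published figures require the original multi-hundred-GB data products and
are out of scope here.

## Numerical choices and degenerate inputs

* Polynomial extrema for standardization: dense 4001-point grid over the
  domain plus the real roots of the derivative (critical points), so the
  max is exact to machine precision rather than grid-limited.
* Power iteration stops when the normalized weight vector moves less than
  1e-12 in max norm; CR is floored at 0 to absorb −1e-16-style round-off
  on consistent matrices.
* `sst_score` clamps to [0, 1] against floating-point overshoot near
  T_opt; the piecewise branch at T_max is evaluated before clamping.
* Regridding: bilinear refinement clamps target centers onto the source
  center hull (nearest-edge extension) instead of extrapolating.
* Raster text I/O writes 17 significant digits so write-then-read
  round-trips doubles exactly.
* Degenerate inputs are contracts, not crashes: an all-infeasible
  criterion yields an empty SI map and a zero-row ranking; an empty farm
  set counts zero overlaps; all-missing cells stay missing through every
  stage; Ref = 0 cells in the climate delta are missing, never ±Inf.
* Gridded stacks travel as a JSON-header + CSV-matrix pair mirroring a
  CF-style NetCDF variable in plain text; static rasters as ESRI ASCII
  grid; vector features as GeoJSON; tables as CSV — all formats chosen to
  be diffable and exactly reproducible.

## Known limitations

* Geographic coordinates only; no projection engine, no land-avoiding
  port routing (distances are great-circle).
* Only the *M. edulis* parameterization ships; all parameters are
  configurable but no alternative species defaults are provided.
* Wind-farm polygons are treated as simple rings (no holes, no
  multipolygons).
* The climatological marine-heatwave definition (90th percentile of a
  30-year baseline) is intentionally not implemented; the heat-spike
  definition here is species-specific.
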