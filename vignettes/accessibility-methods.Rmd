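---
title: "Modelling geographic accessibility and capacity-constrained coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling geographic accessibility and capacity-constrained coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

accesscape measures two related but distinct things about a health
system on a raster landscape: *accessibility* — how long it takes the
population to travel to the nearest facility offering a service — and
*coverage* — how much of the population the reachable facilities can
actually serve given their capacity. This vignette explains the models,
the parameters that matter, the numerical conventions, and what the
synthetic landscape does and does not emulate.

## The friction-surface model

All layers live on one reference frame: the elevation model's grid
(square cells, projected metric CRS; geographic-degree inputs are
rejected rather than silently reprojected). Mismatched layers are
resampled onto that frame with `align_to_reference()` — nearest
neighbour for categorical layers, Keys cubic convolution (a = −0.5) for
continuous ones. Cubic convolution reproduces constants and linear
ramps exactly, which is what makes the resampling tests closed-form.

The merged land-cover grid drives traversal. Twelve classes: seven
generic land-cover classes, three road tiers with the tertiary tier
split into all-vehicle / two-wheeler / walking-only, and water as an
absolute barrier. The stacking priority is barrier > road > generic:
water is impassable to every mode, so a road crossing a water cell is
clipped rather than bridging it. Road rasterization is "all touched"
(every cell a segment passes through), because centre-sampling at 30 m
breaks network connectivity; where tiers cross in one cell the faster
tier wins.

A travel scenario maps each class to a mode and flat speed; the four
built-in scenarios (walking only; walking + motorcycle; walking +
public transport; walking + private vehicle) ship verbatim from the
published speed table, including its scenario-3 anomaly of 1.25 km/h on
major roads under public transport — slower than walking, almost
certainly a typographical slip. We reproduce the printed table as the
default because the engine's job is to run the published scenario, and
provide `scenario_table(3, corrected = TRUE)` (major roads at 40 km/h,
the major-road speed of the other motorized scenarios) clearly
labelled.

## Anisotropic travel time

Travel time is a multi-source shortest path over the 8-connected cell
graph. Three conventions are worth stating because cost-distance
engines differ and rarely document them:

* **Diagonal weighting**: centre-to-centre distance, `s` orthogonally
  and `s√2` diagonally, for cell size `s`.
* **Half-cell cost splitting**: the directed edge cost from cell *a* to
  *b* is `(d/2)/v_a + (d/2)/v_b` — half the distance at each cell's
  speed. This is symmetric in the isotropic case and converges to the
  line integral of `1/v` under grid refinement.
* **Direction of motion**: walking speed on a slope uses the Tobler
  hiking function `V = V_F · exp(−3.5·|S + 0.05|)` with
  `S = (elev(to) − elev(from))/d`, the dimensionless gradient
  experienced moving *toward* the facility. (One published statement of
  the formula gives S "in hundredth of percent"; taken literally that
  would divide gradients by 10,000 and make the correction numerically
  inert, so S is interpreted as the standard rise-over-run argument of
  the Tobler function.) Motorized cells use their flat speed
  unchanged — slope corrections are walking corrections.

Because S is signed by direction, the surface is anisotropic: the time
*toward* a facility differs from the time *from* it wherever the
terrain slopes. The implementation runs Dijkstra from the facilities
over reversed directed edges, so every path is costed in the patient's
direction of travel. On a flat landscape the two directions coincide,
which is one of the package's property tests. The solve itself is
delegated to igraph; the package authors the graph construction, and an
independent Bellman-Ford oracle re-derives small instances in the test
suite.

There is no maximum travel time in the surface computation (the full
extent is always computed); unreachable cells and barriers are NA.
Surfaces are classified into four incremental zones with closed upper
bounds — (0,1], (1,2], (2,3], (3,∞) hours — so a village at exactly
1.0 h counts as "within an hour".

## Coverage capacity and catchments

Coverage capacity converts staffing or bed stock into a maximum annual
service population:

* outpatient tiers (SC, PHC):
  `workers × patients/day × working days ÷ outpatient visits per capita`;
* bed-based tiers (CHC, DH):
  `beds × occupancy × working days ÷ (admittances per capita × average length of stay)`.

Catchments are grown facility-by-facility in descending capacity (ties
broken by facility id): the processing order is not specified by the
methodology this package implements, and largest-first minimizes order
artifacts on small landscapes; the order is a documented convention,
not a tunable result. Each facility's travel-time surface is computed
over the full landscape, and still-unclaimed cells within the maximum
travel time (1 h for ambulatory/immunization, 2 h for delivery and
inpatient care) are claimed in ascending time order — ties broken by
row then column — accumulating population until either the candidates
run out (`max_travel_time`) or the next cell would overflow the
capacity (`max_capacity`).

Two design points deserve emphasis. First, cells are claimed whole: the
marginal cell that would exceed capacity is left for other facilities,
so served ≤ capacity holds strictly and the accounting is conservative.
Second, earlier catchments do *not* act as travel barriers for later
facilities — patients may walk through another facility's catchment.
The alternative (treating claimed cells as temporary barriers) can
sever later facilities' only routes, and breaks the sanity property
that with unlimited capacity the coverage analysis must reduce exactly
to pure accessibility; with the chosen rule that reduction is exact and
is asserted in the tests.

Before any coverage analysis, population sitting on barrier cells
(an artifact of dasymetric population grids, typically around 1% of
the total) is moved to the nearest non-barrier cell — Euclidean
cell-centre distance, ties broken lexicographically by (row, column) —
conserving the total exactly. Served + unserved therefore equals the
corrected total to machine precision, and every cell belongs to at most
one catchment.

## Zonal statistics and the conflict scenario

Zones (medical blocks) are a categorical raster; cells belong to the
zone containing their centre, so zone sums partition district totals
exactly. Per zone the package reports total, served and percent-covered
population, and the Pearson correlation between travel-time thresholds
(default 1, 2, 3, 4 h, mirroring the four incremental zones — the
threshold set is configurable because no canonical set exists) and the
cumulative population reachable within each threshold. Cumulative
curves are non-decreasing, so the correlation is non-negative wherever
defined; a constant curve (e.g. an empty zone) is flagged undefined
rather than reported as a number.

The conflict scenario models access during active border hostilities:
motorized travel stops and walking is slower on every class, so the
walking-only scenario is transformed by halving all defined speeds
(barriers stay barriers). Because travel time is homogeneous of degree
−1 in speed, halving all speeds exactly doubles every finite travel
time — an end-to-end invariant in the test suite that validates both
the transform and the engine's linearity. Conflict summaries are
computed only over border-flagged villages and compared with the same
villages under the normal walking scenario.

## The synthetic district

No geodata from the motivating study is available, so the generator
builds a district with the *structure* the analysis assumes, at reduced
extent. The defaults are chosen once, on density grounds:

* 300 × 300 cells at 30 m (9 km × 9 km, 81 km²) — the 30 m resolution
  of the original analysis on a scaled-down extent;
* 14 facilities (9 SC, 3 PHC, 1 CHC, 1 DH), preserving the real
  system's roughly 6–9 km² per facility and its tier mix;
* delivery at 34/185 and inpatient at 28/185 of facilities — the
  published service-availability proportions — concentrated in the
  higher tiers;
* 23,000 people (≈285 persons/km², the district's census density),
  placed by a low-elevation/settlement-weighted dasymetric-style
  weighting, with 1.2% deliberately dropped on river cells to exercise
  the barrier-correction path;
* 60 villages sampled population-weighted, split into three blocks,
  with the westernmost 60% flagged as border villages;
* a braided river crossing the extent as a barrier, and a connected
  three-tier road tree lying entirely east of the river — the western
  border strip is deliberately road-free, so part of the district is
  unreachable by vehicle and some villages are fully cut off by the
  river.

The elevation model is a sum of smooth Gaussian ridges with a carved
valley (1000–2500 m), not fractal noise: smooth fields make
slope-dependent behaviour predictable in tests. What the generator does
*not* emulate: realistic hydrology or road-network geometry, seasonal
variation, the Random-Forest dasymetric estimator itself (only the
statistical character of its output), or travel-demand behaviour.
Passing tests on this landscape therefore validate the *method* —
conservation, monotonicity, oracle equivalence, the qualitative
ordering of scenarios and services — not any real district's numbers.

## Problem sizes and numerical choices

The test suite exercises the shortest-path engine against an exhaustive
Bellman-Ford oracle on 200+ random grids up to 6 × 6 (tolerance 1e−9
h), the speed-halving law end-to-end on a 200 × 200 landscape, and
monotonicity properties (more facilities, faster classes, longer time
limits, larger capacities never worsen outcomes) on 50 × 50 landscapes;
the full-pipeline checks run at the default 300 × 300 scale. Scenario
speeds are validated strictly (positive where defined, water
impassable, all 12 classes covered). Capacity comparisons use a 1e−9
absolute guard when testing whether a cell overflows capacity, so
binary-representation noise cannot flip a claim; population
conservation is exact because redistribution moves mass, never rescales
it.
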