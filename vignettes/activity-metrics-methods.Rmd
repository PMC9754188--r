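---
title: "Estimating green-space visitation from anonymized mobility tiles: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating green-space visitation from anonymized mobility tiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parkactivity)
```

## The problem

Commercial mobility products summarize smart-device presence as a unitless
"activity index" on a coarse spatial grid (here, 100 x 100 m cells), averaged
monthly within 2-hour windows and split into weekday/weekend strata. Before
delivery the vendor applies three privacy distortions: values below an
undisclosed threshold are *removed* (a quiet cell is absent, never zero), an
undisclosed amount of noise is added, and everything is normalized to a
country-level baseline. For a land manager, the question is whether such
tiles, after sensible preprocessing, still track real visitation well enough
to map human pressure across a portfolio of green spaces.

`parkactivity` implements that preprocessing and analysis chain, together
with a forward simulator of the whole measurement process, so that every
stage can be tested against a known ground truth without any proprietary
data.

## Core metrics

For a green space $g$ with area $A_g$ and retained tile records $k$ with
activity index $a_k$ on cells clipped to the property with areas $A_k$:

$$\mathrm{density}_g = \frac{\sum_k a_k\,A_k}{A_g}, \qquad
  \mathrm{coverage}_g = 100\,\frac{\left|\bigcup_{\text{cells}} A_{\text{clip}}\right|}{A_g}.$$

Two details matter.

* The index describes the *full* cell even when the cell is clipped to a
  sliver of the property, so each record is weighted by its clipped area,
  not re-scaled.
* Density uses a **sum**, not a mean, over records. Because sub-threshold
  records are absent, the record count itself carries signal; a mean over
  surviving records would be biased upward exactly where activity is low.
  A consequence used by the tests:
  `density(all) = density(weekday) + density(weekend)`.

Coverage counts each distinct cell once, however many records it has, via an
exact union of the clipped cell polygons.

### Overnight exclusion

Roads and commercial areas adjacent to property boundaries contaminate
boundary cells with non-visitor activity. Parks are closed or near-empty
between midnight and 06:00 while roads stay active, so any cell with at
least one record in the windows starting 0, 2 or 4 h is excluded from *all*
metrics, at all hours and months (windows are half-open, `[0,2), [2,4),
[4,6)`). The exclusion is cell-global by design: a contaminated sensor cell
is untrustworthy in every window. Exclusion happens before both density and
coverage so the two metrics describe the same retained cell set.

### Trails and land cover

Trail density is clipped trail length over property area (reported in
km/km^2 — the field has no standard unit here; this one makes the numbers
O(1)). The on-trail percentage is the union area of retained activity cells
that intersect the trail network (buffer 0 m by default, monotone buffer
exposed for sensitivity analysis), over all retained activity area; it is
`NA`, never 0, when a property has no activity area. Land-cover usage
apportions the retained activity area among ELC-CC (Ecological Land
Classification Community Class) polygons by geometric intersection and
reports both the share of activity in each class (sums to 1 over a
partition) and the used fraction of each class.

## Statistical layer

**Reservation validation.** Per-property, per-stratum visitor totals from a
reservation system are regressed against the corresponding activity density
with day type (weekday/weekend) as an interacting factor, by OLS with
sequential (type-I) ANOVA — the convention that produces the
single-degree-of-freedom F statistics usually reported for this design.
Type-II users should refit from `$fit`.

**Composition analysis.** A partial canonical correspondence analysis
relates a site x species matrix of mean basal areas to three standardized
activity predictors (density averaged over the two strata, coverage, and the
weekend proportion = weekend density / weekday density), conditioning on
survey year. The implementation is explicit: chi-square standardization
$Q = (P - rc^\top)/\sqrt{rc^\top}$, row-mass-weighted centering of the
predictors, residualization of both $Q$ and $X$ on the conditioning
variables, and an SVD of the weighted projection of $Q$ onto the
residualized constraint space. The inertia decomposition
(conditioned + constrained + residual = total) is exact and tested to 1e-8,
and the engine is verified against both a dense projection-matrix /
generalized-eigen oracle and `vegan::cca`.

Because "variance explained" is ambiguous in partial ordination, the result
reports all three fractions explicitly — constrained/total,
constrained/(total − conditioned), and an Ezekiel-adjusted
$R^2_{adj} = 1 - (1 - R^2)\,(n-1)/(n-1-q-p_z)$ on the first fraction —
rather than a single unlabeled number.

Significance uses free permutation of the constraint rows with the
condition held fixed, re-residualizing each draw, with
$p = (1 + \#\{F^\pi \ge F\})/(1 + n_\pi)$. Residualized-response schemes and
site blocking are not implemented; the free scheme is the common default and
its null calibration is verified by simulation (empirical p-values uniform,
Kolmogorov–Smirnov check). Eigenvectors are sign-ambiguous, so each
constrained axis is oriented to correlate nonnegatively with the first
constraint variable.

A convenience check, `cca_year_check()`, fits a plain CCA on year alone —
the usual argument for treating tree composition as stable across survey
years before conditioning on year.

## The synthetic world

The generator emulates the *structure* of the real data, not its provenance:

* **Landscape**: convex property polygons (rectangles, optionally one cut
  corner) deliberately offset from the grid so boundary cells clip to
  partial areas; a recursive-split partition into convex ELC-CC units (unit
  areas sum exactly to the property area); trail polylines through random
  interior points (inside by convexity); a road along one boundary edge of
  most properties.
* **Truth**: cell intensity = baseline x trail multiplier x class
  multiplier x stratum multiplier in daytime windows, zero overnight; road
  cells add a constant road term in every window. Defaults (baseline 1,
  trail x3, weekend x1.3, road 6, class multipliers 0.3–1.8) encode the
  qualitative findings for summer park use: activity concentrated on
  trails, rock/recreational classes over-used, wetlands under-used, roads
  far busier than park interiors around the clock.
* **Anonymization**: zero-mean Gaussian noise truncated at zero, then
  suppression below a threshold tau, then division by a scalar baseline
  (stand-in for the country-level normalization, which is irreproducible).
  The vendor's threshold and noise magnitude are unpublished, so both are
  free parameters; the default tau = 0.5 (half a baseline cell) suppresses
  the quietest land-cover classes, producing realistic sub-100% coverage,
  and noise defaults to 0 so that exactness tests are exact.
* **Calendar**: every month has 22 weekdays and 8 weekend days, so stratum
  means are deterministic; three months are simulated (a summer season).
* **Consistency**: daily visitor counts per reservation-managed property
  are Poisson with mean proportional to the property's daytime intensity
  for that day's stratum; reservations partition each day's count exactly
  into parties; tree surveys make log mean basal area linear in the
  standardized property activity.

What a green test does and does not establish: the simulator produces
intensity *surfaces*, not device trajectories — the vendor's five-minute
aggregation, trip-end discarding and machine-learned threshold/noise are
replaced by parametric stand-ins. Tests therefore establish correctness of
the analysis pipeline and recoverability under the stated distortion model,
not fidelity of any particular vendor's pipeline.

Two generator subtleties discovered in testing, now part of the design:

* A species-uniform year effect multiplies whole rows of the survey table
  and cancels exactly in correspondence analysis, so `year_loading` acts
  with alternating sign across species — it perturbs composition, which is
  what an interannual check must detect.
* Correspondence analysis sees each species *relative to the
  abundance-weighted mean* response, so the default intercepts pair equal
  abundances with the +/- loading pairs, centering the weighted mean
  loading at ~0; only then is "species score sign = generating loading
  sign" a fair recovery criterion.

## Numerical choices

* All geometry is planar Cartesian meters (areas and lengths are all the
  metrics need) and all polygons are **convex**, which the generator
  guarantees and the clipping (Sutherland–Hodgman), trail clipping
  (Cyrus–Beck) and union-area (vertical slab decomposition over vertex and
  edge-crossing abscissae) routines exploit to be exact to floating point.
  Non-convex inputs to `green_space()` are rejected, or replaced by their
  convex hull with `repair = "hull"`.
* Zero-area (boundary-touching) intersections count as no intersection:
  area-weighted metrics give them no weight.
* Cells straddling two properties contribute to each, with the full-cell
  index weighted by each property's clipped area.
* Undefined ratios (on-trail percent with no activity; used fraction of a
  zero-area class; weekend proportion with zero weekday density) are
  explicit `NA`s or errors, never silent zeros.
* Every stochastic stage takes an explicit seed; the pipeline derives
  per-stage seeds from the single config seed, and reruns are byte-identical
  (output files carry no timestamps; the manifest hashes the scientific
  config, not the output path).

## Validation design

The validation criterion for the reservation analog correlates a per-area
density with a per-property visitor *total*. These are only on comparable
scales when property areas are similar — with a 4-fold area spread the two
decorrelate by construction even for a perfect instrument. The validation
fixture therefore uses near-uniform property sizes, mirroring the
similar-sized flagship parks that reservation systems are typically deployed
on; measurement fidelity itself is checked separately (property intensity
vs. visitor truth, r > 0.99 after road exclusion in the diagnostics that
motivated this design).

## Known limitations

* Geometry is restricted to convex polygons; real cadastral parcels are
  not convex. Scoping to convexity is what makes a dependency-free exact
  implementation feasible; swapping in a full geometry engine behind
  `clip_cells()`/`union_area()` would lift the restriction without touching
  the metrics.
* The overnight filter is all-or-nothing per cell; a per-record variant
  would retain more data at the cost of the contamination argument.
* The permutation test permutes rows freely; if sites were sampled in
  blocks, exchangeability is only approximate.
* The activity index is relative: densities are comparable across
  properties within one dataset, not across vendors or years.
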