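# parkactivity

Estimating human activity in managed green spaces from anonymized,
grid-aggregated smart-device mobility tiles.

## The problem

Mobility-data vendors sell a unitless "activity index" — device presence
aggregated to 100 × 100 m grid cells, averaged monthly within 2-hour
windows, split into weekday/weekend strata — with three privacy
distortions applied: sub-threshold records are *removed* (absent, never
zero), noise is added, and values are normalized to a country-level
baseline. `parkactivity` turns such tiles into per-property visitation
metrics for portfolios of parks, conservation areas and reserves, and
relates them to trails, land cover, reservation records and tree community
composition. Because real tiles are proprietary, the package includes a
forward simulator of the entire measurement process (landscape →
ground-truth intensity → anonymized tiles, plus consistent reservation and
tree-survey tables), so every stage is testable against known truth.

## What it computes

For a green space $g$ with area $A_g$, retained records $k$ with index
$a_k$ on cells clipped to the property with areas $A_k$:

- **activity density** $= \sum_k a_k A_k / A_g$ — an area-weighted *sum*
  (not a mean: absent sub-threshold records carry signal);
- **activity coverage** $= 100\,|\bigcup \text{activity cells}| / A_g$ —
  percent of the property showing any activity, each cell counted once;
- **overnight exclusion** — any cell with activity in the 00:00–06:00
  windows is dropped everywhere (roads stay active overnight; parks do
  not), removing boundary road contamination;
- **trail density** (km/km²) and **on-trail percentage** of the activity
  area; **land-cover usage** fractions per ELC-CC class;
- **reservation validation** — OLS of visitor totals vs. density with an
  interacting day-of-week factor, sequential ANOVA;
- **partial CCA** — tree composition (site × species mean basal area)
  constrained on standardized activity predictors, conditioned on survey
  year, with a permutation test of the pseudo-F; implemented from scratch
  and verified against a dense-matrix oracle and `vegan`.

## Worked example

```r
library(parkactivity)

ls  <- generate_landscape(landscape_config(n_properties = 4), seed = 42)
tr  <- simulate_visitation(ls, visitation_params(), seed = 42)
tiles <- render_activity_tiles(tr, anonymization_params())

gs     <- ls$green_spaces[[3]]
trails <- Filter(function(t) t$property_id == gs$id, ls$trails)
summarize_activity(tiles, gs, trails)[1, ]
#>   property_id day_stratum activity_density activity_coverage_pct trail_density
#> 1        gs03         all              105                 92.12         3.112
#>   on_trail_pct n_cells_retained n_cells_excluded
#> 1        37.93               67               10
```

Reading: property `gs03` has 3.1 km of trail per km²; 10 boundary cells
were excluded for overnight (road) activity; 92.1% of its area shows some
human activity, 37.9% of that activity area lies on the trail network, and
the area-weighted activity sum per unit property area is 105 (unitless —
the index supports relative comparisons only).

Composition analysis on the matching synthetic tree surveys:

```r
surv  <- generate_tree_surveys(ls, tr, species_response(), seed = 42)
parts <- parkactivity:::split_survey_table(surv)
z     <- attr(surv, "activity_z")
fit   <- pcca(parts$Y, cbind(act = z[parts$meta$site_id]),
              cbind(year = as.numeric(parts$meta$year)))
fit
#> Partial canonical correspondence analysis
#> total inertia 0.2118 = conditioned 0.0010 + constrained 0.2020 + residual 0.0088
#> constrained axes: 1; pseudo-F = 207.585 (df 1, 9)
#> constrained/total = 0.954; constrained/(total-conditioned) = 0.958; adj R^2 = 0.944
```

(The constrained fraction is large because the synthetic species were
generated with strong activity loadings and little noise.)

End-to-end, from a YAML config (`seed` and `output_dir` mandatory):

```r
run_pipeline(list(seed = 7, output_dir = "out",
                  landscape = list(n_properties = 8), n_perm = 999))
```

writes `tiles.csv`, GeoJSON layers, `activity_summary.csv`,
`landcover_usage.csv`, reservation/trail model tables, `cca_summary.csv`
and a `manifest.json` (config hash, per-stage record counts); reruns with
the same config are byte-identical. The same pipeline runs from the shell:

```sh
exec/parkactivity all --config run.yaml
```

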