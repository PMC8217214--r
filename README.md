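# stormcross

Tools for quantifying how the trans-oceanic migrations of satellite-tagged
birds interact with Atlantic tropical cyclones. The motivating system is
whimbrel (*Numenius phaeopus hudsonicus*): two North American breeding
populations cross the Atlantic each autumn at the peak of hurricane season
on very different routes — a long nonstop flight far out to sea versus a
shorter passage through the Caribbean "hurricane alley" — and the package
measures what each route costs in storm exposure and storm encounters.

It is written for movement ecologists with ARGOS/Movebank-style telemetry
and NOAA best-track data who want a reproducible, testable version of this
analysis rather than a one-off GIS workflow.

## What it computes

* **Tracks** — ARGOS telemetry ingest with location-class filtering (LC 1–3),
  residency/staging/trans-oceanic segmentation, and per-journey summaries:
  departure and arrival dates, total distance, duration, rate of advance
  (km/day), ocean-crossing length, duration and departure latitude. When a
  coastline crossing falls inside a transmitter duty-cycle gap, the
  crossing instant is interpolated at the mean flight speed
  (v̄ = 14.8 m/s): t = t_fix ± d/v̄, with d the great-circle distance from
  the fix to the boundary.
* **Cyclone climatology** — HURDAT2 parsing/writing, season and status
  filtering (15 Jul–30 Nov, ≥ TD, synoptic points only so storms are
  weighted by lifespan), a Gaussian kernel density surface fitted on an
  equal-area projection, and its 50% highest-density region
  HDR(α) = {x : f̂(x) ≥ t_α}, the smallest region holding mass α.
  Per-journey exposure is the time inside the HDR polygons, entry/exit
  interpolated by the same fixed-speed rule.
* **Encounters** — spatiotemporal bird × storm intersection on a shared
  30-min interpolation grid (default radius 300 km in flight, 100 km for
  grounded birds), Saffir–Simpson intensity at encounter
  (TD ≤ 38, TS 39–73, C1 74–95, C2 96–110, C3 111–129, C4 130–156,
  C5 ≥ 157 mph), and a none / detour (> 20° deflection) / grounding
  response classification.
* **Inference** — two-sample t-tests from published summary statistics
  (pooled: t = (x̄₁−x̄₂)/(s_p√(1/n₁+1/n₂)), df = n₁+n₂−2), G-tests with
  Yates continuity correction (G = 2 Σ O′ log(O′/E), df = 1), and a
  random-intercept logistic regression
  logit P(encounter) = Xβ + u_year, u ~ N(0, σ²), fitted by adaptive
  Gauss–Hermite quadrature with singular-fit detection and AICc ranking.
* **Synthetic scenarios** — a generator that emulates both input formats
  with known ground truth (route archetypes per population, a minimal
  storm-basin model, and planted bird-storm encounters at requested
  separations), so the whole pipeline is testable without any downloads.

## Worked example

Reproduce the published migration-distance contrast from its printed
summary statistics (mean ± SE, n):

```r
library(stormcross)
t_test_from_summary(group_summary(11012, 72.4, 14),
                    group_summary(8404, 76.0, 13))
#> Two-sample t-test from summaries (pooled): statistic = 24.86, df = 25, p = 3.795e-19
```

Classify best-track winds (knots) on the Saffir–Simpson scale:

```r
saffir_simpson_category(knots_to_mph(c(30, 55, 80, 120, 140)))
#> [1] "TD" "TS" "C1" "C4" "C5"
```

Run the full pipeline on the default synthetic scenario (24 birds in two
populations, a 96-storm basin, planted encounters):

```r
cfg <- run_config(scenario = scenario_config(seed = 1), seed = 1)
bundle <- run_pipeline(cfg, quiet = TRUE)
bundle
#> stormcross results bundle
#>   journeys: 24 (HudsonBay: 11, MackenzieDelta: 13)
#>   encounters: 11 (11 in flight, 0 grounded)
#>   risk region: 1 polygon(s), mass 0.50
bundle$rates
#>       population n_crossings n_with_encounter pct_with_encounter ...
#> 1      HudsonBay          11                7                 64
#> 2 MackenzieDelta          13                2                 15
aggregate(total_days ~ population, bundle$exposure, function(x) round(mean(x), 2))
#>       population total_days
#> 1      HudsonBay       1.21
#> 2 MackenzieDelta       0.37
```

The Hudson Bay cohort crosses through the storm core (64% of crossings meet
a storm; 1.21 days of exposure per crossing) while the Mackenzie Delta
cohort flies around it (15%; 0.37 days) — the qualitative contrast the
real tracking study reports. `bundle$statistics` carries the t-tests, the
Yates-corrected G-test on the encounter table, and the mixed-effects
logistic regression; `bundle$model_ranking` is the AICc table; and
`report_results(bundle)` renders everything as markdown.

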