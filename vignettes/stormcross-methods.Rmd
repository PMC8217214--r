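---
title: "Methods: migratory tracks, cyclone climatology and storm encounters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: migratory tracks, cyclone climatology and storm encounters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stormcross)
```

## The analysis

`stormcross` implements a complete pipeline for asking how the autumn
trans-Atlantic routes of satellite-tagged shorebirds (the motivating system
is whimbrel, *Numenius phaeopus hudsonicus*, from the Mackenzie Delta and
Hudson Bay breeding populations) interact with Atlantic tropical cyclones.
The pipeline has five analytical layers:

1. **Ingest and quality control.** ARGOS-style telemetry tables are read
   into per-bird tracks; only Doppler location classes 1–3 (nominal accuracy
   better than 1 km) are retained, duplicate timestamps are collapsed
   keeping the best class, and NOAA HURDAT2 best-track files are parsed into
   six-hourly storm records (west longitudes negative, the `-99` wind
   sentinel mapped to `NA`).
2. **Journey segmentation.** Each annual track is cut into breeding
   residency, staging, trans-oceanic flight and winter residency. Residency
   is operationalized as a maximal interval in which every fix stays within
   50 km of the interval's running centroid for at least 7 days. Neither
   threshold is dictated by the data source; 50 km exceeds class-1 ARGOS
   error by a wide margin and 7 days separates multi-day staging from
   transit. Both are configuration parameters.
3. **Cyclone climatology.** Season- and status-filtered storm records
   (15 July–30 November, tropical depression or stronger, synoptic
   00/06/12/18 UTC points only so each record carries equal lifespan
   weight) are pooled into a weighted point set, projected to an equal-area
   plane, and smoothed with a Gaussian product kernel. The 50%
   highest-density region (HDR) of that surface is the "core cyclone area";
   a journey's exposure is its time inside the HDR polygons.
4. **Encounters.** A bird and a storm "intersect during the same time
   period" when their positions, interpolated to a shared 30-minute grid,
   come within the encounter radius; one encounter is scored per contiguous
   approach, at minimum separation. Grounded birds are scored against the
   storm centre's distance to the stationary-phase centroid. Intensity at
   encounter uses the Saffir–Simpson mph bands (knots × 1.15078). The
   response taxonomy is none / detour (> 20° course deflection between the
   24 h pre-window and the 48 h post-window) / grounding (a stationary
   interval starting within the post-window on an island polygon);
   grounding supersedes detour.
5. **Inference.** Two-sample t-tests reconstructed from group summary
   statistics, G-tests with Yates continuity correction, and a
   random-intercept logistic regression (encounter outcome ~ population,
   with journey year as the random intercept) fitted by adaptive
   Gauss–Hermite quadrature, with AICc model ranking.

## Key parameters

| parameter | default | units | rationale |
|---|---|---|---|
| Earth radius | 6371.0088 | km | IUGG mean radius; haversine distances |
| mean flight speed | 14.8 | m/s | cross-population mean speed between in-flight fixes; converts a distance-to-boundary into a time offset |
| residency radius / dwell | 50 / 7 | km / days | see above; configurable |
| season window | 15 Jul – 30 Nov | month-day | cyclone season overlapping migration; compared as month-day within each year, avoiding leap-day arithmetic |
| year range | 1961–2018 | years | satellite-era best tracks |
| HDR mass | 0.5 | fraction | the "core occurrence" level |
| KDE cell | 25 | km | basin-scale resolution; tests use finer grids |
| encounter radius | 300 | km | typical gale-force wind-field extent; the track archives give no printed threshold, so this is a first-class setting with a built-in 50–500 km sensitivity sweep |
| grounded radius | 100 | km | "storm moved over" a stationary bird |
| sync step | 30 | min | finer grids are spurious against multi-hour duty cycles |
| detour angle / windows | 20° / 24 h pre, 48 h post | — | "deflected by > 20°" over "the previous day", "shortly following" |
| quadrature nodes | 25 | — | log-likelihood changes < 1e-6 between 20 and 50 nodes on test fixtures |

## Numerical choices

**Geometry.** All distances are spherical haversine; "straight line" always
means the great-circle segment. Interpolation between fixes is spherical
(slerp via destination-point construction), so longitude arithmetic never
crosses the antimeridian incorrectly. Boundary crossings are located by a
dense scan (256 samples) plus 40 bisection steps along the segment, i.e. to
about a metre.

**Crossing-time convention.** When consecutive fixes straddle a boundary,
the crossing instant is the anchor fix's time offset by
(distance to boundary)/(14.8 m/s). For region exposure the anchor is the
earlier fix (the last one on the old side); for coastline crossings the
anchor is the in-flight fix, matching the field procedure of measuring from
the first/last over-water point. At exactly the nominal speed the two
conventions coincide. The offset is clamped into the fix gap with a warning
when the rule would overshoot; linear-in-time interpolation is available as
a configuration switch.

**Projection and KDE.** Kernel densities are fitted after a spherical
Lambert azimuthal equal-area projection centred at 25° N, 60° W (implemented
in-package from the closed-form spherical equations), so a fixed kernel
bandwidth represents the same ground area everywhere; an unprojected
lon/lat mode is provided for comparison but not asserted to reproduce any
published surface. The KDE itself is `MASS::kde2d` (product Gaussian
kernel) behind the module surface, renormalized so the grid integrates to
exactly 1. Bandwidth selectors: `nrd` (bivariate normal-reference,
`sd * n^(-1/6)` per axis — the fast default), `scv` (smoothed
cross-validation for a diagonal bandwidth, minimized numerically with a
normal-reference pilot; evaluated on a capped subsample of 1500 points
because the criterion is O(n²)), and `fixed` (used by the tests, which pin
the bandwidth for determinism). The HDR threshold is the largest density
level whose superlevel set holds the requested mass, computed exactly on
the grid (no contour interpolation); polygons are traced with
`contourLines` and inverse-projected.

**Mixed logit.** The marginal likelihood integrates the group intercepts
by adaptive Gauss–Hermite quadrature: per group, a Newton search finds the
conditional mode, the quadrature is recentred and rescaled there, and
nodes/weights come from the Golub–Welsch eigendecomposition. Likelihoods
use `plogis(log.p = TRUE)` throughout to avoid catastrophic underflow.
After optimization the zero-variance boundary fit is always computed; if it
is (numerically) as good, the model is declared singular and the boundary
fit reported — this mirrors the behaviour that led the field analysis to
drop a bird-identity intercept. Standard errors are the fixed-effect block
of the inverse observed information over (β, log σ); on fixtures the
estimates, likelihood and standard errors agree with `lme4::glmer`
(`nAGQ = 25`) to better than 1e-3, and `lme4` serves as the independent
cross-check in the test suite, never as the implementation.

**Yates correction.** Each observed count moves 0.5 toward its expectation
but never past it, so adjusted counts stay positive and the corrected G
statistic never exceeds the uncorrected one away from independence. The
summary t-test defaults to the pooled variant because the published degrees
of freedom (n₁ + n₂ − 2) indicate pooling; Welch is a flag.

**Tie-breaks and degenerate inputs.** Duplicate telemetry timestamps keep
the numerically best location class, first occurrence on ties. An
all-filtered track carries an `empty_track` flag that downstream stages
reject. Collinear storm points are a named KDE error; a track wholly
outside the risk region has zero exposure (not an error); a coincident-point
bearing is an error.

## The synthetic scenario generator

Real deployments cannot be redistributed, so the generator builds inputs
with known truth in exactly the formats the ingest layer consumes. Its
defaults encode the study conditions: cohorts of 13 (Mackenzie Delta) and
11 (Hudson Bay) birds; ocean crossings of 5440 ± 434 km over 6.1 ± 0.65
days from ~47.5° N versus 3643 ± 651 km over 4.5 ± 0.96 days from ~37.0° N
(SDs recovered from the printed standard errors, SD = SE·√n); total
migration distances 11,012 versus 8,404 km; transmitter duty cycles of
48 h off/10 h on and 24 h off/5 h on with class-dependent Gaussian position
noise using the ARGOS class accuracy bounds as 1-σ values.

Routes are smooth spherical quadratic Bézier polylines between a breeding
site, an inland dogleg (solved so the drawn total distance is honoured), a
staging site 150 km inland of the coast, a coast-exit point placed exactly
on the synthetic coastline at the drawn departure latitude, a mid-ocean
bulge (solved so the drawn over-water length is honoured) and the winter
site. Continents are two synthetic polygons whose facing edges play the
two coasts; five convex polygons stand in for the Antilles so grounding
logic is testable without shoreline data.

The storm model is deliberately minimal — genesis in an eastern tropical
box, brisk westward drift at low latitude, slower poleward translation west
of 60° W, Bernoulli recurvature to the northeast, and a bounded random walk
in sustained wind spanning TD–C5 — it exists to exercise parsing, density
estimation, classification and intersection, not to be meteorologically
faithful. Its one structural claim matches the basin: point density (and
hence the 50% HDR) concentrates in the west, on the Hudson Bay route and
away from the Mackenzie Delta route, which reproduces the qualitative
exposure and encounter-rate contrasts. Planted encounters locally warp a
storm track (taper ±36 h) so the centre passes at a requested separation
from the interpolated bird position at a requested instant, to within 1 km
in memory; note that HURDAT2 serialization quantizes coordinates to 0.1°,
so a planted separation re-measured after a write/parse round trip can move
by a few kilometres.

What passing tests on these data do **not** show: robustness to real ARGOS
error structure (heavy-tailed, class-misassigned fixes), to wind-drifted
curved flight paths, to real coastline complexity, or to the actual
HURDAT2 snapshot's climatology. The generator's fixes lie exactly on the
route polyline between noise draws, so segmentation results here are upper
bounds on real-data performance.

## Known limitations

* Flight lengths summed over sparse fixes underestimate the true path
  (corner-cutting across duty-cycle gaps); on default cohorts the bias is
  ~1–3%. The field procedure shares this property.
* Crossing times interpolated at the global 14.8 m/s speed are biased for
  birds whose actual speed differs; per-journey duration errors are
  bounded by the duty-cycle gap (up to ~2 days), with cohort means
  recovered much more tightly.
* Exposure can miss a region crossing entirely when no fix lands inside a
  narrow region arm (possible under 48-h duty cycles); entry/exit
  interpolation requires at least one inside fix per interval.
* The 50% HDR depends on the bandwidth selector; the published polygon
  cannot be reproduced without the exact storm snapshot and selector, so
  region-dependent numbers are compared qualitatively, not to printed
  values.
* The G statistic printed in the motivating study (18.3 on 1 df) is not
  recoverable from either printed contingency table under standard G-test
  formulae with or without continuity correction (the implementation and
  its independent brute-force oracle agree on ≈ 11.4); the implementation
  is validated against its oracle only.

## Problem sizes in the test suite

The suite runs the full pipeline on 6-bird/36-storm scenarios, cohort
recovery on the 24-bird default scenario, KDE closed-form checks at the
full 17,637-point scale, planted-encounter recovery on a 20-bird ×
30-storm basin, and mixed-logit parameter recovery over 200 replicates of
a 30-group × 10-observation design; these sizes were chosen so each
property is measured well inside its Monte-Carlo error.
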