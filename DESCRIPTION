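Package: stormcross
Title: Shorebird Migration Tracks and Tropical-Cyclone Encounter Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing interactions between satellite-tracked
    migratory shorebirds and Atlantic tropical cyclones. Reads ARGOS-style
    telemetry tables and NOAA HURDAT2 best-track files, segments annual
    tracks into residency, staging and trans-oceanic flight phases, builds a
    seasonal cyclone-density surface (Gaussian kernel density estimate) and
    its highest-density risk region, measures per-journey exposure time
    inside the region with fixed-speed boundary interpolation, detects and
    classifies bird-storm encounters (in flight and while grounded, with
    Saffir-Simpson intensity classes and none/detour/grounding responses),
    and provides the inferential layer: summary-statistic t-tests, G-tests
    with Yates correction, random-intercept logistic regression fitted by
    adaptive Gauss-Hermite quadrature, and AICc model ranking. A synthetic
    scenario generator produces telemetry and HURDAT2 files with planted,
    known-truth encounters so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    geosphere,
    MASS,
    mgcv,
    grDevices,
    stats,
    utils,
    tools,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
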