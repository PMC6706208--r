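Package: canopylight
Title: Below-Canopy Light Regimes from Airborne Laser Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Synthesizes hemispherical sky-obstruction images from classified
    airborne laser scanning (ALS) point clouds and a digital terrain model,
    mimicking upward-looking fisheye photographs with an equiangular
    projection, distance-scaled point markers, macro-terrain horizon masking
    and micro-terrain ground returns. From these images it derives three
    point-based light metrics: a diffuse light index under the standard
    overcast sky (SOC) model, a direct (beam) light index from growing-season
    sun tracking with altitude-corrected air mass, and canopy closure as the
    solid-angle obscured fraction of the sky vault. An area-based canopy cover
    metric is computed from height-normalized first returns. Plot-level
    aggregation (grid-of-cameras sampling, log-scale summaries) feeds a
    community-analysis layer: abundance-weighted light indicator values,
    Simpson turnover dissimilarity, distance-based redundancy analysis and
    adjusted R-squared variation partitioning across predictor groups. A
    synthetic forest generator (terrain, conifer stands, plant communities
    along a light gradient) makes the whole pipeline testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RANN,
    vegan,
    jsonlite,
    png,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
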