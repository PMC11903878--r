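Package: turcorg
Title: Spatial Organization and Conformational Analysis of gamma-TuRCs at
    Centrosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of gamma-tubulin ring complex (gamma-TuRC)
    organization at human centrosomes from oriented subtomogram particle
    tables and MINFLUX localization recordings. Provides quaternion and
    rigid-body geometry utilities, signed distance-pool statistics against
    microtubule-triplet B-tubule centerlines, 7-dimensional pose-pair
    clustering of gamma-TuRC-MTT configurations, MINFLUX trace filtering
    with cylinder-axis fitting and radial profiling, per-spoke ring-geometry
    deviation analysis against a closed microtubule-capping reference, and
    synthetic-data generators with planted, recoverable geometry for
    validating every stage offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    bio3d,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
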