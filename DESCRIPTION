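Package: enoseLOD
Title: Detection and Quantification Limits for Electronic-Nose Sensor Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates limits of detection (LOD) and quantification (LOQ) for
    volatile compounds measured with multi-sensor electronic noses. The
    first-order sensor-array response is reduced to a univariate surrogate
    signal (first principal component scores, or concentrations predicted by
    principal component regression or partial least squares regression) so
    that classical blank-based and calibration-curve detection-limit theory
    applies, including Student-t k-factors, leverage-corrected calibration
    uncertainty, an intercept-adjusted LOD, a coefficient-vector method and a
    mean-relative-error change-point method. Includes readers for day-level
    sensor recordings, drift-corrected feature extraction against an
    analyte-free reference, a synthetic study generator with Monte-Carlo
    detection-limit oracles, and a feasibility report against odor-threshold
    reference data for beer volatiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    mixOmics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'k-factor.R'
    'univariate-limits.R'
    'sensor-io.R'
    'feature-extraction.R'
    'surrogate.R'
    'synthetic.R'
    'pipeline.R'
    'feasibility.R'
    'show-methods.R'
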