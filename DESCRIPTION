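Package: flagellaR
Title: Quantitative Analysis of Planar Flagellar Beat Patterns
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the planar beating of eukaryotic flagella
    from digitized midline coordinates. Captured tracks are normalized onto a
    common arclength-by-time grid (beat-period detection by autocorrelation,
    spatial rescaling by flagellum length, single-beat truncation and phase
    alignment), converted between Cartesian and tangent-angle parametrizations,
    and decomposed by population-level principal component analysis so that
    mode coefficients are comparable across swimmers. Includes the maximal
    distal curvature summary statistic, sinusoidal linear-model fits of mode
    coefficients with two-sample Kolmogorov-Smirnov and Wilcoxon rank-sum
    decision procedures, evidence-based synthetic waveform generation that
    preserves the pointwise mean and variance of an empirical dataset, and a
    simulator of flagellate populations with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils-numeric.R'
    'AllClasses.R'
    'AllGenerics.R'
    'geometry.R'
    'preprocess.R'
    'popmodes.R'
    'stats.R'
    'synth.R'
    'simdata.R'
    'io.R'
    'cli.R'
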