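Package: clotmetrics
Title: Quantitative Analysis of Fibrin Clot Formation, Lysis and Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for the quantitative characterization of fibrin clots:
    turbidimetric clot-waveform metrics (maximal turbidity, CT50/CT90
    clotting times, LT50 lysis time with intrinsic or extrinsic time
    origins), Darcy-constant permeability from throughput readings,
    oscillation-rheometry plateau moduli and gel-fluid transition
    detection (maximal bearable strain and critical shear stress), fibrin
    fiber-diameter morphometry from grayscale electron micrographs via
    skeleton and distance-transform analysis, distribution-comparison
    statistics (Kuiper's test with Monte Carlo calibration and the
    two-sample Kolmogorov-Smirnov test), and censored fibrinogen
    clottability time courses.  Seeded synthetic-data generators emulate
    all five measurement modalities with known ground truth, so every
    analysis stage has a parameter-recovery test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    MASS,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
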