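Package: laametrics
Title: Morphometry and In Silico Haemodynamics of the Left Atrial Appendage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint morpho-haemodynamic characterisation of the left atrial
    appendage (LAA) for thrombogenic risk assessment. Computes ostium and
    appendage morphometrics (diameters, area, perimeter, eccentricity,
    centreline length, tortuosity, bending) from triangulated surface meshes;
    wall-shear-stress derived indices (TAWSS, OSI, ECAP, RRT), volume-
    normalised velocity and washout-based flow stagnation from time-resolved
    wall and flow series; and the cohort-level statistical stage (univariate
    group tests with automatic test selection, min-max normalisation,
    stepwise-AIC logistic modelling and random-forest importance). Includes a
    calibrated synthetic cohort generator that emits meshes, wall fields and
    flow traces with known ground truth so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    randomForest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
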