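Package: footmorph
Title: Geometric Morphometrics of Three-Dimensional Foot Shape
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Statistical shape analysis of triangulated 3D foot scans.
    Reads and writes surface meshes (OBJ, PLY, STL) with per-vertex scalar
    maps, preprocesses scans (mirroring of left feet, cropping above the
    ankle, plantar-surface foot measurements), establishes dense anatomical
    correspondence by elastic registration of a template mesh with an
    increasing-elasticity schedule, superimposes corresponded shapes by
    Generalized Procrustes Analysis, fits principal-component point
    distribution models, and relates subject factors (sex, age, shoe size,
    BMI, sport activity, foot loading, foot side) to shape through
    multivariate linear regression with BIC forward selection of
    components, post-hoc power analysis, per-vertex bilateral-asymmetry and
    loading measures, and model-predicted shape-difference maps.  Includes
    a synthetic foot-cohort generator with known ground truth (deformation
    modes, factor effects, correspondences) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
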