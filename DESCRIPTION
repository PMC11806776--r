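Package: prosomorph
Title: Geometric Morphometrics of Replicated 2-D Landmark Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Landmark-based geometric morphometrics for two-dimensional
    configurations digitized in replicate, organised as a pipe-friendly
    toolkit: TPS (tpsDig dialect) input/output, generalized Procrustes
    superimposition with tangent-space projection, centroid-size statistics,
    hierarchical Procrustes ANOVA for imaging and digitizing error with a
    Pillai's-trace cross-check, principal component analysis of shape with
    MANOVA on retained scores, two-group discriminant and multi-group
    canonical variate analysis with Mahalanobis and Procrustes distances,
    permutation tests and jackknife cross-validated classification,
    multivariate regression of shape on log centroid size with a
    common-slopes MANCOVA, thin-plate-spline deformation grids and wireframe
    displays, and a synthetic landmark-data generator that emulates a
    two-population by two-sex study design with replicated photography and
    digitization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
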