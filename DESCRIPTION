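Package: airwaymorph
Title: Synthesis and Morphometry of Monopodial Airway Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the branching geometry of monopodial
    (pig-like) bronchial trees. Provides a parametric generator of
    synthetic airway trees with a tracheal bronchus, asymmetric
    bifurcations whose daughter/parent diameter ratios and angles depend
    on the rotation of the bifurcating plane, transition zones and
    rounded flow dividers; CT-like binary voxelization and STL surface
    export; centreline extraction from binary lumen masks via 3-D
    homotopic thinning and Euclidean distance transforms; and the
    morphometric analyses used for real airway casts: diameter-based
    generation assignment with a measurement tolerance, bifurcation
    angle and diameter-ratio summaries stratified by bifurcating-plane
    class, plane-rotation series along mainstem pathways, and piecewise
    log-linear regression of airway diameter against generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
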