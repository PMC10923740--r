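Package: hto3d
Title: Three-Dimensional Planning and Evaluation of Medial Open-Wedge High
    Tibial Osteotomy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Landmark-based three-dimensional analysis, virtual planning and
    quantitative evaluation of medial open-wedge high tibial osteotomy (HTO)
    on triangulated bone surface models. Builds an anatomic tibial coordinate
    frame from named landmarks, measures the medial proximal tibial angle
    (MPTA), medial and lateral tibial slope and tibial torsion, constructs and
    executes a biplanar osteotomy with a lateral hinge and a prescribed medial
    gap, and compares realized against planned anatomy via best-fit rigid
    registration, signed surface-deviation maps with banded grading, and
    cohort deviation statistics. A parametric synthetic-tibia generator with
    analytically known landmarks makes every stage testable without imaging
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
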