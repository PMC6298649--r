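Package: cvoplan
Title: Geometric Planning and Radiographic Validation for Curved
    Intertrochanteric Varus Osteotomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Pre-operative planning tools for curved intertrochanteric
    varus osteotomy (CVO) of the hip.  Implements the closed-form rigid
    rotation model that predicts post-operative leg shortening and
    femoral lateralization from the varus angle and the lateral/distal
    offsets of the osteotomy-arc center relative to the femoral-head
    center, together with the radiographic measurement pipeline that
    extracts those quantities from digitized anteroposterior landmarks
    (neck-shaft angle, teardrop-referenced vertical and lateral
    distances, lateral head index, least-squares circle fits), inverse
    planning utilities, validation statistics (Pearson correlation,
    intraclass correlation from ANOVA mean squares), and a seeded
    synthetic-cohort simulator so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
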