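Package: fmeatriz
Title: Fuzzy FMEA Risk Prioritization and TRIZ Solution Mapping for
    Service Blueprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for diagnosing and prioritizing service failure modes
    with fuzzy failure mode and effects analysis (Fuzzy-FMEA) and mapping
    their causes to inventive solution principles through a TRIZ
    contradiction matrix.  Multi-rater Likert ratings of severity,
    occurrence and detectability are fuzzified on a five-level linguistic
    scale of triangular fuzzy numbers, aggregated component-wise,
    defuzzified and ranked by fuzzy risk priority number (FRPN).  A
    service-blueprint data model carries failure-point annotations, a
    panel simulator and reverse count-fitting make every stage testable
    from published summary tables, and a bundled combined medical and
    elderly care (CMEC) case study exercises the full three-phase
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
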