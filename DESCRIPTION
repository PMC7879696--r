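Package: faersdispro
Title: Disproportionality Analysis of Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection in FAERS-style
    spontaneous adverse-event report databases. Reads and writes the public
    FAERS quarterly ASCII dialect, deduplicates cases to their latest version,
    builds exposure and comparator report cohorts from named term sets with an
    ordered cascade of exclusion filters and full attrition accounting, and
    computes proportional reporting ratios with log-scale Wald confidence
    intervals, reporting rates per 1000 reports, and Pearson chi-square tests.
    Ships the analysis battery used to study atrial fibrillation reporting for
    SGLT2 inhibitors versus other glucose-lowering drugs, including internal
    positive and negative controls and a forest-plot rendering, together with
    a seeded generator of FAERS-like report stores with known ground truth for
    validating every pipeline stage by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    ggplot2,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
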