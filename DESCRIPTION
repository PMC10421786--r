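Package: figgcba
Title: Cost-Benefit Analysis for Large SNP Panel Forensic Genetic Genealogy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the costs and benefits of replacing
    STR/capillary-electrophoresis DNA databasing with large SNP panels and
    forensic investigative genetic genealogy (FIGG). Implements a
    deterministic bounding model of investigative leads, prevented victims
    and tangible/intangible crime-cost savings per crime category; Monte
    Carlo uncertainty propagation over triangular and uniform input
    distributions with one-at-a-time tornado sensitivity analysis; and a
    sequencing reagent, caseload and infrastructure cost model including
    cost per investigative lead. Ships a parameter fixture encoding
    published database statistics and per-category input ranges, a
    synthetic-scenario generator with closed-form and enumeration oracles,
    and table/figure report writers.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
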