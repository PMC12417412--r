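Package: vaersmine
Title: Disproportionality Signal Mining for VAERS-Style Spontaneous Reports
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for post-marketing vaccine safety surveillance on
    spontaneous adverse-event report databases in the VAERS CSV dialect.
    Reads and links yearly VAERSDATA/VAERSVAX/VAERSSYMPTOMS triplets,
    tabulates demographics, clinical outcomes, onset times and vaccine
    characteristics, and screens target-vaccine/event pairs with four
    disproportionality statistics (reporting odds ratio, proportional
    reporting ratio with Pearson chi-square, the BCPNN information
    component, and the DuMouchel gamma-Poisson shrinker EBGM) under
    Benjamini-Hochberg false discovery rate control, followed by
    Designated-Medical-Event screening and missing-data sensitivity
    analysis. A synthetic-report generator with planted signal structure
    and configurable missingness makes the whole pipeline testable
    without access to the live database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
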