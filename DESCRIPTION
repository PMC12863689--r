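Package: pvmine
Title: Disproportionality Signal Mining for FAERS-Style Spontaneous Report Databases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pharmacovigilance pipeline for spontaneous adverse-event report
    databases distributed in the FAERS quarterly ASCII dialect. Reads and joins
    the DEMO/DRUG/REAC/OUTC/THER/INDI tables, applies the FDA case-level
    deduplication rule, extracts a drug cohort by synonym, suspect role and
    indication, maps MedDRA Preferred Terms to System Organ Classes, computes
    reporting odds ratio (ROR) and Bayesian confidence propagation neural
    network (BCPNN) disproportionality statistics with positivity thresholds
    and graded signal strength, produces demographic, outcome and time-to-onset
    descriptive tables, and screens graded signals against a product-label term
    list for new suspected adverse events. Includes a synthetic FAERS-schema
    database generator with injectable disproportionality so the whole pipeline
    is testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
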