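Package: faersignal
Title: Disproportionality Signal Detection and Time-to-Onset Profiling for FAERS-Style Spontaneous Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance analysis of FDA Adverse Event
    Reporting System (FAERS) quarterly extracts and FAERS-style data:
    reading the dollar-delimited DEMO/DRUG/REAC/THER/OUTC tables,
    curating and deduplicating case versions, identifying a target
    condition from an SMQ-style preferred-term list, normalising drug
    names and mapping ingredients to ATC level-2 classes, reporting
    odds ratio (ROR) disproportionality at drug and class level,
    Weibull shape parameter (WSP) time-to-onset profiling, and
    Table-1-style demographic summaries. A synthetic FAERS generator
    with planted drug-event signals makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
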