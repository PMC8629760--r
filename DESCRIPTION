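Package: crsaudit
Title: Audit of Panel-Based Genome Diagnostic Pipelines Using a Craniosynostosis Cohort
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-implements, as a tested and reusable pipeline, the diagnostic
    audit of a panel-based rare-disease genome sequencing programme, using
    craniosynostosis as the model disorder. Provides a trio-aware small-variant
    tiering engine (frequency, consequence, segregation under complete or
    incomplete penetrance, legacy quality filters, virtual gene-panel
    intersection), a CNV/SV Tier A engine with breakpoint-aware review, a
    synthetic trio-cohort generator that plants the audited causal-variant
    archetypes and failure modes alongside benign background variation, an
    embedded fixture of the 36 audited diagnoses, and strategy/audit engines
    that decompose diagnostic sensitivity by detection strategy and compare
    syndromic with non-syndromic diagnostic rates by one-tailed Fisher exact
    test.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    vcfR,
    yaml,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
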