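Package: targetrank
Title: Weighted Drug-Target Prioritization from Pathway Enrichment Results
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns a table of significant signaling pathways (SPIA or enrichr
    output) into ranked drug-repurposing candidates. Pathway members are
    resolved against an offline snapshot of target annotations modelled on the
    Open Targets Platform (disease associations, tractability, safety
    liabilities, clinical-phase drug counts and drug links), each target is
    scored with a configurable linear weighting scheme, and enrichment of a
    curated gold target set among the top-ranked candidates is assessed with a
    hypergeometric upper-tail test. Includes a deterministic synthetic-data
    generator so the full pipeline is testable without network access.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
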