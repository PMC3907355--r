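Package: ibdrelate
Title: Relationship Estimation from Identity-by-Descent Segments
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood classification of pairwise genetic
    relationships (1st through 12th degree) from identity-by-descent (IBD)
    segment data. Fits a null model of background IBD sharing from a control
    cohort, models the number and length of segments expected under each
    candidate relationship (including dedicated parent-offspring,
    ancestor-descendant, full-sibling and avuncular models, with optional use
    of IBD2 segments), and tests each pair with a two-degree-of-freedom
    likelihood-ratio test. Includes detection and masking of genomic regions
    with excess IBD in controls, readers for GERMLINE-like segment files and
    genetic maps, and a gene-dropping pedigree simulator that produces
    ground-truth IBD segments for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: data.table, stats, utils
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
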