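Package: sigscan
Title: APOBEC Mutational Signature Enrichment and Somatic Mutation Spectrum Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of somatic mutation cohorts for evidence of APOBEC3
    cytidine-deaminase mutagenesis. Reads somatic variant calls (VCF or TSV)
    and a reference genome, applies read-support filters, builds 96-context
    single-base-substitution spectra, computes the TCW fold-enrichment score
    over 41-base mutation contexts with one-sided Fisher exact significance
    and Benjamini-Hochberg correction, refits spectra against a signature
    catalog by forward selection with non-negative least squares, classifies
    small insertions and deletions (including microhomology deletions), and
    profiles mutation density across replication-timing quintiles. A
    synthetic-cohort generator plants known APOBEC signal so that every
    stage of the pipeline is verifiable by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
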