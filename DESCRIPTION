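Package: estdged
Title: Corrected Digital Gene Expression from EST cDNA Library Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for digital gene expression analysis of expressed sequence
    tag (EST) cDNA library counts in the style of the CGAP xProfiler and cDNA
    DGED workflow. Parses CGAP-style library metadata flat files and
    UniGene-style relational expression and gene tables, selects cDNA
    libraries for a tissue either by exact matching of the controlled
    "unique tissue" annotation (corrected mode) or by emulating the historical
    substring keyword matcher (legacy mode), accounts for library size by the
    number of sequences that actually map onto gene clusters, tabulates
    per-gene counts across two library pools with Boolean and sequence
    odds-ratio outputs, and computes the posterior probability of at least
    k-fold upregulation from independent Beta posteriors by Gauss-Legendre
    quadrature, alongside Fisher exact tests and Benjamini-Hochberg q-values
    whose values are independent of any display cut-off. Includes a
    deterministic synthetic fixture generator reproducing documented library
    database pathologies for testing.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
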