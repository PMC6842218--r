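Package: cistrans
Title: Cis- and Trans-Regulatory Divergence from Allele-Specific
    Expression in F1 Hybrids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies cis- and trans-regulatory divergence between two
    parental species from replicated allele-specific read counts at
    diagnostic SNP sites in the parents and their F1 hybrid. Implements
    the max-of-two-mappings merge and SNP-site quality filters, TMM
    normalization with replicate quality control, a conditional
    negative-binomial exact test for hybrid-versus-parent differential
    expression and the eight expression-inheritance clusters, exact
    binomial and Fisher tests with Benjamini-Hochberg FDR control for
    the seven regulatory categories (cis only, trans only, cis + trans,
    cis x trans, compensatory, conserved, ambiguous), and comparative
    summaries across crosses. A negative-binomial simulator with known
    cis/trans structure makes every stage verifiable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    edgeR,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
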