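Package: pleiocfdr
Title: Pleiotropy-Informed Conditional FDR for Paired GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Discovers genetic loci shared between two traits from genome-wide
    association study (GWAS) summary statistics using the conditional false
    discovery rate (cFDR). Harmonizes two per-SNP p-value tables, prunes
    correlated variants against a genotype reference panel with a
    sliding-window r-squared filter, estimates per-SNP cFDR in both
    conditioning directions from conditional empirical cumulative distribution
    functions, combines the two directions into a conjunction FDR to call
    pleiotropic loci, and computes conditional Q-Q, fold-enrichment, and
    conditional Manhattan diagnostics. A two-trait summary-statistics
    simulator with known pleiotropic architecture and an LD-blocked reference
    panel generator make the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    ggplot2,
    stats,
    utils,
    tools,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
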