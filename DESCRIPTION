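Package: gsdtools
Title: Grand H3K27me3 Silencer Domain Analysis
Version: 0.1.0
Authors@R:
    person("GSD", "Maintainers", email = "gsdtools@example.org", role = c("aut", "cre"))
Description: Calls breadth-defined repressive H3K27me3 domains from ChIP-seq
    peaks, classifies the top-quantile "grand silencer domains" (GSDs),
    relates them to gene constraint, expression, TADs and chromatin loops
    with a genomic permutation null, and classifies two-condition domain
    loss/gain integrated with differential expression and DNA methylation.
    Ships a seeded synthetic-epigenome generator with planted truth so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
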