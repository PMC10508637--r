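Package: lncomp
Title: Long Non-Coding RNA Expression Compendium Analysis
Version: 0.1.0
Authors@R: person("EmbryoGENE", "Reanalysis Team", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to reannotate microarray probes against multiple genome
    annotation sources (mRNA, intronic, antisense and intergenic lncRNA
    classes with cross-source consensus voting), assemble a quantile
    normalized expression compendium with negative-control based detection
    calling and tissue-specificity accounting, build signed weighted
    co-expression networks from first principles (soft thresholding,
    topological overlap, module eigengenes, module-trait correlation),
    perform hypergeometric gene-set enrichment with Benjamini-Hochberg
    control, and score hub transcription factors and hub genes by
    correlation-coefficient sums.  Includes a synthetic-data generator with
    planted ground truth (co-expression modules, tissue-specific probe
    sets, negative-control backgrounds, disagreeing annotation sources) so
    the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
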