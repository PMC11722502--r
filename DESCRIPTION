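Package: chicv2g
Title: Variant-to-Gene Mapping from GWAS Fine-Mapping and Capture Hi-C
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A post-GWAS variant-to-gene analysis pipeline: fine-maps risk
    signals from summary statistics using likelihood-ratio, linkage
    disequilibrium, and externally supplied Bayesian credible sets; models
    dual-enzyme restriction fragment maps and CHiCAGO-style fragment bins;
    links credible causal variants to gene promoters through high-confidence
    chromatin interaction loops or direct promoter overlap; filters links
    with cell-type-specific regulatory annotation (ChromHMM states, ATAC
    peaks) and massively parallel reporter assay results; and ranks
    candidate genes with an integrative 0-8 evidence score. A synthetic-data
    generator with a planted-truth ledger emulates every input so the whole
    analysis is testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
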