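Package: nrpbm
Title: SNV-Based Protein-Binding Microarray Analysis of Nuclear Receptor
    Heterodimers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for single-nucleotide-variant (SNV) protein-binding
    microarray (PBM) experiments on nuclear receptor heterodimers. Generates
    combinatorial direct-repeat probe libraries (seed sequences, all SNVs,
    half-site ablations, random genomic background probes), converts raw
    fluorescence into background-referenced z-scores, infers per-seed delta-z
    energy matrices and position frequency matrices via a Boltzmann (softmax)
    transform, classifies binding modes (full-site versus 5'/3' half-site),
    builds spacer-preference landscapes, quantifies PWM enrichment in genomic
    regions by ROC/AUC with Wilcoxon rank-sum significance, and estimates
    relative dissociation constants from competition EMSA titrations. A
    synthetic-data generator with a dual-mode occupancy model and lognormal
    noise makes the whole pipeline testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    withr,
    jsonlite,
    yaml,
    ggplot2,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
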