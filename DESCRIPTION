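Package: denovofp
Title: De Novo Motif Discovery from Chromatin Accessibility Footprints
Version: 0.1.0
Authors@R:
    person("BCU", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects transcription-factor footprints from per-base ATAC-seq
    binding-score tracks by custom peak calling, removes footprint portions
    explained by known database motifs, and iteratively derives de novo motifs
    from the remaining sequences with a built-in ZOOPS
    (zero-or-one-occurrence-per-sequence) EM motif finder, a dynamic
    knee-point e-value filter and sequence-pool subtraction with flank
    retention. Discovered motifs are clustered and merged into consensus
    motifs and characterized by genome-wide scanning, open-chromatin
    enrichment, nearest-feature annotation, hypergeometric gene-set
    enrichment, database comparison (rediscovered versus novel at a
    similarity-distance threshold) and binding-site-overlap TF-class
    enrichment, including a differential two-condition mode. A synthetic-data
    module generates genomes with implanted motif instances and flat-topped
    footprint score tracks so the full pipeline is testable without external
    datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    rtracklayer,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
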