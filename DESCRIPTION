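Package: perlscan
Title: Discovery and Characterization of Germline-Specific Expression Loci
    and piRNA Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a coverage-based caller for large (>= 250 kb)
    germ-cell-specific non-genic expression loci (PERLs) from replicated
    RNA-seq coverage, together with the small RNA analytics used to
    characterize them: ping-pong signature Z-scores, sense/antisense bias,
    read length profiles, positional nucleotide bias (1U/10A, downstream U),
    transposable-element enrichment against size- and chromosome-matched
    shuffled backgrounds, intergenic-transcription quantification, and
    fold-change/FDR gene-set selection with Pearson/Ward expression
    clustering. Ships a synthetic-data generator that plants known loci,
    biases and gene archetypes so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
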