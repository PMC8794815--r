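Package: riboStart
Title: Start-Codon Context Analysis of Translation Initiation Inhibition from Ribosome Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying context-specific inhibition of bacterial
    translation initiation from ribosome profiling (Ribo-seq) and RNA-seq
    alignments. Implements A-site footprint density assignment (3' end, -12 nt
    shift), fractional RNA coverage, per-gene RPKM and translation efficiency
    (TE), drug-induced TE changes, start-codon metagene profiles, the head
    enrichment statistic, position-specific binomial (pLogo-style) enrichment
    of start-codon context, and categorization of operonic genes by
    start/stop-codon overlap (translational coupling). Includes a synthetic
    footprint simulator encoding a mechanistic model of start-codon arrest
    whose severity depends on the nucleotide immediately preceding the start
    codon, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
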