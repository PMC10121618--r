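Package: tribetools
Title: RBP Target Calling from ADAR-Fusion RNA Editing with Downstream
    Multi-Omics and Cell-Division Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies RNA-binding-protein (RBP) mRNA targets from
    HyperTRIBE-style experiments, in which an RBP fused to the catalytic
    domain of ADAR deposits A-to-I edits on bound transcripts. Calls
    differential editing events from per-site reference/alternate read
    counts (pooled Fisher exact test or a replicate-aware beta-binomial
    likelihood-ratio test, Benjamini-Hochberg FDR), annotates genic
    location (5'UTR/CDS/3'UTR), performs de novo k-mer motif enrichment
    around edit sites and nearest-motif distance density estimation,
    integrates target lists with transcriptome and label-free proteomics
    fold-change tables (normalization, one-sided rank tests, Venn region
    counting), and scores asymmetric cell division and polarity from
    paired daughter-cell immunofluorescence intensities. A synthetic-data
    generator with known ground truth makes the full pipeline testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
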