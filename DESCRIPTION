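Package: ncharlab
Title: Compilation, Enhancer Prediction and Validation Calling for
    Non-Coding Human Accelerated Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing non-coding human accelerated regions
    (ncHARs) as candidate developmental enhancers.  Compiles a
    non-redundant ncHAR set from multiple published interval sets,
    annotates genomic context and enhancer-associated functional
    genomics evidence, performs regulatory-domain based gene-term
    enrichment, predicts developmental enhancers and their tissues with
    a two-stage multi-kernel support vector machine, scores
    human-chimpanzee transcription-factor binding-site divergence with
    a permutation test, ranks candidates for transgenic validation, and
    calls enhancer activity, confidence and species differences from
    embryo LacZ staining tables.  A synthetic-data module generates
    every input with planted ground truth so the whole pipeline can be
    exercised offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    kernlab,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
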