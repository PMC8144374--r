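Package: bbsplice
Title: Beta-Binomial Differential Splicing and Splice-Outlier Analysis with
    Protein Effect Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical analysis of alternative splice events quantified as
    per-isoform read counts. Provides a beta-binomial likelihood-ratio test
    for differential percent-spliced-in (PSI) between two sample groups, a
    beta-binomial outlier score that measures how extreme a sample's
    minor-isoform usage is relative to a reference panel, and simple
    comparator statistics (Welch t-test on PSI, MAD and IQR outlier scores).
    Splice events are translated into predicted protein consequences by
    matching event junctions to annotated transcripts, swapping junctions,
    translating the edited transcript and classifying the altered
    amino-acid run; annotated tables and protein FASTA databases are
    emitted for downstream proteogenomics. A synthetic-data module
    generates beta-binomial count tables and toy genome/annotation
    fixtures covering all five event types.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
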