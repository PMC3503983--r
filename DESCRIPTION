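Package: ltrfate
Title: Structural Annotation, Fate Classification and Insertion Dating of
    LTR Retrotransposons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how long-terminal-repeat (LTR)
    retrotransposons shape plant genomic regions. Provides a synthetic
    region simulator with planted ground truth (genes, nested LTR
    elements of known family, age and fate, DNA transposons, tandem
    arrays and gene-movement footprints), a structural annotator
    (self-comparison LTR-pair search, consensus-library matching,
    target-site-duplication detection), a nine-category element-fate
    classifier with removal-mechanism inference and region
    contraction/expansion balance, Kimura two-parameter insertion dating
    (T = K/2r), TE-composition and gene-density region profiling with a
    descriptive chromatin indicator, and scanners for double-strand-break
    repair gene-movement footprints (target-site-duplication capture,
    shared borders, Helitron capture, tandem-repeat flanks, retrocopies).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
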