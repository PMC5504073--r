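Package: ctcfLandscape
Title: CTCF Binding Landscape Analysis from ChIP-seq Peak Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising the genome-wide CTCF binding landscape
    of a species from ChIP-seq peak calls: replicate-consensus and
    significant peak selection, de novo discovery of the two-part CTCF
    recognition sequence (16-bp core plus upstream "M2" motif) by ZOOPS
    expectation-maximisation against a first-order Markov background, exact
    PWM p-values by dynamic programming, association testing between binding
    sites and repeat families (Fisher's exact test, conditional-MLE odds
    ratios, Storey q-values with sampled N-free control regions), and
    orientation-aware mapping of binding sites across Hox clusters. A fully
    seeded synthetic-data generator with ground truth makes every stage
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    stats,
    methods,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
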