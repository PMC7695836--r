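Package: crispriscreen
Title: Design and Analysis of Inducible CRISPRi Screens in Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end toolkit for pooled, inducible CRISPR interference
    (CRISPRi) screens in Saccharomyces cerevisiae: enumeration and selection
    of promoter-proximal spacers using TSS-distance and nucleosome-occupancy
    rules, scrambled non-targeting control generation, spacer counting from
    amplicon reads with a one-mismatch contract, log-frequency and depletion
    scoring, a resampled scrambled-gene empirical null with Stouffer
    combination of replicate z-scores, empirical-FDR hit calling and
    benchmark curves, a cross-validated random-forest guide-efficacy
    classifier with permutation feature contributions and per-position
    nucleotide enrichment, plus a synthetic-screen generator with known
    ground truth for validating every stage offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    randomForest,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
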